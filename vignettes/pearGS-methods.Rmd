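---
title: "Models and methods in pearGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pearGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearGS)
```

pearGS implements a complete quantitative-genetics workflow for fruit-sugar
traits in a pear breeding program: a synthetic-population generator, marker
quality control, population-structure and linkage-disequilibrium (LD)
statistics, two complementary genome-wide association (GWAS) models, per-SNP
variance summaries, and genomic prediction with leave-one-family-out
cross-validation. This vignette documents the models, the tunable parameters
and their defaults, the numerical choices, and the known limits of what the
synthetic data can demonstrate.

## The study design being emulated

The package is built around a breeding-program design common in fruit-tree
genetics: a collection of 106 cultivars plus full-sib F1 families (the
default preset uses 18 crosses of 28–121 seedlings, 1112 F1 individuals, so
1218 individuals in total), genotyped at roughly 3,500 tag SNPs spread over
17 chromosomes, with ten fruit traits. The sugar traits are sucrose (SUC),
fructose (FRU), glucose (GLC) and sorbitol (SOR) content of juice (mg/ml),
and their sum, the total sugar content (TSC). The other traits are harvest
time (HarT, days after June 30, so July 1 = day 1), fruit weight (g), fruit
hardness (lb), soluble-solids concentration (SSC, %), and acidity (juice pH).

## The synthetic-population generator

### Founder haplotypes and LD

`simulate_founders()` draws marker positions uniformly per chromosome and
per-marker allele frequencies from a U-shaped Beta(0.5, 0.5) distribution
truncated to [0.05, 0.95]. Each haplotype is generated by an
along-chromosome copying process: a latent Gaussian AR(1) whose
marker-to-marker correlation decays as exp(−d/L), dichotomised at the
frequency-matching normal quantile. This is not a coalescent — it is the
simplest process with one interpretable dial, the decay length L.

L is calibrated once, analytically: the expected dosage r² between two
markers at latent correlation ρ is computed by integrating the bivariate
normal orthant probability over the allele-frequency distribution, and the
ρ\* solving E[r²] = 0.2 is converted to L = −`ld_range_bp`/log ρ\*. With the
default `ld_range_bp = 250000` the founder panel's mean r² falls to about
0.2 at 250 kb, the value reported for this kind of breeding germplasm. In
the full population (families of full sibs bred from a limited set of
parents) the realised pooled r² at 250 kb sits slightly higher (typically
0.18–0.24), because family structure and parent reuse add long-range
disequilibrium — as they do in real programs.

### Meiosis and population assembly

`simulate_meiosis()` uses a no-interference (Haldane) model: crossover
counts are Poisson with mean equal to the chromosome's genetic length
(default 1 Morgan), crossover points uniform on the genetic map, and genetic
position proportional to physical position. `build_population()` advances
the founders two generations by random crossing to form the cultivar
collection — a stand-in for the untracked pedigree of a real program, not an
inferred one — and then crosses randomly chosen cultivar pairs (parents may
recur across crosses, as they do in practice) to produce the F1 families.

### The sugar-trait model

Sugar phenotypes are generated through four latent channels rather than a
multivariate-normal effect matrix, because the signature of interest —
one locus raising sucrose while lowering the hexoses with total sugar almost
unchanged — is a *conversion* phenomenon:

* total sugar `T` (mg/ml): polygenic + family effects + noise;
* sorbitol `SOR`: an independent polygenic channel;
* a conversion fraction `c ∈ (0,1)` on a logistic scale: the share of
  `S = T − SOR` converted from sucrose into hexoses;
* a hexose split `h ∈ (0,1)`: the fructose share of the hexose pool.

Traits are `SUC = S(1−c)`, `FRU = S·c·h`, `GLC = S·c·(1−h)`, and
`TSC = SUC + FRU + GLC + SOR` computed as that literal sum, so the
accounting identity holds exactly for every individual. Noise enters
*through the channels*, not per trait: year-to-year variation in conversion
moves SUC and GLC in opposite directions, which is what makes the strong
negative SUC–GLC correlation possible at trait heritabilities around
0.6–0.8. (With independent per-trait noise the achievable correlation is
capped near −0.5, visibly weaker than real data.)

Channel parameters are solved at generation time from trait-level anchors
(means 43.1/40.6/14.9/32.2/130.7 mg/ml; variances 355.6 for SUC, 125.2 for
TSC, 56.5 for SOR, 64.3 for GLC; heritabilities 0.64/0.69/0.71/0.76/0.33):

* the conversion-channel mean and variance are found by exact
  logistic-normal moment matching (Gauss–Hermite quadrature) so that the SUC
  mean and variance are hit despite the nonlinearity;
* a coupling `κ` tilts the hexose split toward glucose as conversion rises;
  it is calibrated so the model's GLC variance equals its anchor. The
  emergent SUC–GLC correlation is about −0.67. A correlation of −0.76, as
  observed in real data, is not representable in this model class once the
  hexose-split QTL (which is uncorrelated with SUC) carries its observed
  variance share — a documented structural limit, not a tuning choice;
* QTL effects are assigned with `assign_qtl_effects()` — the per-dosage
  effect `a = sqrt(PVE · Var(y) / Var(x))` — mapped onto the logit channels
  through moment-based effective derivatives, so the realised trait-level
  PVE matches the target (23.5% of SUC for the sucrose-conversion locus,
  21.7% of GLC for the hexose-split locus) rather than being attenuated by
  the logistic link;
* polygenic channel scores (random 300-marker subsets) and channel noises
  are orthogonalised in-sample against the QTL and family components and
  rescaled to their exact variance budgets. Without this, chance
  correlations between channels — mediated by family structure — blur the
  calibrated covariance structure from one seed to the next.

Family effects (default variance 12.5 (mg/ml)², about 10% of the TSC
variance) enter the total-sugar channel for F1 families; the collection has
none. Non-sugar traits are independent polygenic channels with optional
direct QTLs (harvest time and acidity carry two each by default); SSC is
TSC/9.47 plus a small noise term, reproducing the near-unity TSC–SSC
correlation.

What the generator does *not* emulate: genotyping error and imputation
noise, multi-year phenotype replication, the positive harvest-time–fruit-
weight correlation, crossover interference, and a realistic admixture
history (the PCA leading-component share is consequently smaller than in
real germplasm). Tests passing on this generator therefore validate the
estimators' statistical behaviour, not any claim about real pear data.

## Marker QC and input formats

`read_vcf()` (backed by vcfR) parses biallelic records to dosages, accepts
phased and unphased separators, treats `./.`-style tokens as missing, and
skips multiallelic records with a count. QUAL/depth filters apply only when
the fields are present, so synthetic files pass unfiltered.
`filter_markers()` keeps markers with MAF ≥ 0.01 (computed on non-missing
calls) and missing rate ≤ 0.25; removal is strict-greater on missingness, so
a marker at exactly 25% stays. `impute_mode()` fills missing calls with the
marker's majority dosage (ties toward the smaller dosage); it is the
documented stand-in for haplotype-based imputation, which is out of scope,
and is adequate once QC has capped the missing rate.

## Structure and LD statistics

* `vanraden_kinship()`: G = W W′ / (2 Σ p(1−p)), W the dosage matrix
  centered by 2p, frequencies observed on the full analysed set; a 1e-8
  ridge keeps G numerically PSD.
* `pairwise_r2()`: squared Pearson correlation of dosages (composite LD) —
  phase-free, which is the standard surrogate when only imputed genotypes
  exist; undefined pairs return missing.
* `ld_decay()`: all intra-chromosomal pairs up to 2 Mb, excluding the
  fictive chromosome "0" of unassigned scaffolds, binned in 10-kb steps.
* `greedy_tag_snps()`: Haploview-style pairwise tagging at r² ≥ 0.8 — the
  marker covering the most uncovered markers is picked repeatedly, ties
  broken by chromosome then position. Every marker ends up covered, and
  tagging the tag set returns it unchanged.
* `ld_prune()`: PLINK-style sliding window (50 markers, step 10, r² > 0.1),
  dropping the later-positioned member of each offending pair.
* `genotype_pca()`: centered (not scaled) dosages decomposed by SVD,
  optional pruning first, sign fixed by the largest-magnitude loading;
  variance-scaling is available behind a flag.

## The mixed-linear-model GWAS

`fit_null_mlm()` fits y = Xβ + u + e with u ~ N(0, σ²g K) by REML on the
eigenbasis of K: the likelihood is profiled over δ = σ²e/σ²g, scanned on a
100-point log grid spanning [1e-5, 1e5] and refined by golden-section /
parabolic search to 1e-8. `mlm_scan()` then Wald-tests each marker's dosage
coefficient under V̂ = σ̂²g K + σ̂²e I held fixed at the null estimates —
the P3D approximation, which is orders of magnitude faster than per-marker
REML and standard at these effect sizes; `exact = TRUE` re-optimises per
marker for validation. P-values are χ²(1) (not F), consistent with the
sample sizes involved; covariates default to the first three genotype PCs.
Monomorphic markers get missing p-values. `bh_fdr()` is the
Benjamini–Hochberg step-up at q = 0.05 and also returns the largest rejected
p-value — the significance line drawn on Manhattan plots.

## The variational BayesB multiple-QTL model

All markers are fitted simultaneously in

y_i = μ + Σ_j x_ij δ_j a_j + f_{fam(i)} + e_i,

with δ_j ~ Bernoulli(π), a_j | σ²_aj ~ N(0, σ²_aj), σ²_aj ~
scaled-inv-χ²(ν, S²), family (progeny) effects f_k ~ N(0, σ²_f) — the
cultivar collection counts as one class — and e_i ~ N(0, σ²_e). Fitting is
mean-field coordinate ascent. Each SNP's spike-and-slab factor is updated
against the current residual:

* slab variance ṽ_j = σ²_e / (x_j′x_j + σ²_e/σ²_aj),
* slab mean ã_j = ṽ_j x_j′ r_j / σ²_e,
* inclusion log-odds λ_j = logit(π) + ½ log(ṽ_j/σ²_aj) + ã_j²/(2ṽ_j),
  γ_j = logistic(λ_j) — γ_j is the "SNP weight".

σ²_aj is updated as the exact coordinate maximiser of the objective under
its scaled-inv-χ² prior with γ-weighted sufficient statistics,
(νS² + γ_j(ã_j² + ṽ_j)) / (ν + γ_j + 2); μ, the family factors, σ²_f and
σ²_e have closed-form updates. Because *every* update is an exact ascent
step, the evidence lower bound is non-decreasing by construction; the C++
core computes the ELBO each sweep and aborts on any decrease beyond float
slack (1e-6 relative), so a monotonicity violation is an internal error, not
a warning. Convergence is a relative ELBO change below 1e-6, capped at 1000
sweeps; the update order follows genomic coordinates (storage order is
irrelevant), with optional seeded per-sweep shuffling and restarts.

Hyperparameter defaults follow standard BayesB practice, since the original
settings are not printed anywhere: π = 10/m (about ten QTLs expected),
ν = 4.2, and S² scaled so the prior mean of σ²_aj equals
0.5·Var(y)/(π·Σ 2p(1−p)) — markers in the model account for half the
phenotypic variance a priori. All are overridable through `vb_hyper()`.
Significance uses the posterior-weight threshold γ ≥ 0.85; the comparison is
inclusive, the safer reading of a rule that reports markers "at" the
threshold, and it is configurable. Progeny effects are treated as a random
effect with its own estimated variance rather than fixed — they exist to
absorb genetic-background differences, and shrinkage keeps small families
from overfitting.

## Effect characterisation

`snp_pve()` implements the variance-share definition: PVE = 100 · effect² ·
Var(x) / Var(y) with population variances — the reading of "variance of the
SNP divided by the total phenotypic variance" consistent with an additive
per-dosage effect. A genotype-class-mean R² alternative exists behind a
flag-level choice (fit the class means yourself via
`genotype_class_means()`). `pve_per_family()` recomputes the share within
each family with a family-re-estimated OLS effect — family-specific
percentages imply family-level re-estimation — blanking cells where the
marker does not segregate or any genotype class has fewer than 2 members.
The model-averaged vBayesB effect is b̂_j = γ_j·ã_j.

## Genomic prediction

GBLUP is the intercept-only mixed model (no other fixed effects); the
polygenic effect is the breeding value, and new individuals are scored as
û = K_test,train (K + δI)⁻¹ (y − μ̂) with both kinship blocks built from
*training-set* allele frequencies to keep CV folds honest (full-sample
frequencies would leak test information). The vBayesB prediction is the sum
of estimated SNP effects times SNP weights, μ̂ + Σ_j x_ij γ_j ã_j, without
family effects — test families are unseen by construction.

`leave_one_family_out_cv()` holds out each F1 family in turn; the collection
is always training-only. Accuracy is Pearson's r between predictions and
observations, with negative values recorded as 0 and undefined values
(zero-variance folds) also 0 — one rule covering both degeneracies. Both the
per-family mean and the pooled r over all F1 individuals are reported; the
headline figure is the pooled one, which is what a single correlation "over
all individuals in F1 families" measures. On the default preset the pooled
GBLUP accuracy for SUC is about 0.4–0.55 — deliberately read as a sanity
band consistent with, not equal to, the 0.55–0.75 range real programs
report: the synthetic polygenic background is exchangeable across families,
which is harder to transfer than real shared ancestry.

## Numerical choices and degenerate inputs

* REML: δ-grid [1e-5, 1e5], 1e-8 refinement tolerance; K must be PSD after
  the 1e-8 ridge; constant phenotypes are rejected.
* vBayesB: γ entropy terms use exact x·log x limits at 0/1; σ²_f floored at
  1e-10; σ²_e at 1e-12; monomorphic (zero-variance) columns keep γ = π and
  a zero effect.
* Tie-breaks: mode imputation ties toward the smaller dosage; the tagger
  toward the smaller chromosome then position; pruning drops the
  later-positioned member.
* Harvest dates on or before June 30 are rejected rather than clamped.
* A family with fewer than 3 phenotyped members is skipped in CV with a
  warning; an all-missing marker is an error in imputation.

## Problem sizes used by the test-suite simulations

The packaged tests run the estimators at reduced but informative scale,
chosen as the smallest sizes at which the checked properties are stable:
parameter recovery at n ≈ 1000 individuals × 2000 markers (20 replicates),
null calibration at n = 500 × 2000 (200 MLM replicates, 20 vBayesB
replicates), and population fidelity plus prediction on the full default
preset (1218 × 3485). Oracle-equivalence checks (dense GLS, mixed-model
solves, conjugate posteriors, exhaustive set cover, dense eigensolvers) run
on fixtures of 25–60 individuals.
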