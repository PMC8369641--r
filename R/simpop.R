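#' Simulation configuration for a multi-family breeding population
#'
#' Describes the genome (chromosome count, physical and genetic lengths,
#' marker density), the linkage-disequilibrium target, and the population
#' design: a cultivar collection bred from a founder panel by two generations
#' of random crossing, plus F1 full-sib families of designated cultivar
#' pairs.
#'
#' @param n_founders founder haplotype-panel size (default 106)
#' @param n_cultivars cultivar-collection size (default 106)
#' @param family_sizes F1 family sizes; the default reproduces a pear
#'   breeding program: 18 crosses of 28-121 individuals totalling 1112 F1
#'   seedlings, 1218 individuals with the collection
#' @param n_chromosomes number of chromosomes (default 17)
#' @param chrom_length_bp physical chromosome length in bp (default 45 Mb)
#' @param chrom_length_morgans genetic length per chromosome in Morgans
#'   (default 1.0)
#' @param n_markers_per_chrom markers per chromosome (default 205, about
#'   3,500 genome-wide, emulating a tag-SNP panel)
#' @param ld_range_bp distance at which expected founder r-squared is about
#'   0.2 (default 250 kb); 0 disables linkage disequilibrium entirely
#' @param family_size_range allowed family-size bounds (default c(28, 121))
#' @param prop_chrom0 fraction of markers relabelled to the fictive
#'   chromosome "0" (unassigned scaffolds) to exercise downstream exclusion
#'   logic (default 0)
#' @param seed integer seed; fixed seed gives bit-identical output
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_founders = 106,
                       n_cultivars = 106,
                       family_sizes = c(106, 28, 62, 47, 33, 78, 38, 36, 70,
                                        51, 100, 62, 121, 49, 39, 74, 72, 46),
                       n_chromosomes = 17,
                       chrom_length_bp = 45e6,
                       chrom_length_morgans = 1.0,
                       n_markers_per_chrom = 205,
                       ld_range_bp = 250000,
                       family_size_range = c(28, 121),
                       prop_chrom0 = 0,
                       seed = 1L) {
  counts <- c(n_founders, n_cultivars, n_chromosomes, n_markers_per_chrom)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (any(family_sizes < 1)) stop("family sizes must be >= 1")
  if (any(family_sizes < family_size_range[1] | family_sizes > family_size_range[2])) {
    stop("family sizes outside the declared bounds [",
         family_size_range[1], ", ", family_size_range[2], "]")
  }
  if (chrom_length_bp < n_markers_per_chrom) stop("chromosome too short for marker count")
  if (ld_range_bp < 0) stop("ld_range_bp must be >= 0")
  if (prop_chrom0 < 0 || prop_chrom0 >= 1) stop("prop_chrom0 must be in [0, 1)")
  structure(list(n_founders = as.integer(n_founders),
                 n_cultivars = as.integer(n_cultivars),
                 family_sizes = as.integer(family_sizes),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp,
                 chrom_length_morgans = chrom_length_morgans,
                 n_markers_per_chrom = as.integer(n_markers_per_chrom),
                 ld_range_bp = ld_range_bp,
                 family_size_range = family_size_range,
                 prop_chrom0 = prop_chrom0,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# ---- founder LD calibration ------------------------------------------------

# correlation of two threshold-dichotomised standard normals with latent
# correlation rho and marginal allele frequencies p1, p2
.binary_corr <- function(rho, p1, p2) {
  if (rho == 0) return(0)
  t1 <- stats::qnorm(p1); t2 <- stats::qnorm(p2)
  s <- sqrt(1 - rho^2)
  p11 <- stats::integrate(function(z) stats::pnorm((t2 - rho * z) / s) * stats::dnorm(z),
                          -Inf, t1, rel.tol = 1e-8)$value
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# expected dosage r^2 between two markers at latent correlation rho, averaged
# over the U-shaped allele-frequency distribution used by simulate_founders
.expected_r2 <- function(rho, n_nodes = 8) {
  lo <- stats::pbeta(0.05, 0.5, 0.5); hi <- stats::pbeta(0.95, 0.5, 0.5)
  p <- stats::qbeta(lo + (hi - lo) * (seq_len(n_nodes) - 0.5) / n_nodes, 0.5, 0.5)
  grid <- expand.grid(p1 = p, p2 = p)
  mean(mapply(function(a, b) .binary_corr(rho, a, b)^2, grid$p1, grid$p2))
}

.calib_env <- new.env(parent = emptyenv())

# latent AR(1) correlation at which the expected dosage r^2 equals `target`
.calibrate_rho <- function(target = 0.2) {
  key <- sprintf("rho_%.6f", target)
  if (!is.null(.calib_env[[key]])) return(.calib_env[[key]])
  f <- function(rho) .expected_r2(rho) - target
  if (f(0.999) < 0) {
    stop("LD calibration failure: target r2 ", target,
         " is not reachable by the copying process (no positive root)")
  }
  rho <- stats::uniroot(f, c(1e-4, 0.999), tol = 1e-6)$root
  .calib_env[[key]] <- rho
  rho
}

#' Simulate founder haplotypes with calibrated linkage disequilibrium
#'
#' Marker positions are drawn uniformly per chromosome; per-marker allele
#' frequencies come from a U-shaped Beta(0.5, 0.5) distribution truncated to
#' [0.05, 0.95]. Each haplotype is an along-chromosome copying process: a
#' latent Gaussian AR(1) with marker-to-marker correlation exp(-d/L),
#' dichotomised at the frequency-matching threshold. L is calibrated so the
#' expected pairwise dosage r-squared at distance `ld_range_bp` is 0.2;
#' `ld_range_bp = 0` yields independent markers.
#'
#' @param config a [sim_config()]
#' @return list of class `haplotype_panel`: `haplo` (2 * n_founders x m
#'   binary matrix, rows 2i-1 and 2i are founder i's haplotypes) and `map`
#'   (marker metadata with physical and genetic positions)
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m_chr <- config$n_markers_per_chrom
  n_hap <- 2L * config$n_founders
  L <- if (config$ld_range_bp > 0) {
    rho_star <- .calibrate_rho(0.2)
    -config$ld_range_bp / log(rho_star)
  } else 0
  maps <- vector("list", config$n_chromosomes)
  haps <- vector("list", config$n_chromosomes)
  lo <- stats::pbeta(0.05, 0.5, 0.5); hi <- stats::pbeta(0.95, 0.5, 0.5)
  for (chr in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(config$chrom_length_bp, m_chr))
    if (any(diff(pos) <= 0)) stop("non-increasing marker positions")
    p <- stats::qbeta(stats::runif(m_chr, lo, hi), 0.5, 0.5)
    thr <- stats::qnorm(p)
    rho <- if (L > 0) exp(-diff(pos) / L) else rep(0, m_chr - 1L)
    z <- matrix(0, n_hap, m_chr)
    z[, 1L] <- stats::rnorm(n_hap)
    for (k in 2L:m_chr) {
      z[, k] <- rho[k - 1L] * z[, k - 1L] +
        sqrt(1 - rho[k - 1L]^2) * stats::rnorm(n_hap)
    }
    a <- matrix(0L, n_hap, m_chr)
    a[z <= rep(thr, each = n_hap)] <- 1L
    haps[[chr]] <- a
    maps[[chr]] <- data.frame(
      marker = sprintf("Chr%02d_%d", chr, pos),
      chrom = as.character(chr), pos = pos, ref = "A", alt = "C",
      gpos = pos / config$chrom_length_bp * config$chrom_length_morgans,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  if (config$prop_chrom0 > 0) {
    relabel <- sample.int(nrow(map), round(config$prop_chrom0 * nrow(map)))
    map$chrom[relabel] <- "0"
  }
  structure(list(haplo = do.call(cbind, haps), map = map,
                 n_founders = config$n_founders, L = L, config = config),
            class = "haplotype_panel")
}

#' Simulate one meiosis
#'
#' Produces a gamete from a parent's pair of haplotypes. Crossovers per
#' chromosome are Poisson with rate equal to the chromosome's genetic length
#' in Morgans (no interference, Haldane model), crossover points uniform on
#' the genetic map. A zero-length chromosome transmits one randomly chosen
#' haplotype intact. Uses the current RNG state; seed with `set.seed()`.
#'
#' @param parent_haplotypes 2 x m binary matrix (the parent's haplotypes)
#' @param genetic_map data.frame with columns `chrom` and `gpos` (Morgans),
#'   positions non-decreasing within chromosome
#' @return length-m binary vector (the gamete)
#' @export
simulate_meiosis <- function(parent_haplotypes, genetic_map) {
  stopifnot(nrow(parent_haplotypes) == 2,
            ncol(parent_haplotypes) == nrow(genetic_map))
  gamete <- integer(ncol(parent_haplotypes))
  for (chr in unique(genetic_map$chrom)) {
    j <- which(genetic_map$chrom == chr)
    gp <- genetic_map$gpos[j]
    if (is.unsorted(gp)) stop("genetic map must be monotone within chromosome")
    len <- max(gp) - min(gp)
    start <- sample.int(2L, 1L)
    if (len <= 0) {
      gamete[j] <- parent_haplotypes[start, j]
      next
    }
    n_xo <- stats::rpois(1L, len)
    if (n_xo == 0) {
      gamete[j] <- parent_haplotypes[start, j]
      next
    }
    points <- sort(stats::runif(n_xo, min(gp), max(gp)))
    strand <- (start - 1L + findInterval(gp, points)) %% 2L + 1L
    gamete[j] <- parent_haplotypes[cbind(strand, j)]
  }
  gamete
}

# advance a haplotype generation by random crossing: returns 2*n_off x m
.random_cross <- function(haplo, n_off, gmap) {
  n_par <- nrow(haplo) / 2L
  out <- matrix(0L, 2L * n_off, ncol(haplo))
  for (i in seq_len(n_off)) {
    pair <- sample.int(n_par, 2L)
    out[2L * i - 1L, ] <- simulate_meiosis(haplo[c(2L * pair[1] - 1L, 2L * pair[1]), ], gmap)
    out[2L * i, ] <- simulate_meiosis(haplo[c(2L * pair[2] - 1L, 2L * pair[2]), ], gmap)
  }
  out
}

#' Build a cultivar collection plus F1 full-sib families
#'
#' Cultivars are the founder panel advanced two generations by random
#' crossing (a stand-in for the untracked pedigree of a breeding program);
#' each F1 family is the full-sib progeny of a designated pair of distinct
#' cultivars, with parental cultivars reusable across families as in real
#' crossing schemes.
#'
#' @param config the [sim_config()] used for the panel
#' @param panel a [simulate_founders()] result
#' @return list with `genotypes` (genotype_matrix of
#'   n_cultivars + sum(family_sizes) individuals), `families` (data.frame
#'   id/family; cultivars are labelled `"collection"`), `haplo` (phased
#'   haplotypes, 2n x m), and `parents` (family parental cultivar indices)
#' @export
build_population <- function(config, panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (any(config$family_sizes > config$family_size_range[2] |
          config$family_sizes < config$family_size_range[1])) {
    stop("family size outside configured bounds")
  }
  set.seed(config$seed + 1L)
  gmap <- panel$map[, c("chrom", "gpos")]
  gen1 <- .random_cross(panel$haplo, config$n_cultivars, gmap)
  cult <- .random_cross(gen1, config$n_cultivars, gmap)
  n_fam <- length(config$family_sizes)
  fam_parents <- matrix(0L, n_fam, 2L)
  fam_haplo <- vector("list", n_fam)
  for (k in seq_len(n_fam)) {
    pair <- sample.int(config$n_cultivars, 2L)
    fam_parents[k, ] <- pair
    nk <- config$family_sizes[k]
    hk <- matrix(0L, 2L * nk, ncol(cult))
    pa <- cult[c(2L * pair[1] - 1L, 2L * pair[1]), ]
    pb <- cult[c(2L * pair[2] - 1L, 2L * pair[2]), ]
    for (i in seq_len(nk)) {
      hk[2L * i - 1L, ] <- simulate_meiosis(pa, gmap)
      hk[2L * i, ] <- simulate_meiosis(pb, gmap)
    }
    fam_haplo[[k]] <- hk
  }
  haplo <- rbind(cult, do.call(rbind, fam_haplo))
  odd <- seq(1L, nrow(haplo), by = 2L)
  dosage <- haplo[odd, , drop = FALSE] + haplo[odd + 1L, , drop = FALSE]
  fam_label <- sprintf("F%02d", seq_len(n_fam))
  ids <- c(sprintf("C%03d", seq_len(config$n_cultivars)),
           unlist(lapply(seq_len(n_fam), function(k)
             sprintf("%s_%03d", fam_label[k], seq_len(config$family_sizes[k])))))
  family <- c(rep("collection", config$n_cultivars),
              rep(fam_label, config$family_sizes))
  rownames(dosage) <- ids
  g <- genotype_matrix(dosage, panel$map[, c("marker", "chrom", "pos", "ref", "alt")])
  list(genotypes = g,
       families = data.frame(id = ids, family = family, stringsAsFactors = FALSE),
       haplo = haplo,
       parents = fam_parents,
       gmap = panel$map[, c("chrom", "gpos")])
}

#' Declare a QTL
#'
#' @param chromosome chromosome index
#' @param position bp position; the nearest segregating marker is used
#' @param mode `"direct"` (additive effect on the trait) or `"conversion"`
#'   (effect on a sugar-conversion logit channel)
#' @param trait target trait name; for conversion QTLs, `"SUC"` targets the
#'   sucrose-to-hexose channel and `"GLC"`/`"FRU"` the hexose-split channel
#' @param target_pve fraction of the trait's phenotypic variance the QTL
#'   should explain (0 < pve < 1; 0 allowed for a null effect)
#' @param allele which allele carries the positive effect (`"alt"` or
#'   `"ref"`)
#' @return list of class `qtl_spec`
#' @export
qtl_spec <- function(chromosome, position, mode = c("direct", "conversion"),
                     trait, target_pve, allele = "alt") {
  mode <- match.arg(mode)
  if (target_pve < 0 || target_pve >= 1) stop("target_pve must be in [0, 1)")
  if (position < 1) stop("position must be >= 1")
  structure(list(chromosome = as.character(chromosome), position = position,
                 mode = mode, trait = trait, target_pve = target_pve,
                 allele = allele),
            class = "qtl_spec")
}

# nearest marker to the QTL position with MAF >= maf_min on its chromosome
.qtl_marker <- function(qtl, g, maf_min = 0.05) {
  j <- which(g$map$chrom == qtl$chromosome)
  if (!length(j)) stop("no markers on chromosome ", qtl$chromosome)
  maf <- marker_maf(g)[j]
  j <- j[maf >= maf_min]
  if (!length(j)) stop("no segregating marker near the QTL on chromosome ", qtl$chromosome)
  j[which.min(abs(g$map$pos[j] - qtl$position))]
}

#' Additive effect size for a target variance share
#'
#' Returns the per-dosage additive effect a = sqrt(target_pve * Var(y) /
#' Var(x)) so that the QTL explains `target_pve` of the phenotypic variance
#' in expectation. Variances are population variances (divisor n).
#'
#' @param qtl a [qtl_spec()]
#' @param genotypes genotype_matrix the QTL marker is drawn from
#' @param current_pheno_variance total phenotypic variance of the target
#'   trait
#' @return effect size (trait units per alt-allele copy); attribute `marker`
#'   holds the marker index used
#' @export
assign_qtl_effects <- function(qtl, genotypes, current_pheno_variance) {
  j <- .qtl_marker(qtl, genotypes)
  x <- genotypes$dosage[, j]
  vx <- mean((x - mean(x))^2)
  if (vx == 0) stop("QTL marker is monomorphic")
  a <- sqrt(qtl$target_pve * current_pheno_variance / vx)
  if (identical(qtl$allele, "ref")) a <- -a
  attr(a, "marker") <- j
  a
}

#' Sugar-trait generative model
#'
#' Parameters of the conversion-based trait model. Fruit sugars are generated
#' from four latent channels: total sugar T (mg/ml), an independent sorbitol
#' channel, a sucrose-to-hexose conversion fraction c in (0,1) on a logistic
#' scale, and a hexose fructose-vs-glucose split h in (0,1). Traits are
#' SUC = (T - SOR)(1 - c), FRU = (T - SOR) c h, GLC = (T - SOR) c (1 - h),
#' TSC = SUC + FRU + GLC + SOR (exact accounting identity). Noise is placed
#' in the channels, reproducing the strong negative SUC-GLC correlation of
#' conversion genetics; channel variances are solved at generation time from
#' the trait-level anchors below (delta method around the channel means).
#'
#' @param mean_tsc,mean_suc,mean_fru,mean_glc,mean_sor trait means, mg/ml
#' @param var_tsc,var_suc,var_sor trait phenotypic variances (mg/ml)^2;
#'   FRU and GLC variances follow from the channel solution
#' @param var_eta_h variance of the hexose-split logit channel used when no
#'   conversion QTL targets the split (otherwise the channel is sized from
#'   the QTL's target share)
#' @param var_glc target GLC phenotypic variance; calibrates the
#'   conversion-to-split coupling (higher conversion tilts hexose toward
#'   glucose), which also drives the negative SUC-GLC correlation
#' @param h_channel_h2 heritability of the hexose-split channel
#' @param h_qtl_share share of the split-channel variance carried by the
#'   conversion QTLs that target it
#' @param heritabilities named per-trait targets in (0, 1]; SUC, SOR and TSC
#'   are matched exactly by the channel solution, FRU and GLC emerge close to
#'   their targets
#' @param family_variance variance of family-specific deviations of total
#'   sugar (mg/ml)^2
#' @param conversion_qtls list of conversion-mode [qtl_spec()]s
#' @param direct_qtls list of direct-mode [qtl_spec()]s (non-sugar traits)
#' @param nonsugar list of mean/variance pairs for HarT, FruW, FruH, Aci and
#'   the SSC scaling (SSC = TSC / ssc_scale + noise)
#' @param n_polygenes markers drawn per polygenic channel (default 300)
#' @return list of class `sugar_trait_model`
#' @export
pear_trait_model <- function(mean_tsc = 130.7, mean_suc = 43.1, mean_fru = 40.6,
                             mean_glc = 14.9, mean_sor = 32.2,
                             var_tsc = 125.2, var_suc = 355.6, var_sor = 56.5,
                             var_eta_h = 0.08, var_glc = 64.3,
                             h_channel_h2 = 0.77, h_qtl_share = 0.80,
                             heritabilities = c(SUC = 0.64, FRU = 0.69,
                                                GLC = 0.71, SOR = 0.76,
                                                TSC = 0.33, HarT = 0.70,
                                                FruW = 0.60, FruH = 0.50,
                                                Aci = 0.60),
                             family_variance = 12.5,
                             conversion_qtls = list(
                               qtl_spec(7, 33139082, "conversion", "SUC", 0.235),
                               qtl_spec(11, 41197041, "conversion", "GLC", 0.217)),
                             direct_qtls = list(
                               qtl_spec(3, 31587739, "direct", "HarT", 0.165),
                               qtl_spec(15, 16568005, "direct", "HarT", 0.203),
                               qtl_spec(6, 20720912, "direct", "Aci", 0.131),
                               qtl_spec(16, 3043313, "direct", "Aci", 0.110)),
                             nonsugar = list(HarT = c(mean = 62, var = 324),
                                             FruW = c(mean = 394.2, var = 14400),
                                             FruH = c(mean = 4.8, var = 1.0),
                                             Aci = c(mean = 4.9, var = 0.1225),
                                             ssc_scale = 9.47,
                                             ssc_noise_var = 0.25),
                             n_polygenes = 300) {
  if (any(heritabilities <= 0 | heritabilities > 1)) {
    stop("heritabilities must be in (0, 1]")
  }
  structure(list(mean_tsc = mean_tsc, mean_suc = mean_suc, mean_fru = mean_fru,
                 mean_glc = mean_glc, mean_sor = mean_sor,
                 var_tsc = var_tsc, var_suc = var_suc, var_sor = var_sor,
                 var_eta_h = var_eta_h, var_glc = var_glc,
                 h_channel_h2 = h_channel_h2, h_qtl_share = h_qtl_share,
                 heritabilities = heritabilities,
                 family_variance = family_variance,
                 conversion_qtls = conversion_qtls, direct_qtls = direct_qtls,
                 nonsugar = nonsugar, n_polygenes = n_polygenes),
            class = "sugar_trait_model")
}

# ---- logistic-normal channel moments (Gauss-Hermite) -----------------------

.gh_env <- new.env(parent = emptyenv())

# probabilists' Gauss-Hermite nodes/weights (Golub-Welsch), standard normal
.gauss_hermite <- function(n = 40) {
  key <- paste0("gh", n)
  if (!is.null(.gh_env[[key]])) return(.gh_env[[key]])
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = e$values, weights = e$vectors[1, ]^2)
  .gh_env[[key]] <- res
  res
}

# E[f(eta)] for eta ~ N(mu, v), f vectorised
.gh_expect <- function(f, mu, v) {
  gh <- .gauss_hermite()
  sum(gh$weights * f(mu + sqrt(v) * gh$nodes))
}

# first two moments of plogis(eta) and cov(plogis(eta), eta)
.logistic_moments <- function(mu, v) {
  m1 <- .gh_expect(stats::plogis, mu, v)
  m2 <- .gh_expect(function(x) stats::plogis(x)^2, mu, v)
  w1 <- .gh_expect(function(x) stats::plogis(x) * (x - mu), mu, v)
  list(m1 = m1, m2 = m2, w1 = w1)
}

# mu such that E[plogis(N(mu, v))] = target
.solve_logit_mean <- function(target, v) {
  stats::uniroot(function(mu) .gh_expect(stats::plogis, mu, v) - target,
                 c(-12, 12), tol = 1e-10)$root
}

# joint moments of c = plogis(eta_c) and h = plogis(eta_h) where
# eta_c ~ N(mu_c, vc), eta_h = mu_h + own - kappa (eta_c - mu_c),
# own ~ N(0, vh) independent; 2-D Gauss-Hermite tensor grid
.split_moments <- function(mu_c, vc, mu_h, vh, kappa, n_nodes = 24) {
  gh <- .gauss_hermite(n_nodes)
  dev_c <- sqrt(vc) * gh$nodes
  cv <- stats::plogis(mu_c + dev_c)
  one_h <- 1 - stats::plogis(outer(-kappa * dev_c,
                                   sqrt(max(vh, 0)) * gh$nodes, "+") + mu_h)
  w2 <- outer(gh$weights, gh$weights)
  list(g1 = sum(w2 * (cv * one_h)),             # E[c (1-h)]
       g2 = sum(w2 * (cv^2 * one_h^2)),         # E[c^2 (1-h)^2]
       g3 = sum(w2 * ((1 - cv) * cv * one_h)),  # E[(1-c) c (1-h)]
       g4 = sum(w2 * (cv * (1 - one_h) * one_h)))  # E[c h (1-h)]
}

# polygenic value over a random marker subset, scaled to an exact population
# variance; returns a list(value, markers, effects)
.polygene <- function(g, target_var, n_poly, exclude = integer(0)) {
  n <- nrow(g$dosage)
  if (target_var <= 0) return(list(value = numeric(n), markers = integer(0)))
  poly_ok <- which(marker_maf(g) > 0)
  poly_ok <- setdiff(poly_ok, exclude)
  mk <- sample(poly_ok, min(n_poly, length(poly_ok)))
  b <- stats::rnorm(length(mk))
  u <- as.numeric(g$dosage[, mk, drop = FALSE] %*% b)
  u <- u - mean(u)
  vu <- mean(u^2)
  if (vu < 1e-12) return(list(value = numeric(n), markers = mk))
  list(value = u * sqrt(target_var / vu), markers = mk)
}

#' Simulate the ten fruit traits
#'
#' Generates phenotypes from the conversion-based model: channel variances
#' are solved from the model's trait anchors, QTL effects via
#' [assign_qtl_effects()], polygenic values over random marker subsets, and
#' family-specific deviations of total sugar for the F1 families. TSC is
#' computed as the exact sum SUC + FRU + GLC + SOR; SSC tracks TSC.
#'
#' @param model a [pear_trait_model()]
#' @param genotypes genotype_matrix without missing dosages
#' @param families character vector of family labels aligned to individuals
#'   (`"collection"` for cultivars) or a data.frame with columns id/family
#' @param seed integer seed
#' @return data.frame with `id` plus the ten traits; attributes
#'   `genetic_values` (individual x trait matrix of true genetic values,
#'   environmental channel noise zeroed), `qtl_markers` (marker indices used
#'   for each QTL) and `family_effects`
#' @export
simulate_sugar_phenotypes <- function(model, genotypes, families, seed = 1L) {
  stopifnot(inherits(model, "sugar_trait_model"))
  if (is.data.frame(families)) {
    families <- families$family[match(individual_ids(genotypes), families$id)]
  }
  n <- nrow(genotypes$dosage)
  stopifnot(length(families) == n)
  h2 <- model$heritabilities
  set.seed(seed)

  ## channel means and linearisation constants
  s_bar <- model$mean_tsc - model$mean_sor
  c_bar <- 1 - model$mean_suc / s_bar
  h_bar <- model$mean_fru / (model$mean_fru + model$mean_glc)
  d_c <- c_bar * (1 - c_bar)
  d_h <- h_bar * (1 - h_bar)

  ## linear channels: total sugar T (with family effects) and sorbitol
  vt <- model$var_tsc
  vt_g <- h2[["TSC"]] * vt
  fam_var <- min(model$family_variance, 0.9 * vt_g)
  vt_poly <- vt_g - fam_var
  vt_e <- vt - vt_g
  vs <- model$var_sor
  vs_g <- h2[["SOR"]] * vs
  vs_e <- vs - vs_g
  var_s <- vt + vs
  es2 <- var_s + s_bar^2                      # E[S^2], S = T - SOR

  ## conversion channel: exact logistic-normal moment matching of the SUC
  ## mean and variance (Gauss-Hermite), genetic share from the SUC
  ## heritability target
  suc_floor <- (1 - c_bar)^2 * var_s
  if (model$var_suc <= suc_floor) {
    stop("var_suc too small for the total-sugar variance: no conversion variance left")
  }
  var_suc_of <- function(v) {
    mu <- .solve_logit_mean(c_bar, v)
    m <- .logistic_moments(mu, v)
    es2 * (1 - 2 * m$m1 + m$m2) - (s_bar * (1 - m$m1))^2
  }
  vc <- stats::uniroot(function(v) var_suc_of(v) - model$var_suc,
                       c(1e-6, 20), tol = 1e-9, extendInt = "upX")$root
  mu_c <- .solve_logit_mean(c_bar, vc)
  mc <- .logistic_moments(mu_c, vc)
  share_c <- (h2[["SUC"]] * model$var_suc - (1 - c_bar)^2 * (vt_g + vs_g)) /
    (model$var_suc - suc_floor)
  if (share_c <= 0 || share_c > 1) stop("infeasible SUC heritability for the channel budgets")
  vc_g <- share_c * vc

  ## hexose-split channel and the conversion-to-split coupling kappa:
  ## higher conversion tilts hexose toward glucose; kappa is calibrated so
  ## the model's SUC-GLC correlation hits the declared target, and the own
  ## channel is sized so the split-targeting QTLs carry their declared share
  pve_h <- sum(vapply(model$conversion_qtls, function(q)
    if (q$trait %in% c("GLC", "FRU")) q$target_pve else 0, numeric(1)))
  dh_s2 <- (s_bar * c_bar * d_h)^2
  glc_stats <- function(kappa, vh) {
    mu_h <- stats::uniroot(function(m) {
      s_bar * .split_moments(mu_c, vc, m, vh, kappa)$g1 - model$mean_glc
    }, c(-12, 12), tol = 1e-9)$root
    g <- .split_moments(mu_c, vc, mu_h, vh, kappa)
    list(mu_h = mu_h, g4 = g$g4,
         var_glc = es2 * g$g2 - (s_bar * g$g1)^2,
         cov = es2 * g$g3 - s_bar^2 * (1 - mc$m1) * g$g1)
  }
  state_of <- function(kappa) {
    # own-channel variance sized so the split-targeting QTLs carry their
    # declared share; fixed point in vh (contraction, few iterations); the
    # effective (moment-based) derivative s_bar * g4 maps GLC variance to
    # the logit scale
    vh <- if (pve_h > 0) 0.05 else model$var_eta_h
    st <- glc_stats(kappa, vh)
    if (pve_h > 0) {
      for (it in 1:60) {
        vh_new <- pve_h * st$var_glc / (model$h_qtl_share * (s_bar * st$g4)^2)
        st <- glc_stats(kappa, vh_new)
        if (abs(vh_new - vh) < 1e-8 * (vh + 1e-8)) { vh <- vh_new; break }
        vh <- vh_new
      }
    }
    c(st, list(vh = vh))
  }
  kappa <- if (state_of(0)$var_glc >= model$var_glc) {
    0
  } else if (state_of(5)$var_glc <= model$var_glc) {
    warning("GLC variance target unreachable; using maximal conversion-split coupling")
    5
  } else {
    stats::uniroot(function(k) state_of(k)$var_glc - model$var_glc,
                   c(0, 5), tol = 1e-6)$root
  }
  st <- state_of(kappa)
  vh <- st$vh
  var_glc_model <- st$var_glc
  vh_g <- model$h_channel_h2 * vh
  mu_h <- st$mu_h
  # effective trait-per-logit derivatives under the fitted channel laws
  d_suc_eta <- s_bar * (mc$m1 - mc$m2)          # -dE[SUC]/d mu_c
  d_glc_eta <- s_bar * st$g4                    # -dE[GLC]/d mu_h

  ## conversion QTLs: channel effects via the trait-scale formula
  qtl_markers <- integer(0)
  beta_c <- numeric(0); mk_c <- integer(0)
  beta_h <- numeric(0); mk_h <- integer(0)
  qvar_c <- 0; qvar_h <- 0
  for (q in model$conversion_qtls) {
    if (q$trait == "SUC") {
      a <- assign_qtl_effects(q, genotypes, model$var_suc)
      j <- attr(a, "marker")
      # allele raising SUC lowers the conversion fraction
      beta_c <- c(beta_c, -as.numeric(a) / d_suc_eta)
      mk_c <- c(mk_c, j)
    } else {
      a <- assign_qtl_effects(q, genotypes, var_glc_model)
      j <- attr(a, "marker")
      # allele raising GLC lowers the fructose share of hexose
      beta_h <- c(beta_h, -as.numeric(a) / d_glc_eta)
      mk_h <- c(mk_h, j)
    }
    qtl_markers <- c(qtl_markers, j)
  }
  .qtl_channel_value <- function(mk, beta) {
    if (!length(mk)) return(numeric(n))
    x <- genotypes$dosage[, mk, drop = FALSE]
    as.numeric(scale(x, scale = FALSE) %*% beta)
  }
  qc <- .qtl_channel_value(mk_c, beta_c)
  qh <- .qtl_channel_value(mk_h, beta_h)
  qvar_c <- mean(qc^2) - mean(qc)^2
  qvar_h <- mean(qh^2) - mean(qh)^2
  if (qvar_c > vc_g) stop("conversion QTL variance exceeds the genetic budget of the conversion channel")
  vc_poly <- vc_g - qvar_c
  vc_e <- vc - vc_g
  vh_poly <- max(vh_g - qvar_h, 0)
  vh_e <- vh - max(vh_g, qvar_h)

  ## family effects on total sugar (collection = 0), exact variance
  fams <- setdiff(unique(families), "collection")
  f_eff <- stats::setNames(numeric(length(fams)), fams)
  if (length(fams) >= 2 && fam_var > 0) {
    f <- stats::rnorm(length(fams))
    f <- f - mean(f)
    f_eff[] <- f * sqrt(fam_var / mean(f^2))
  }
  fam_i <- ifelse(families == "collection", 0, f_eff[families])
  fam_i[is.na(fam_i)] <- 0

  ## channel components are orthogonalised in-sample against the QTL, family
  ## and previously drawn components and rescaled to their exact variance
  ## budgets: chance correlations between channels (through relatedness and
  ## LD) would otherwise blur the calibrated trait covariance structure
  basis <- cbind(1, qc, qh, fam_i)
  ortho <- function(v, target_var) {
    if (target_var <= 0) return(numeric(n))
    r <- stats::lm.fit(basis, v)$residuals
    vr <- mean((r - mean(r))^2)
    if (vr < 1e-12) return(numeric(n))
    r <- (r - mean(r)) * sqrt(target_var / vr)
    basis <<- cbind(basis, r)
    r
  }
  ## polygenes: random marker subsets per channel (QTL markers excluded);
  ## channels may share markers, the orthogonalisation keeps their scores
  ## separated
  pg <- function(v) {
    res <- .polygene(genotypes, v, model$n_polygenes, exclude = qtl_markers)
    ortho(res$value, v)
  }
  u_t <- pg(vt_poly)
  u_sor <- pg(vs_g)
  u_c <- pg(vc_poly)
  u_h <- pg(vh_poly)
  e_t <- ortho(stats::rnorm(n), max(vt_e, 0))
  e_sor <- ortho(stats::rnorm(n), max(vs_e, 0))
  e_c <- ortho(stats::rnorm(n), max(vc_e, 0))
  e_h <- ortho(stats::rnorm(n), max(vh_e, 0))

  ## assemble channels: genetic part + environmental channel noise
  t_g <- model$mean_tsc + u_t + fam_i
  sor_g <- model$mean_sor + u_sor
  eta_c_g <- mu_c + qc + u_c
  t_i <- t_g + e_t
  sor_i <- sor_g + e_sor
  eta_c <- eta_c_g + e_c
  # coupling: the conversion deviation (genetic and environmental alike)
  # tilts the hexose split toward glucose
  eta_h_g <- mu_h + qh + u_h - kappa * (eta_c_g - mu_c)
  eta_h <- mu_h + qh + u_h - kappa * (eta_c - mu_c) + e_h

  sugars <- function(t, sor, ec, eh) {
    s <- t - sor
    cc <- stats::plogis(ec)
    hh <- stats::plogis(eh)
    suc <- s * (1 - cc)
    fru <- s * cc * hh
    glc <- s * cc * (1 - hh)
    cbind(SUC = suc, FRU = fru, GLC = glc, SOR = sor,
          TSC = suc + fru + glc + sor)
  }
  ph_sugar <- sugars(t_i, sor_i, eta_c, eta_h)
  g_sugar <- sugars(t_g, sor_g, eta_c_g, eta_h_g)

  ## non-sugar traits: independent polygenic channels with optional QTLs
  ns <- model$nonsugar
  ph_ns <- matrix(0, n, 4, dimnames = list(NULL, c("HarT", "FruW", "FruH", "Aci")))
  g_ns <- ph_ns
  for (tr in colnames(ph_ns)) {
    mu <- ns[[tr]][["mean"]]; v <- ns[[tr]][["var"]]
    qv <- 0
    qval <- numeric(n)
    for (q in model$direct_qtls) {
      if (q$trait != tr) next
      a <- assign_qtl_effects(q, genotypes, v)
      j <- attr(a, "marker")
      x <- genotypes$dosage[, j]
      qval <- qval + as.numeric(a) * (x - mean(x))
      qtl_markers <- c(qtl_markers, j)
      qv <- qv + q$target_pve * v
    }
    poly_v <- h2[[tr]] * v - qv
    if (poly_v < 0) stop("QTL variance exceeds heritability budget for ", tr)
    u <- pg(poly_v)
    gval <- mu + qval + u
    g_ns[, tr] <- gval
    ph_ns[, tr] <- gval + ortho(stats::rnorm(n), (1 - h2[[tr]]) * v)
  }

  ssc <- ph_sugar[, "TSC"] / ns$ssc_scale + ortho(stats::rnorm(n), ns$ssc_noise_var)
  ssc_g <- g_sugar[, "TSC"] / ns$ssc_scale

  pheno <- data.frame(id = individual_ids(genotypes),
                      ph_sugar[, c("SUC", "FRU", "GLC", "SOR", "TSC")],
                      HarT = ph_ns[, "HarT"], FruW = ph_ns[, "FruW"],
                      FruH = ph_ns[, "FruH"], SSC = ssc, Aci = ph_ns[, "Aci"],
                      stringsAsFactors = FALSE)
  gv <- cbind(g_sugar[, c("SUC", "FRU", "GLC", "SOR", "TSC")],
              HarT = g_ns[, "HarT"], FruW = g_ns[, "FruW"],
              FruH = g_ns[, "FruH"], SSC = ssc_g, Aci = g_ns[, "Aci"])
  rownames(gv) <- pheno$id
  attr(pheno, "genetic_values") <- gv
  attr(pheno, "qtl_markers") <- unique(qtl_markers)
  attr(pheno, "family_effects") <- f_eff
  pheno
}

#' Harvest-day index
#'
#' Encodes a calendar date as the number of days after June 30 of the same
#' year (July 1 = day 1).
#'
#' @param calendar_date a `Date` or string `"YYYY-MM-DD"`
#' @return integer day index
#' @export
encode_harvest_day <- function(calendar_date) {
  d <- as.Date(calendar_date)
  if (anyNA(d)) stop("unparseable date")
  jun30 <- as.Date(paste0(format(d, "%Y"), "-06-30"))
  if (any(d <= jun30)) stop("harvest date must be after June 30")
  as.integer(d - jun30)
}

#' Simulate a complete pear-like study population
#'
#' Convenience wrapper: founder panel, cultivar collection plus F1 families,
#' and the ten fruit traits, all from one seed. The defaults reproduce the
#' study conditions the package is designed around: 106 cultivars, 18 F1
#' families of 28-121 individuals (1218 individuals total), 17 chromosomes,
#' about 3,500 markers with founder LD falling below r-squared 0.2 by 250 kb,
#' and large-effect sugar-conversion QTLs.
#'
#' @param config a [sim_config()]; the seed inside drives all genotype
#'   randomness
#' @param model a [pear_trait_model()]
#' @param pheno_seed seed for the phenotype draw (default `config$seed + 2`)
#' @return list with `genotypes`, `families` (data.frame), `phenotypes`,
#'   `panel`, `gmap` and `qtl_markers`
#' @export
sim_pear_population <- function(config = sim_config(),
                                model = pear_trait_model(),
                                pheno_seed = config$seed + 2L) {
  panel <- simulate_founders(config)
  pop <- build_population(config, panel)
  pheno <- simulate_sugar_phenotypes(model, pop$genotypes, pop$families,
                                     seed = pheno_seed)
  list(genotypes = pop$genotypes, families = pop$families, phenotypes = pheno,
       panel = panel, gmap = pop$gmap,
       qtl_markers = attr(pheno, "qtl_markers"),
       genetic_values = attr(pheno, "genetic_values"))
}
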