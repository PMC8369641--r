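test_that("simulation is bit-identical under a fixed seed and conserves dosage", {
  cfg <- small_config(7)
  p1 <- simulate_founders(cfg)
  p2 <- simulate_founders(cfg)
  expect_identical(p1$haplo, p2$haplo)
  expect_identical(p1$map, p2$map)
  pop1 <- build_population(cfg, p1)
  pop2 <- build_population(cfg, p2)
  expect_identical(pop1$genotypes$dosage, pop2$genotypes$dosage)
  ph1 <- simulate_sugar_phenotypes(small_model(), pop1$genotypes,
                                   pop1$families, seed = 9)
  ph2 <- simulate_sugar_phenotypes(small_model(), pop2$genotypes,
                                   pop2$families, seed = 9)
  expect_identical(ph1, ph2)
  # dosage = sum of the two inherited gametic alleles at every marker
  odd <- seq(1, nrow(pop1$haplo), by = 2)
  expect_identical(unname(pop1$genotypes$dosage),
                   pop1$haplo[odd, ] + pop1$haplo[odd + 1, ] + 0)
})

test_that("founders without copying correlation behave as independent loci", {
  cfg <- sim_config(n_founders = 50, n_cultivars = 10, family_sizes = c(30, 30),
                    n_chromosomes = 1, chrom_length_bp = 1e7,
                    n_markers_per_chrom = 200, ld_range_bp = 0, seed = 3)
  panel <- simulate_founders(cfg)
  h <- panel$haplo
  # disjoint marker pairs keep the r^2 values independent
  j1 <- seq(1, 199, by = 2); j2 <- j1 + 1
  r2 <- vapply(seq_along(j1),
               function(k) cor(h[, j1[k]], h[, j2[k]])^2, numeric(1))
  n_hap <- 2 * cfg$n_founders
  expected <- 1 / (n_hap - 1)                  # E[r^2] for independent loci
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - expected), 3 * se)
})

test_that("calibrated founder LD decays to about 0.2 by 250 kb", {
  cfg <- sim_config(n_founders = 200, n_cultivars = 10, family_sizes = c(30, 30),
                    n_chromosomes = 4, chrom_length_bp = 2e7,
                    n_markers_per_chrom = 220, ld_range_bp = 250000, seed = 5)
  panel <- simulate_founders(cfg)
  odd <- seq(1, nrow(panel$haplo), by = 2)
  g <- genotype_matrix(panel$haplo[odd, ] + panel$haplo[odd + 1, ],
                       panel$map[, c("marker", "chrom", "pos", "ref", "alt")])
  ld <- ld_decay(g, bin_bp = 10000, max_bp = 3e5)
  sel <- ld$bin_start %in% c(240000, 250000)
  mean_r2 <- sum(ld$mean_r2[sel] * ld$n_pairs[sel]) / sum(ld$n_pairs[sel])
  expect_gt(sum(ld$n_pairs[sel]), 50)
  expect_gte(mean_r2, 0.15)
  expect_lte(mean_r2, 0.25)
})

test_that("meiosis respects Mendelian segregation and the Haldane map", {
  gmap <- data.frame(chrom = "1", gpos = c(0, 0.5))
  # AA x aa: every offspring dosage 1
  pa <- rbind(c(1, 1), c(1, 1))
  pb <- rbind(c(0, 0), c(0, 0))
  set.seed(1)
  off <- replicate(50, simulate_meiosis(pa, gmap) + simulate_meiosis(pb, gmap))
  expect_true(all(off == 1))
  # Aa x Aa at one locus: 1:2:1
  gmap1 <- data.frame(chrom = "1", gpos = 0)
  het <- rbind(1, 0)
  set.seed(2)
  dos <- replicate(400, simulate_meiosis(het, gmap1) + simulate_meiosis(het, gmap1))
  counts <- tabulate(dos + 1, 3)
  expect_gt(chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.01)
  # two loci 0.5 M apart: recombinant fraction ~ Haldane c = (1 - e^-1)/2
  coupled <- rbind(c(1, 1), c(0, 0))
  set.seed(3)
  gam <- t(replicate(2000, simulate_meiosis(coupled, gmap)))
  rec <- mean(gam[, 1] != gam[, 2])
  c_true <- (1 - exp(-1)) / 2
  expect_lt(abs(rec - c_true), 3 * sqrt(c_true * (1 - c_true) / 2000))
  # zero-length chromosome: one haplotype transmitted intact
  gmap0 <- data.frame(chrom = "1", gpos = c(0.2, 0.2))
  set.seed(4)
  g0 <- replicate(20, simulate_meiosis(rbind(c(1, 0), c(0, 1)), gmap0))
  expect_true(all(colSums(g0) == 1))      # always one whole haplotype
})

test_that("build_population assembles the configured design", {
  cfg <- small_config(11)
  pop <- build_population(cfg, simulate_founders(cfg))
  expect_equal(nrow(pop$genotypes$dosage),
               cfg$n_cultivars + sum(cfg$family_sizes))
  expect_equal(as.vector(table(pop$families$family)[paste0("F0", 1:4)]),
               cfg$family_sizes)
  expect_equal(sum(pop$families$family == "collection"), cfg$n_cultivars)
  # both parents homozygous identical at a marker -> no variance in family
  cult_dos <- pop$genotypes$dosage[pop$families$family == "collection", ]
  par1 <- cult_dos[pop$parents[1, 1], ]
  par2 <- cult_dos[pop$parents[1, 2], ]
  j <- which(par1 == 0 & par2 == 0)[1]
  expect_false(is.na(j))
  fam_dos <- pop$genotypes$dosage[pop$families$family == "F01", j]
  expect_identical(unname(fam_dos), rep(0, length(fam_dos)))
  # family size bounds are enforced
  bad <- cfg
  bad$family_sizes <- c(200L, 60L, 70L, 70L)
  expect_error(build_population(bad, simulate_founders(cfg)), "bounds")
})

test_that("full sibs are more related than random cultivar pairs", {
  # wide founder base so that random cultivar pairs are near-unrelated
  cfg <- sim_config(n_founders = 200, n_cultivars = 50,
                    family_sizes = c(30, 30), n_chromosomes = 3,
                    chrom_length_bp = 3e7, n_markers_per_chrom = 80,
                    ld_range_bp = 250000, seed = 19)
  pop <- build_population(cfg, simulate_founders(cfg))
  K <- vanraden_kinship(pop$genotypes)
  fam <- pop$families$family
  sib_rows <- which(fam == "F02")
  cult_rows <- which(fam == "collection")
  set.seed(42)
  wins <- 0
  for (i in 1:100) {
    s <- sample(sib_rows, 2)
    u <- sample(cult_rows, 2)
    wins <- wins + (K[s[1], s[2]] > K[u[1], u[2]])
  }
  expect_gte(wins, 95)
})

test_that("assign_qtl_effects implements the variance-share formula", {
  g <- genotype_matrix(matrix(c(0, 1, 1, 2), ncol = 1),
                       data.frame(marker = "m1", chrom = "1", pos = 100,
                                  ref = "A", alt = "C"))
  q <- qtl_spec(1, 100, "direct", "SUC", 0.25)
  a <- assign_qtl_effects(q, g, current_pheno_variance = 100)
  expect_equal(as.numeric(a), sqrt(0.25 * 100 / 0.5))  # sqrt(50) ~ 7.071
  expect_equal(as.numeric(a), 7.0710678, tolerance = 1e-6)
  q0 <- qtl_spec(1, 100, "direct", "SUC", 0)
  expect_equal(as.numeric(assign_qtl_effects(q0, g, 100)), 0)
  gm <- genotype_matrix(matrix(c(2, 2, 2, 2), ncol = 1),
                        data.frame(marker = "m1", chrom = "1", pos = 100,
                                   ref = "A", alt = "C"))
  expect_error(assign_qtl_effects(q, gm, 100), "segregating|monomorphic")
})

test_that("simulated QTL effect recovers its target variance share", {
  pop <- pear_pop()
  g <- pop$genotypes
  y <- qtl_trait(g, qtl_index = 500, pve = 0.235, seed = 8)
  fit <- summary(lm(y ~ g$dosage[, 500]))
  expect_gte(fit$r.squared, 0.19)
  expect_lte(fit$r.squared, 0.28)
})

test_that("sugar phenotypes satisfy the accounting identity and correlation structure", {
  pop <- small_pop()
  ph <- pop$phenotypes
  expect_identical(ph$TSC, ph$SUC + ph$FRU + ph$GLC + ph$SOR)
  expect_lt(cor(ph$SUC, ph$GLC), -0.4)    # conversion signature at small n
  expect_gt(cor(ph$TSC, ph$SSC), 0.85)
  # with conversion QTLs removed, the conversion channel squeezed to nothing
  # and GLC driven by its own split channel, SUC and GLC decouple
  h2 <- pear_trait_model()$heritabilities
  h2[["SUC"]] <- 0.55
  m0 <- pear_trait_model(var_tsc = 0.5, var_sor = 0.5, var_suc = 0.21,
                         var_eta_h = 0.05, var_glc = 1,
                         heritabilities = h2, family_variance = 0.01,
                         conversion_qtls = list(),
                         direct_qtls = list(
                           qtl_spec(3, 5e6, "direct", "HarT", 0.165),
                           qtl_spec(1, 28e6, "direct", "Aci", 0.131)))
  ph0 <- simulate_sugar_phenotypes(m0, pop$genotypes, pop$families, seed = 4)
  expect_lt(abs(cor(ph0$SUC, ph0$GLC)), 0.1)
  expect_identical(ph0$TSC, ph0$SUC + ph0$FRU + ph0$GLC + ph0$SOR)
})

test_that("realized heritabilities track their targets across replicates", {
  pop <- small_pop()
  model <- small_model()
  targets <- model$heritabilities
  traits <- names(targets)
  h2 <- matrix(0, 30, length(traits), dimnames = list(NULL, traits))
  for (r in 1:30) {
    ph <- simulate_sugar_phenotypes(model, pop$genotypes, pop$families,
                                    seed = 1000 + r)
    gv <- attr(ph, "genetic_values")
    h2[r, ] <- vapply(traits, function(tr) cor(ph[[tr]], gv[, tr])^2, numeric(1))
  }
  realized <- colMeans(h2)
  expect_true(all(abs(realized - targets[traits]) <= 0.1),
              info = paste(round(realized, 2), collapse = " "))
})

test_that("family effects carry the configured variance", {
  pop <- small_pop()
  model <- small_model()
  ph <- simulate_sugar_phenotypes(model, pop$genotypes, pop$families, seed = 2)
  f <- attr(ph, "family_effects")
  expect_equal(mean((f - mean(f))^2), model$family_variance, tolerance = 1e-8)
})

test_that("heritability targets outside (0, 1] are rejected", {
  h2 <- c(SUC = 1.2, FRU = 0.69, GLC = 0.71, SOR = 0.76, TSC = 0.33,
          HarT = 0.7, FruW = 0.6, FruH = 0.5, Aci = 0.6)
  expect_error(pear_trait_model(heritabilities = h2), "heritabilities")
})

test_that("harvest days are encoded relative to June 30", {
  expect_identical(encode_harvest_day("2016-07-01"), 1L)
  expect_identical(encode_harvest_day("2016-07-23"), 23L)
  expect_identical(encode_harvest_day("2016-08-31"), 62L)
  expect_identical(encode_harvest_day("2016-10-23"), 115L)
  expect_error(encode_harvest_day("2016-06-30"), "after June 30")
  expect_error(encode_harvest_day("2016-05-01"), "after June 30")
})
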