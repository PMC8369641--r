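# shared fixtures; heavyweight objects are cached across test files
.fixture_env <- new.env(parent = emptyenv())

# small multi-family population (fast; ~300 individuals, 180 markers)
small_config <- function(seed = 101L) {
  sim_config(n_founders = 40, n_cultivars = 40,
             family_sizes = c(60, 60, 70, 70),
             n_chromosomes = 3, chrom_length_bp = 3e7,
             chrom_length_morgans = 1, n_markers_per_chrom = 60,
             ld_range_bp = 250000, family_size_range = c(28, 121),
             seed = seed)
}

# trait model with the QTLs remapped onto the 3-chromosome fixture genome
small_model <- function(...) {
  pear_trait_model(
    conversion_qtls = list(qtl_spec(1, 15e6, "conversion", "SUC", 0.235),
                           qtl_spec(2, 20e6, "conversion", "GLC", 0.217)),
    direct_qtls = list(qtl_spec(3, 5e6, "direct", "HarT", 0.165),
                       qtl_spec(3, 25e6, "direct", "HarT", 0.203),
                       qtl_spec(1, 28e6, "direct", "Aci", 0.131),
                       qtl_spec(2, 3e6, "direct", "Aci", 0.110)),
    ...)
}

small_pop <- function(seed = 101L) {
  key <- paste0("small", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- small_config(seed)
    panel <- simulate_founders(cfg)
    pop <- build_population(cfg, panel)
    pheno <- simulate_sugar_phenotypes(small_model(), pop$genotypes,
                                       pop$families, seed = cfg$seed + 2L)
    .fixture_env[[key]] <- list(genotypes = pop$genotypes,
                                families = pop$families, phenotypes = pheno,
                                panel = panel, parents = pop$parents,
                                qtl_markers = attr(pheno, "qtl_markers"),
                                genetic_values = attr(pheno, "genetic_values"))
  }
  .fixture_env[[key]]
}

# the default study-scale preset (1218 individuals, 3485 markers)
pear_pop <- function(seed = 101L) {
  key <- paste0("pear", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- sim_pear_population(sim_config(seed = seed))
  }
  .fixture_env[[key]]
}

# iid genotype matrix without LD or structure
iid_geno <- function(n, m, seed = 1, maf_range = c(0.1, 0.5), chrom = NULL) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  d <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  if (is.null(chrom)) chrom <- rep("1", m)
  genotype_matrix(d, data.frame(marker = sprintf("m%04d", seq_len(m)),
                                chrom = chrom,
                                pos = seq_len(m) * 1000L,
                                ref = "A", alt = "C"))
}

# phenotype with one focal QTL of a given PVE plus polygenic background
qtl_trait <- function(g, qtl_index, pve, h2 = 0.7, n_poly = 150, seed = 1) {
  set.seed(seed)
  n <- nrow(g$dosage)
  x <- g$dosage[, qtl_index]
  vx <- mean((x - mean(x))^2)
  a <- sqrt(pve / vx)
  if (h2 > pve) {
    poly_idx <- setdiff(sample(ncol(g$dosage)), qtl_index)[seq_len(n_poly)]
    u <- as.numeric(g$dosage[, poly_idx, drop = FALSE] %*% rnorm(n_poly))
    u <- u - mean(u)
    u <- u * sqrt((h2 - pve) / mean(u^2))
  } else {
    u <- numeric(n)
  }
  e <- rnorm(n, 0, sqrt(1 - h2))
  y <- a * (x - mean(x)) + u + e
  attr(y, "qtl_effect") <- a
  y
}

# markers in strong LD (r^2 >= r2_min) with a focal marker
tags_of <- function(g, j, r2_min = 0.8) {
  r2 <- suppressWarnings(as.numeric(cor(g$dosage[, j], g$dosage))^2)
  which(!is.na(r2) & r2 >= r2_min)
}
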