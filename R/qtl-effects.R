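#' Trait summaries per genotype class
#'
#' Count, mean and median of the trait within each dosage class (0, 1, 2),
#' over individuals with a non-missing phenotype. Absent classes carry
#' missing summaries.
#'
#' @param y trait values (missing allowed)
#' @param x dosages in {0, 1, 2}
#' @return data.frame with columns class, n, mean, median
#' @export
genotype_class_means <- function(y, x) {
  stopifnot(length(y) == length(x), all(x %in% 0:2))
  ok <- !is.na(y)
  out <- data.frame(class = 0:2, n = 0L, mean = NA_real_, median = NA_real_)
  for (k in 0:2) {
    sel <- ok & x == k
    out$n[k + 1L] <- sum(sel)
    if (any(sel)) {
      out$mean[k + 1L] <- mean(y[sel])
      out$median[k + 1L] <- stats::median(y[sel])
    }
  }
  out
}

#' Phenotypic variance explained by a SNP
#'
#' PVE = 100 * Var(x * effect) / Var(y) = 100 * effect^2 * Var(x) / Var(y),
#' with population variances (divisor n). Invariant to allele-label flips and
#' to rescaling y together with the effect.
#'
#' @param y trait values (missing dropped pairwise with x)
#' @param x dosages
#' @param effect additive per-dosage effect estimate
#' @return PVE in percent
#' @export
snp_pve <- function(y, x, effect) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  vy <- mean((y - mean(y))^2)
  if (vy == 0) stop("phenotype has zero variance")
  vx <- mean((x - mean(x))^2)
  100 * effect^2 * vx / vy
}

#' Per-family variance explained
#'
#' Recomputes each marker's PVE within each family, using the family's own
#' phenotypic variance and a within-family re-estimated (ordinary least
#' squares) effect. Cells where the marker does not segregate in the family,
#' or where any observed genotype class has fewer than `min_class_count`
#' members, are missing — mirroring the blank cells of a per-population PVE
#' heatmap.
#'
#' @param y trait values
#' @param g genotype_matrix
#' @param families family labels aligned to individuals (vector or data.frame
#'   id/family)
#' @param markers marker indices (or names) to summarise
#' @param min_class_count minimum individuals per observed genotype class
#'   (default 2)
#' @return matrix markers x families of PVE (%), `NA` where undefined; the
#'   last column `ALL` is the global PVE with the OLS effect re-estimated on
#'   everyone
#' @export
pve_per_family <- function(y, g, families, markers, min_class_count = 2) {
  if (is.data.frame(families)) {
    families <- families$family[match(individual_ids(g), families$id)]
  }
  if (is.character(markers)) markers <- match(markers, g$map$marker)
  fams <- c(sort(unique(families)), "ALL")
  out <- matrix(NA_real_, length(markers), length(fams),
                dimnames = list(g$map$marker[markers], fams))
  for (mi in seq_along(markers)) {
    x_all <- g$dosage[, markers[mi]]
    for (fi in seq_along(fams)) {
      sel <- if (fams[fi] == "ALL") rep(TRUE, length(y)) else families == fams[fi]
      sel <- sel & !is.na(y) & !is.na(x_all)
      x <- x_all[sel]; yy <- y[sel]
      if (length(x) < 3) next
      counts <- table(x)
      if (length(counts) < 2 || any(counts < min_class_count)) next
      if (mean((yy - mean(yy))^2) == 0) next
      eff <- stats::cov(yy, x) / stats::var(x)
      out[mi, fi] <- snp_pve(yy, x, eff)
    }
  }
  out
}

#' Long-format per-family PVE table
#'
#' Heatmap-ready reshaping of [pve_per_family()].
#'
#' @inheritParams pve_per_family
#' @return data.frame with columns marker, family, pve
#' @export
pve_per_family_long <- function(y, g, families, markers, min_class_count = 2) {
  m <- pve_per_family(y, g, families, markers, min_class_count)
  data.frame(marker = rep(rownames(m), ncol(m)),
             family = rep(colnames(m), each = nrow(m)),
             pve = as.vector(m), stringsAsFactors = FALSE)
}
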