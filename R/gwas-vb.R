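#' Hyperparameters for the vBayesB model
#'
#' Defaults follow standard BayesB practice: prior inclusion probability
#' pi = 10/m (about ten QTLs expected), prior degrees of freedom nu = 4.2,
#' and prior scale S2 set so that the prior mean of each SNP-effect variance
#' equals 0.5 Var(y) / (pi * sum_k 2 p_k (1 - p_k)), i.e. markers in the
#' model account for half the phenotypic variance a priori. `NULL` values are
#' resolved from the data inside [fit_vbayesb()].
#'
#' @param pi prior SNP inclusion probability in (0, 1), or `NULL` for 10/m
#' @param nu prior degrees of freedom of the scaled-inv-chi2 on the per-SNP
#'   effect variance (> 2 so the prior mean exists)
#' @param s2 prior scale, or `NULL` for the data-driven default
#' @param max_iter maximum coordinate-ascent sweeps (default 1000)
#' @param tol relative ELBO change declaring convergence (default 1e-6)
#' @param n_restarts number of restarts with shuffled update order; the fit
#'   with the best ELBO is kept (default 1: single deterministic genomic-order
#'   fit)
#' @param shuffle shuffle the update order each sweep (default FALSE)
#' @param seed seed for order shuffling and restarts
#' @return list of class `vb_hyper`
#' @export
vb_hyper <- function(pi = NULL, nu = 4.2, s2 = NULL, max_iter = 1000,
                     tol = 1e-6, n_restarts = 1, shuffle = FALSE, seed = 1L) {
  if (!is.null(pi) && (pi <= 0 || pi >= 1)) stop("pi must be in (0, 1)")
  if (nu <= 0) stop("nu must be > 0")
  if (!is.null(s2) && s2 <= 0) stop("s2 must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(pi = pi, nu = nu, s2 = s2, max_iter = as.integer(max_iter),
                 tol = tol, n_restarts = as.integer(n_restarts),
                 shuffle = shuffle, seed = as.integer(seed)),
            class = "vb_hyper")
}

#' Fit the variational BayesB multiple-QTL model
#'
#' All markers are fitted simultaneously: each SNP j carries an inclusion
#' indicator with prior probability pi (its posterior mean gamma_j is the
#' "SNP weight"), an effect with its own scaled-inv-chi2-distributed
#' variance, and each family (the cultivar collection counting as one class)
#' a shrunken progeny effect absorbing genetic-background differences.
#' Fitting is mean-field coordinate ascent; every update is an exact ascent
#' step, so the ELBO is non-decreasing (verified internally each sweep).
#'
#' @param y phenotype vector, no missing values
#' @param g genotype_matrix without missing dosages (columns are centered
#'   internally)
#' @param families family labels aligned to individuals (vector or
#'   data.frame id/family), or `NULL` for no progeny effects
#' @param hyper a [vb_hyper()]
#' @return list of class `vb_fit`: `mu`, `gamma`, `atilde`, `vtilde`,
#'   `sigma2_a`, `family_effects` (named), `sigma2_e`, `sigma2_f`, `elbo`
#'   (trace), `converged`, `n_iter`, plus the marker map and column centers
#'   needed for prediction
#' @export
fit_vbayesb <- function(y, g, families = NULL, hyper = vb_hyper()) {
  stopifnot(inherits(hyper, "vb_hyper"))
  if (anyNA(y)) stop("y must be complete; subset individuals first")
  if (anyNA(g$dosage)) stop("dosages must be complete; run impute_mode() first")
  n <- length(y)
  stopifnot(nrow(g$dosage) == n)
  m <- ncol(g$dosage)
  if (is.data.frame(families)) {
    families <- families$family[match(individual_ids(g), families$id)]
  }
  if (!is.null(families)) {
    stopifnot(length(families) == n)
    if (anyNA(families)) stop("every individual needs a family label")
    lev <- sort(unique(families))
    fam_idx <- match(families, lev) - 1L
    n_fam <- length(lev)
  } else {
    lev <- character(0)
    fam_idx <- integer(0)
    n_fam <- 0L
  }
  centers <- colMeans(g$dosage)
  X <- sweep(g$dosage, 2L, centers)
  pi <- if (is.null(hyper$pi)) min(10 / m, 0.5) else hyper$pi
  p <- centers / 2
  sum2pq <- sum(2 * p * (1 - p))
  vy <- mean((y - mean(y))^2)
  s2 <- if (is.null(hyper$s2)) {
    (hyper$nu - 2) / hyper$nu * 0.5 * vy / (pi * sum2pq)
  } else hyper$s2
  if (!is.finite(s2) || s2 <= 0) stop("prior scale s2 is not positive; supply s2 explicitly")

  # update order follows genomic coordinates, not storage order
  chrom_rank <- suppressWarnings(as.numeric(g$map$chrom))
  if (anyNA(chrom_rank)) chrom_rank <- rank(g$map$chrom, ties.method = "min")
  base_order <- order(chrom_rank, g$map$pos, g$map$marker) - 1L

  runs <- max(1L, hyper$n_restarts)
  best <- NULL
  for (rst in seq_len(runs)) {
    fit <- vb_cavi_cpp(y, X, fam_idx, n_fam, pi, hyper$nu, s2,
                       hyper$max_iter, hyper$tol,
                       shuffle = hyper$shuffle || rst > 1L,
                       seed = hyper$seed + rst - 1L,
                       base_order = base_order)
    if (is.null(best) || max(fit$elbo) > max(best$elbo)) best <- fit
  }
  fit <- best
  for (fld in c("gamma", "atilde", "vtilde", "sigma2_a")) fit[[fld]] <- drop(fit[[fld]])
  if (!fit$converged) {
    warning("vBayesB did not converge in ", hyper$max_iter,
            " sweeps; returning the best state reached")
  }
  names(fit$family_effects) <- lev
  fit$hyper <- list(pi = pi, nu = hyper$nu, s2 = s2, tol = hyper$tol,
                    max_iter = hyper$max_iter, seed = hyper$seed)
  fit$map <- g$map
  fit$centers <- centers
  fit$family_levels <- lev
  class(fit) <- "vb_fit"
  fit
}

#' @export
print.vb_fit <- function(x, ...) {
  cat(sprintf("vb_fit: %d markers, %d sweeps (%s), ELBO %.3f\n",
              length(x$gamma), x$n_iter,
              if (x$converged) "converged" else "not converged",
              max(x$elbo)))
  cat(sprintf("  markers with gamma >= 0.85: %d; sigma2_e = %.4g\n",
              sum(x$gamma >= 0.85), x$sigma2_e))
  invisible(x)
}

#' Markers passing the posterior-probability threshold
#'
#' @param fit a [fit_vbayesb()] result
#' @param threshold inclusion-probability cutoff; the comparison is inclusive
#'   (gamma >= threshold), default 0.85
#' @return integer marker indices sorted by chromosome then position
#' @export
significant_snps <- function(fit, threshold = 0.85) {
  idx <- which(fit$gamma >= threshold)
  chrom_rank <- suppressWarnings(as.numeric(fit$map$chrom[idx]))
  if (anyNA(chrom_rank)) chrom_rank <- rank(fit$map$chrom[idx], ties.method = "min")
  idx[order(chrom_rank, fit$map$pos[idx])]
}

#' Effect summary of the vBayesB fit
#'
#' Model-averaged effect b_j = gamma_j * atilde_j and its variance explained
#' for every marker passing the threshold.
#'
#' @param fit a [fit_vbayesb()] result
#' @param y phenotype the model was fitted to
#' @param g the genotype_matrix the model was fitted to
#' @param threshold inclusion-probability cutoff (default 0.85)
#' @return data.frame of class `gwas_result`: marker, chrom, pos, gamma,
#'   effect (posterior slab mean), b (model-averaged effect), pve (%)
#' @export
vb_effect_summary <- function(fit, y, g, threshold = 0.85) {
  idx <- significant_snps(fit, threshold)
  b <- fit$gamma[idx] * fit$atilde[idx]
  pve <- vapply(seq_along(idx), function(k) {
    snp_pve(y, g$dosage[, idx[k]], b[k])
  }, numeric(1))
  res <- data.frame(marker = fit$map$marker[idx], chrom = fit$map$chrom[idx],
                    pos = fit$map$pos[idx], gamma = fit$gamma[idx],
                    effect = fit$atilde[idx], b = b, pve = pve,
                    stringsAsFactors = FALSE)
  class(res) <- c("gwas_result", "data.frame")
  res
}
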