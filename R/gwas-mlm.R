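#' REML fit of the polygenic null model
#'
#' Fits y = X beta + u + e with u ~ N(0, sigma2_g K) and e ~ N(0, sigma2_e I)
#' by restricted maximum likelihood on the eigenbasis of K (spectral
#' transformation): the REML log-likelihood is profiled over
#' delta = sigma2_e / sigma2_g, scanned on a log grid over [1e-5, 1e5] and
#' refined by golden-section/parabolic search to 1e-8 tolerance.
#'
#' @param y phenotype vector; individuals with missing y must be dropped by
#'   the caller together with the matching rows of `covariates` and `K`
#' @param covariates numeric matrix of fixed-effect covariates (e.g. the
#'   first principal components) or `NULL`; an intercept is always added
#' @param K kinship matrix, positive semi-definite
#' @return list of class `mlm_null_fit`: `sigma2_g`, `sigma2_e`, `delta`,
#'   `beta`, `loglik` (REML), and the cached eigen-decomposition
#' @export
fit_null_mlm <- function(y, covariates = NULL, K) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (stats::var(y) == 0) stop("phenotype is constant")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  p <- ncol(X)
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- eK$values
  if (min(d) < -1e-6 * max(d)) stop("kinship matrix is not positive semi-definite")
  d <- pmax(d, 0)
  U <- eK$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  ldet_xtx <- determinant(crossprod(X), logarithm = TRUE)$modulus

  reml_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs, Xs * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, ys * w)))
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(d + delta)) +
              2 * sum(log(diag(ch))) - ldet_xtx)
  }

  grid <- seq(log(1e-5), log(1e5), length.out = 100)
  ll <- vapply(grid, reml_ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  ld <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  delta <- exp(ld)

  w <- 1 / (d + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  sigma2_g <- sum(w * r^2) / (n - p)
  structure(list(sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g,
                 delta = delta, beta = drop(beta), loglik = reml_ll(ld),
                 eigenvalues = d, U = U, X = X, Xs = Xs, ys = ys, n = n, p = p),
            class = "mlm_null_fit")
}

#' Single-marker mixed-model association scan
#'
#' Wald test of each marker's dosage coefficient in the generalized
#' least-squares regression under V = sigma2_g K + sigma2_e I held fixed at
#' the null REML estimates (the P3D approximation). Monomorphic markers get a
#' missing p-value. With `exact = TRUE` the variance components are
#' re-estimated per marker (slow; for validation).
#'
#' @param y phenotype vector
#' @param g genotype_matrix without missing dosages
#' @param covariates fixed covariates (or `NULL`), as in [fit_null_mlm()]
#' @param K kinship matrix
#' @param null_fit optional [fit_null_mlm()] result for the same y /
#'   covariates / K (computed when absent)
#' @param exact re-estimate variance components per marker (default FALSE)
#' @return data.frame of class `gwas_result`: marker, chrom, pos, effect
#'   (trait units per alt allele), se, wald, p, neg_log10_p, pve (%)
#' @export
mlm_scan <- function(y, g, covariates = NULL, K, null_fit = NULL, exact = FALSE) {
  if (is.null(null_fit)) null_fit <- fit_null_mlm(y, covariates, K)
  d <- null_fit$eigenvalues
  U <- null_fit$U
  w <- 1 / (null_fit$sigma2_g * d + null_fit$sigma2_e)
  Xs <- null_fit$Xs
  ys <- null_fit$ys
  M <- crossprod(U, g$dosage)                 # markers on the eigenbasis, n x m
  vx <- apply(g$dosage, 2L, function(x) mean((x - mean(x))^2))
  mono <- vx == 0
  XtWX <- crossprod(Xs, Xs * w)
  proj <- Xs %*% solve(XtWX, crossprod(Xs * w, M))
  Mt <- M - proj                              # marker residualized on covariates
  den <- colSums(w * Mt^2)
  num <- colSums((w * Mt) * drop(ys))
  b <- num / den
  se <- sqrt(1 / den)
  if (exact) {
    for (j in which(!mono)) {
      fx <- fit_null_mlm(y, cbind(covariates, g$dosage[, j]), K)
      bj <- fx$beta[length(fx$beta)]
      wj <- 1 / (fx$sigma2_g * fx$eigenvalues + fx$sigma2_e)
      XtWXj <- crossprod(fx$Xs, fx$Xs * wj)
      se[j] <- sqrt(solve(XtWXj)[fx$p, fx$p])
      b[j] <- bj
    }
  }
  wald <- (b / se)^2
  pval <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  b[mono] <- NA_real_; se[mono] <- NA_real_
  wald[mono] <- NA_real_; pval[mono] <- NA_real_
  if (any(mono)) {
    message(sum(mono), " monomorphic marker(s): p-value set to missing")
  }
  vy <- mean((y - mean(y))^2)
  res <- data.frame(marker = g$map$marker, chrom = g$map$chrom, pos = g$map$pos,
                    effect = b, se = se, wald = wald, p = pval,
                    neg_log10_p = -log10(pval),
                    pve = 100 * b^2 * vx / vy,
                    stringsAsFactors = FALSE)
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Benjamini-Hochberg significance calls
#'
#' Step-up procedure at level `q`; also returns the largest rejected p-value,
#' the height of the line drawn on Manhattan plots.
#'
#' @param pvalues vector of p-values in (0, 1]; `NA`s allowed (never
#'   rejected, not counted in m)
#' @param q FDR level (default 0.05)
#' @return list with `significant` (logical, same length), `threshold`
#'   (largest rejected p, or `NA` when nothing is rejected) and `n_rejected`
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  sig <- rep(FALSE, length(pvalues))
  ok <- which(!is.na(pvalues))
  if (!length(ok)) {
    return(list(significant = sig, threshold = NA_real_, n_rejected = 0L))
  }
  p <- pvalues[ok]
  m <- length(p)
  o <- order(p)
  below <- p[o] <= q * seq_len(m) / m
  if (!any(below)) {
    return(list(significant = sig, threshold = NA_real_, n_rejected = 0L))
  }
  kstar <- max(which(below))
  thr <- p[o][kstar]
  sig[ok] <- pvalues[ok] <= thr
  list(significant = sig, threshold = thr, n_rejected = sum(sig))
}
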