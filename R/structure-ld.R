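#' VanRaden genomic relationship matrix
#'
#' G = W W' / (2 * sum_k p_k (1 - p_k)) with W the dosage matrix centered by
#' twice the alt-allele frequency of each marker. Frequencies are observed
#' frequencies of the supplied individuals (the full analysed set).
#' Monomorphic markers contribute nothing and are skipped. A ridge of 1e-8 is
#' added to the diagonal so the result is numerically positive semi-definite.
#'
#' @param g genotype_matrix without missing dosages
#' @return symmetric n x n matrix with individual IDs as dimnames
#' @export
vanraden_kinship <- function(g) {
  d <- g$dosage
  if (anyNA(d)) stop("kinship needs complete dosages; run impute_mode() first")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("need >= 2 polymorphic markers for kinship")
  w <- sweep(d[, poly, drop = FALSE], 2L, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(w) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + 1e-8
  dimnames(G) <- list(individual_ids(g), individual_ids(g))
  G
}

#' Composite linkage disequilibrium between two markers
#'
#' Squared Pearson correlation of dosage vectors (phase-free composite LD),
#' invariant to swapping the reference and alternate allele labels at either
#' marker.
#'
#' @param x,y dosage vectors of equal length >= 3
#' @return r-squared in [0, 1], or `NA` when either vector has zero variance
#' @export
pairwise_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Linkage-disequilibrium decay table
#'
#' Mean r-squared of all intra-chromosomal marker pairs, binned by physical
#' distance. Markers on the fictive chromosome `"0"` (unassigned scaffolds)
#' are excluded. Bins are contiguous from 0; a pair at distance d falls in
#' bin `floor(d / bin_bp)`.
#'
#' @param g genotype_matrix without missing dosages
#' @param bin_bp bin width in bp (default 10 kb)
#' @param max_bp largest pair distance considered (default 2 Mb)
#' @return data.frame with columns `bin_start` (bp), `mean_r2`, `n_pairs`
#' @export
ld_decay <- function(g, bin_bp = 10000, max_bp = 2e6) {
  n_bins <- ceiling(max_bp / bin_bp)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (chr in setdiff(unique(g$map$chrom), "0")) {
    j <- which(g$map$chrom == chr)
    if (length(j) < 2) next
    pos <- g$map$pos[j]
    o <- order(pos)
    j <- j[o]; pos <- pos[o]
    d <- g$dosage[, j, drop = FALSE]
    sd0 <- apply(d, 2L, stats::sd) == 0
    cc <- suppressWarnings(stats::cor(d))
    r2 <- cc^2
    m <- length(j)
    dist <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dist)
    ok <- ut & dist <= max_bp & !outer(sd0, sd0, "|")
    b <- pmin(dist[ok] %/% bin_bp + 1L, n_bins)
    v <- r2[ok]
    good <- !is.na(v)
    tab_s <- tapply(v[good], b[good], sum)
    idx <- as.integer(names(tab_s))
    sums[idx] <- sums[idx] + tab_s
    tab_n <- tapply(v[good], b[good], length)
    counts[idx] <- counts[idx] + tab_n
  }
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_bp,
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = counts)
}

#' Greedy pairwise tag-SNP selection
#'
#' Haploview-style pairwise tagger: repeatedly pick the marker that covers
#' (r-squared >= `r2_min`, same chromosome, itself included) the largest
#' number of not-yet-covered markers, until every marker is covered. Ties are
#' broken toward the smaller chromosome label, then the smaller position.
#'
#' @param g genotype_matrix without missing dosages
#' @param r2_min minimum r-squared for a tag to represent a marker
#'   (default 0.8)
#' @return list with `tags` (marker indices into `g`, sorted) and `tagged_by`
#'   (integer vector mapping every marker to its covering tag's index)
#' @export
greedy_tag_snps <- function(g, r2_min = 0.8) {
  m <- ncol(g$dosage)
  tagged_by <- integer(m)
  tags <- integer(0)
  chrom_rank <- rank(suppressWarnings(as.numeric(g$map$chrom)), ties.method = "min")
  if (anyNA(chrom_rank)) chrom_rank <- rank(g$map$chrom, ties.method = "min")
  for (chr in unique(g$map$chrom)) {
    j <- which(g$map$chrom == chr)
    pos <- g$map$pos[j]
    pref <- order(pos)                   # tie-break: smaller position wins
    r2 <- suppressWarnings(stats::cor(g$dosage[, j, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 1
    covers <- r2 >= r2_min
    uncovered <- rep(TRUE, length(j))
    while (any(uncovered)) {
      gain <- colSums(covers & uncovered)
      gain_pref <- gain[pref]
      pick <- pref[which.max(gain_pref)]
      newly <- which(covers[, pick] & uncovered)
      tagged_by[j[newly]] <- j[pick]
      uncovered[newly] <- FALSE
      tags <- c(tags, j[pick])
    }
  }
  list(tags = sort(tags), tagged_by = tagged_by)
}

#' PLINK-style sliding-window LD pruning
#'
#' Windows of `window` markers advanced by `step` markers along each
#' chromosome (positions sorted); within a window, while any retained pair
#' has r-squared above `r2_max`, the later-positioned member of the worst
#' pair is dropped. Deterministic.
#'
#' @param g genotype_matrix without missing dosages
#' @param window window size in markers (default 50)
#' @param step window shift in markers (default 10)
#' @param r2_max maximum tolerated pairwise r-squared (default 0.1)
#' @return integer vector of retained marker indices (original order)
#' @export
ld_prune <- function(g, window = 50, step = 10, r2_max = 0.1) {
  keep <- rep(TRUE, ncol(g$dosage))
  for (chr in unique(g$map$chrom)) {
    j <- which(g$map$chrom == chr)
    j <- j[order(g$map$pos[j])]
    m <- length(j)
    start <- 1L
    repeat {
      end <- min(start + window - 1L, m)
      win <- j[start:end]
      win <- win[keep[win]]
      if (length(win) > 1) {
        r2 <- suppressWarnings(stats::cor(g$dosage[, win, drop = FALSE]))^2
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        repeat {
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          if (r2[worst[1], worst[2]] <= r2_max) break
          drop_local <- max(worst)       # later-positioned member
          keep[win[drop_local]] <- FALSE
          r2[drop_local, ] <- 0
          r2[, drop_local] <- 0
        }
      }
      if (end == m) break
      start <- start + step
    }
  }
  which(keep)
}

#' Principal component analysis of genotype dosages
#'
#' Markers are optionally LD-pruned, then column-centered (not scaled) and
#' decomposed by SVD. Variance proportions are eigenvalue shares of the total
#' dosage variance. Sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param g genotype_matrix without missing dosages
#' @param n_components number of components returned (default 3)
#' @param prune_first LD-prune markers before the PCA (default TRUE)
#' @param scale. also scale columns to unit variance (default FALSE, matching
#'   common PLINK usage)
#' @return list with `scores` (n x n_components), `proportion` (variance
#'   share per component) and `markers_used`
#' @export
genotype_pca <- function(g, n_components = 3, prune_first = TRUE, scale. = FALSE) {
  stopifnot(nrow(g$dosage) >= n_components + 1)
  j <- if (prune_first) ld_prune(g) else seq_len(ncol(g$dosage))
  d <- g$dosage[, j, drop = FALSE]
  keep <- apply(d, 2L, stats::sd) > 0
  d <- d[, keep, drop = FALSE]
  pc <- stats::prcomp(d, center = TRUE, scale. = scale.)
  if (n_components > sum(pc$sdev > 1e-12)) {
    stop("n_components exceeds the rank of the genotype matrix")
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    s <- sign(load[which.max(abs(load[, k])), k])
    if (s < 0) {
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- individual_ids(g)
  list(scores = scores,
       proportion = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
       markers_used = j[keep])
}
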