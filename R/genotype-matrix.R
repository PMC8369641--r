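#' Genotype matrix container
#'
#' Bundles an individuals x markers alt-allele dosage matrix (values 0, 1, 2
#' or `NA` for missing) with per-marker metadata. Dosage is always the count
#' of the alternate allele; every function in the package shares this coding.
#'
#' @param dosage numeric matrix, individuals in rows, markers in columns.
#'   Row names are individual IDs, column names marker IDs; both are
#'   generated when absent.
#' @param map data.frame with one row per marker and columns `marker`,
#'   `chrom` (character; `"0"` marks the fictive chromosome of unassigned
#'   scaffolds), `pos` (bp, 1-based), `ref`, `alt`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind%04d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- if (!is.null(map$marker)) as.character(map$marker) else
      sprintf("mrk%05d", seq_len(ncol(dosage)))
  }
  if (anyDuplicated(rownames(dosage))) {
    stop("duplicate individual IDs: ",
         paste(unique(rownames(dosage)[duplicated(rownames(dosage))]), collapse = ", "))
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("marker", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols)) stop("map lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(map) != ncol(dosage)) stop("map rows must match dosage columns")
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (any(map$pos < 1L, na.rm = TRUE)) stop("marker positions must be >= 1 (1-based, as in VCF)")
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%d chromosomes)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' `g[i, j]` keeps individuals `i` and markers `j` (any standard index type),
#' keeping dosage and marker metadata aligned.
#'
#' @param x genotype_matrix
#' @param i,j individual / marker indices
#' @param ... ignored
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$map$marker)
  d <- x$dosage[i, j, drop = FALSE]
  jj <- seq_len(ncol(x$dosage))
  names(jj) <- colnames(x$dosage)
  genotype_matrix(d, x$map[jj[colnames(d)], , drop = FALSE])
}

#' Individual IDs of a genotype matrix
#' @param g genotype_matrix
#' @return character vector
#' @export
individual_ids <- function(g) rownames(g$dosage)

#' Per-marker alternate-allele frequency
#'
#' Computed on non-missing calls only.
#'
#' @param g genotype_matrix
#' @return numeric vector, length = number of markers
#' @export
alt_freq <- function(g) colMeans(g$dosage, na.rm = TRUE) / 2

#' Per-marker minor-allele frequency
#' @param g genotype_matrix
#' @return numeric vector in [0, 0.5]
#' @export
marker_maf <- function(g) {
  p <- alt_freq(g)
  pmin(p, 1 - p)
}

#' Per-marker missing-call rate
#' @param g genotype_matrix
#' @return numeric vector in [0, 1]
#' @export
marker_missing_rate <- function(g) colMeans(is.na(g$dosage))
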