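#' Trait names handled by the package
#'
#' The ten fruit traits: sucrose, fructose, glucose and sorbitol contents and
#' their sum (mg/ml juice), harvest time (days after June 30), fruit weight
#' (g), fruit hardness (lb), soluble solids concentration (%) and acidity
#' (juice pH).
#'
#' @return character vector of trait names
#' @export
pear_traits <- function() {
  c("SUC", "FRU", "GLC", "SOR", "TSC", "HarT", "FruW", "FruH", "SSC", "Aci")
}

#' Read genotypes from a VCF file
#'
#' Parses biallelic records of a VCFv4.x file (plain or gzip) into alt-allele
#' dosages. Phased (`|`) and unphased (`/`) genotype separators are both
#' accepted; `./.`, `.|.` and `.` become missing. Multiallelic records
#' (ALT containing a comma) are skipped and counted. When `min_qual` is given
#' and the file carries numeric QUAL values, records below it are dropped;
#' files without QUAL (synthetic data) pass unfiltered.
#'
#' @param path VCF file path
#' @param min_qual optional minimum QUAL; default `NULL` (no filter)
#' @return genotype_matrix; attributes `n_multiallelic` and `n_qual_removed`
#'   carry the skipped-record counts
#' @export
read_vcf <- function(path, min_qual = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) stop("no records in VCF: ", path)
  fmt <- v@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF has records without a GT field")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  qual_rm <- rep(FALSE, nrow(fix))
  if (!is.null(min_qual)) {
    q <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    qual_rm <- !is.na(q) & q < min_qual
  }
  keep <- !multi & !qual_rm
  if (!any(keep)) stop("all VCF records removed by filters")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  gt <- sub(":.*$", "", gt)
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  lut <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2)
  idx <- match(gt, names(lut))
  dos[] <- lut[idx]
  known_missing <- gt %in% c("./.", ".|.", ".", NA) | is.na(gt)
  unparsed <- is.na(dos) & !known_missing
  if (any(unparsed)) stop("unparseable GT values, e.g. ", gt[which(unparsed)[1]])
  dos <- t(dos)
  rownames(dos) <- colnames(gt)
  fixk <- fix[keep, , drop = FALSE]
  id <- fixk[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0("Chr", fixk[noid, "CHROM"], "_", fixk[noid, "POS"])
  colnames(dos) <- id
  g <- genotype_matrix(dos, data.frame(
    marker = id, chrom = fixk[, "CHROM"], pos = as.integer(fixk[, "POS"]),
    ref = fixk[, "REF"], alt = fixk[, "ALT"], stringsAsFactors = FALSE))
  attr(g, "n_multiallelic") <- sum(multi)
  attr(g, "n_qual_removed") <- sum(qual_rm)
  g
}

#' Write genotypes as a minimal VCFv4.2 file
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT=GT columns with
#' unphased genotypes; missing dosages become `./.`.
#'
#' @param g genotype_matrix
#' @param path output path (plain text)
#' @return `path`, invisibly
#' @export
write_vcf <- function(g, path) {
  gtcode <- c("0/0", "0/1", "1/1")
  d <- t(g$dosage)                      # markers x individuals
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtcode[d[ok] + 1L]
  body <- paste(g$map$chrom, g$map$pos, g$map$marker, g$map$ref, g$map$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=pearGS",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", individual_ids(g)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Marker quality-control filter
#'
#' Keeps markers whose minor-allele frequency (computed on non-missing calls)
#' is at least `maf_min` and whose missing rate is at most `max_missing`.
#' A marker with exactly `max_missing` missing data is retained (strictly
#' greater rates are removed). Marker order is preserved.
#'
#' @param g genotype_matrix
#' @param maf_min minimum minor-allele frequency (default 0.01)
#' @param max_missing maximum missing-call rate (default 0.25)
#' @return filtered genotype_matrix; attributes `n_kept` / `n_removed`
#' @export
filter_markers <- function(g, maf_min = 0.01, max_missing = 0.25) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  keep <- marker_maf(g) >= maf_min & marker_missing_rate(g) <= max_missing
  keep[is.na(keep)] <- FALSE            # entirely-missing marker
  if (!any(keep)) warning("all markers removed by QC filters")
  out <- g[, which(keep)]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Mode imputation of missing genotype calls
#'
#' Replaces each missing call by the marker's most frequent dosage class,
#' breaking ties toward the smaller dosage. A deliberately simple stand-in
#' for haplotype-based imputation, adequate after QC has capped the missing
#' rate.
#'
#' @param g genotype_matrix
#' @return genotype_matrix without missing values; attribute
#'   `imputed_fraction` reports the fraction of calls filled in
#' @export
impute_mode <- function(g) {
  d <- g$dosage
  na_mat <- is.na(d)
  n_missing <- sum(na_mat)
  if (n_missing == 0) {
    attr(g, "imputed_fraction") <- 0
    return(g)
  }
  all_missing <- colSums(!na_mat) == 0
  if (any(all_missing)) {
    stop("markers entirely missing, cannot impute: ",
         paste(utils::head(g$map$marker[all_missing], 5), collapse = ", "))
  }
  cols <- which(colSums(na_mat) > 0)
  for (j in cols) {
    x <- d[, j]
    counts <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)
    mode_dos <- which.max(counts) - 1L   # which.max takes first max: tie -> smaller
    x[is.na(x)] <- mode_dos
    d[, j] <- x
  }
  out <- genotype_matrix(d, g$map)
  attr(out, "imputed_fraction") <- n_missing / length(d)
  out
}

#' Read a phenotype table
#'
#' Tab-separated file with a header row; first column holds individual IDs,
#' remaining columns one trait each. `NA` (or `na_token`) marks missing
#' values. Unknown trait names are rejected unless `allow_unknown = TRUE`.
#'
#' @param path TSV path
#' @param allow_unknown accept trait columns outside [pear_traits()]
#' @param na_token string representing missing values (default `"NA"`)
#' @return data.frame with column `id` plus one numeric column per trait
#' @export
read_phenotypes <- function(path, allow_unknown = FALSE, na_token = "NA") {
  ph <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = na_token,
                          colClasses = "character", check.names = FALSE)
  if (ncol(ph) < 2) stop("phenotype file needs an ID column plus >= 1 trait")
  names(ph)[1] <- "id"
  if (anyDuplicated(ph$id)) {
    stop("duplicate individual ID in phenotype file: ",
         paste(unique(ph$id[duplicated(ph$id)]), collapse = ", "))
  }
  traits <- names(ph)[-1]
  unknown <- setdiff(traits, pear_traits())
  if (length(unknown) && !allow_unknown) {
    stop("unknown trait column(s): ", paste(unknown, collapse = ", "),
         " (set allow_unknown = TRUE to accept)")
  }
  for (tr in traits) {
    raw <- ph[[tr]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(val)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' in trait %s", raw[which(bad)[1]], tr))
    }
    ph[[tr]] <- val
  }
  ph
}

#' Write a phenotype table as TSV
#' @param pheno data.frame with `id` column plus trait columns
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a family-membership table
#'
#' Tab-separated, header row, columns `id` and `family`; the cultivar
#' collection carries the family label `"collection"`.
#'
#' @param path TSV path
#' @return data.frame with columns `id`, `family`
#' @export
read_families <- function(path) {
  fam <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(fam) < 2) stop("family file needs columns id, family")
  names(fam)[1:2] <- c("id", "family")
  if (anyDuplicated(fam$id)) {
    stop("duplicate individual ID in family file: ",
         paste(unique(fam$id[duplicated(fam$id)]), collapse = ", "))
  }
  fam[, c("id", "family")]
}

#' Write a family-membership table as TSV
#' @param families data.frame with columns `id`, `family`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_families <- function(families, path) {
  utils::write.table(families, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a phenotype table to a genotype matrix
#'
#' Returns the trait values ordered as the genotyped individuals; individuals
#' genotyped but absent from the phenotype table get all-missing phenotypes.
#'
#' @param pheno data.frame from [read_phenotypes()]
#' @param g genotype_matrix
#' @return data.frame with one row per genotyped individual
#' @export
align_phenotypes <- function(pheno, g) {
  ids <- individual_ids(g)
  idx <- match(ids, pheno$id)
  out <- pheno[idx, , drop = FALSE]
  out$id <- ids
  rownames(out) <- NULL
  out
}
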