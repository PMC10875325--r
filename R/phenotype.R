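#' Reference-allele read fraction
#'
#' The heteroplasmy "phenotype": reads supporting the reference allele
#' divided by total reads at the site. Zero total reads (or a masked
#' observation) yields `NA` -- a missing measurement, not a frequency of
#' zero.
#'
#' @param ref_count reads supporting the reference allele.
#' @param total_count total reads at the site.
#' @return fraction in `[0, 1]`, or `NA` when `total_count` is 0 or missing.
#' @export
ref_allele_fraction <- function(ref_count, total_count) {
  if (any(ref_count > total_count, na.rm = TRUE))
    stop("ref_count exceeds total_count")
  if (any(ref_count < 0, na.rm = TRUE) || any(total_count < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  out <- ref_count / total_count
  out[is.na(total_count) | total_count == 0 | is.na(ref_count)] <- NA_real_
  out
}

#' Build the phenotype matrix from filtered mitochondrial variants
#'
#' One row per mitochondrial variant (keyed "contig:pos"), one column per
#' sample; entries are reference-allele fractions computed from the
#' post-filtering read counts. Total reads are `ref_count + alt_count` (the
#' reads informative about the two alleles).
#'
#' @param vt a filtered [variant_table()].
#' @return numeric matrix (variants x samples) with `NA` for missing
#'   observations.
#' @export
build_phenotype_matrix <- function(vt) {
  ids <- variant_ids(vt)
  if (anyDuplicated(ids)) stop("duplicate variant keys: ",
                               ids[duplicated(ids)][1])
  m <- ref_allele_fraction(vt$ref_count, vt$ref_count + vt$alt_count)
  dimnames(m) <- list(ids, vt$samples)
  m
}

#' Binarize a phenotype matrix
#'
#' Homoplasmic-style recoding of the continuous fractions: values strictly
#' below `low` become 0, values strictly above `high` become 1, and
#' intermediate (heteroplasmic) or missing values become `NA`, so only
#' near-fixed states enter the binary re-analysis.
#'
#' @param m continuous phenotype matrix from [build_phenotype_matrix()].
#' @param low,high thresholds (defaults 0.05 / 0.95; strict inequalities).
#' @return matrix of 0/1/`NA`.
#' @export
binarize <- function(m, low = 0.05, high = 0.95) {
  if (low >= high) stop("low must be < high")
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  out[!is.na(m) & m < low] <- 0
  out[!is.na(m) & m > high] <- 1
  out
}

#' Classify the heteroplasmy pattern of each variant
#'
#' Uses the binarization thresholds as the operational meaning of a
#' homoplasmic state (raw read ratios are never exactly 0 or 1 at finite
#' depth): a fraction below `low` is alt-homoplasmic, above `high`
#' ref-homoplasmic, in between heteroplasmic.
#'
#' * `exclusively_heteroplasmic_alt`: the alternative allele is observed
#'   (some fraction < `high`) but never homoplasmic (no fraction < `low`).
#' * `homoplasmic_both_alleles`: both alleles reach homoplasmic levels in at
#'   least one sample each.
#' * `monomorphic`: everything else (e.g. all samples ref-homoplasmic, or
#'   alt observed only where ref never is).
#'
#' @param m continuous phenotype matrix.
#' @param low,high thresholds as in [binarize()].
#' @return character vector of labels, one per variant (row).
#' @export
classify_heteroplasmy <- function(m, low = 0.05, high = 0.95) {
  apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return("monomorphic")
    alt_hom <- any(x < low)
    ref_hom <- any(x > high)
    alt_seen <- any(x < high)
    if (alt_hom && ref_hom) "homoplasmic_both_alleles"
    else if (!alt_hom && alt_seen) "exclusively_heteroplasmic_alt"
    else "monomorphic"
  })
}

#' Write / read a phenotype matrix as TSV
#'
#' Layout: first column `sample`, then one column per variant key
#' ("contig:pos"); missing entries are written as `NA`. The transposed
#' layout (variants in rows) is also accepted on read and detected from the
#' header.
#'
#' @param m phenotype matrix (variants x samples).
#' @param path TSV file.
#' @return `path` (write) or the matrix in variants x samples orientation
#'   (read).
#' @export
write_phenotype_tsv <- function(m, path) {
  df <- data.frame(sample = colnames(m), t(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  first <- names(df)[1]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (identical(first, "sample") || !grepl(":", first) &&
      all(grepl(":", colnames(m)))) m <- t(m)
  storage.mode(m) <- "double"
  m
}
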