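#' Per-site, per-sample variant table
#'
#' The central container for variant calls from one genome (mitochondrial or
#' nuclear): site metadata plus aligned per-sample read-count and genotype
#' matrices. Reference/alternative read counts come from the VCF `AD` field,
#' total depth from `DP`. Missing observations are `NA`, never zero: a zero
#' would fabricate a measured allele frequency.
#'
#' @param contig character vector of contig names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref reference allele per site.
#' @param alt alternative allele(s) per site; multi-allelic sites are a single
#'   comma-separated string and are flagged, not dropped (the biallelic filter
#'   removes them later so filter counts stay auditable).
#' @param ref_count,alt_count,total_depth integer matrices, sites x samples.
#'   `alt_count` is the summed depth over all alternative alleles.
#' @param gt character matrix of genotype calls (`NA` = missing).
#' @param samples sample names, in file order.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(contig, pos, ref, alt,
                          ref_count, alt_count, total_depth,
                          gt, samples) {
  n <- length(pos)
  ref_count <- as.matrix(ref_count); alt_count <- as.matrix(alt_count)
  total_depth <- as.matrix(total_depth); gt <- as.matrix(gt)
  stopifnot(length(contig) == n, length(ref) == n, length(alt) == n,
            nrow(ref_count) == n, nrow(alt_count) == n,
            nrow(total_depth) == n, nrow(gt) == n,
            ncol(ref_count) == length(samples),
            ncol(alt_count) == length(samples),
            ncol(total_depth) == length(samples),
            ncol(gt) == length(samples))
  if (any(pos < 1)) stop("positions must be >= 1")
  alt <- as.character(alt)
  if (any(ref == alt)) stop("ref allele equals alt allele at some site")
  bad <- which(ref_count + alt_count > total_depth)
  if (length(bad) > 0)
    stop("ref_count + alt_count exceeds total_depth at ",
         length(bad), " observation(s)")
  rn <- if (n == 0) character(0) else paste0(contig, ":", pos)
  dimnames(ref_count) <- dimnames(alt_count) <-
    dimnames(total_depth) <- dimnames(gt) <- list(rn, samples)
  structure(list(
    sites = data.frame(contig = as.character(contig), pos = as.integer(pos),
                       ref = as.character(ref), alt = alt,
                       multiallelic = grepl(",", alt),
                       stringsAsFactors = FALSE),
    ref_count = ref_count, alt_count = alt_count,
    total_depth = total_depth, gt = gt,
    samples = as.character(samples)
  ), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x", length(x$samples),
      "samples on contig(s)", paste(unique(x$sites$contig), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param vt a `variant_table`.
#' @return integer count.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' @rdname n_sites
#' @export
n_samples <- function(vt) length(vt$samples)

#' Variant identifiers ("contig:pos")
#' @param vt a `variant_table`.
#' @return character vector of site keys.
#' @export
variant_ids <- function(vt) paste0(vt$sites$contig, ":", vt$sites$pos)

#' Subset a variant table by site index
#' @param vt a `variant_table`.
#' @param idx logical or integer site index.
#' @return a `variant_table` with the selected sites, sample order unchanged.
#' @export
subset_sites <- function(vt, idx) {
  variant_table(vt$sites$contig[idx], vt$sites$pos[idx],
                vt$sites$ref[idx], vt$sites$alt[idx],
                vt$ref_count[idx, , drop = FALSE],
                vt$alt_count[idx, , drop = FALSE],
                vt$total_depth[idx, , drop = FALSE],
                vt$gt[idx, , drop = FALSE], vt$samples)
}

#' Convert genotype calls to alt-allele dosages
#'
#' Diploid genotypes are coded by alternative-allele count 0/1/2; haploid
#' calls code 0/1. Missing calls stay `NA`.
#'
#' @param vt a `variant_table`.
#' @return list with `genotypes` (samples x sites dosage matrix) and `info`
#'   (site data.frame), the layout the association engine consumes.
#' @export
as_dosage <- function(vt) {
  g <- vt$gt
  alleles <- gsub("[|/]", "", g)
  dos <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  ok <- !is.na(alleles) & !grepl("\\.", g)
  dos[ok] <- vapply(strsplit(alleles[ok], ""), function(a)
    sum(a != "0"), numeric(1))
  list(genotypes = t(dos), info = vt$sites)
}
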