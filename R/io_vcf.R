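#' Read a VCF with per-sample allele depths into a variant table
#'
#' Wraps [vcfR::read.vcfR()] and extracts the `GT`, `AD` and `DP` FORMAT
#' fields. `ref_count` is the first `AD` value, `alt_count` the sum of the
#' remaining values (multi-allelic sites are retained and flagged). A sample
#' with missing `AD` gets missing counts at that site.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return a [variant_table()].
#' @export
read_vcf <- function(path) {
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(x)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- x@gt[, "FORMAT"]
  miss <- !grepl("(^|:)AD(:|$)", fmt) | !grepl("(^|:)DP(:|$)", fmt)
  if (any(miss)) {
    i <- which(miss)[1]
    stop("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
         " lacks AD and/or DP in FORMAT")
  }
  ad <- vcfR::extract.gt(x, "AD")
  dp <- suppressWarnings(vcfR::extract.gt(x, "DP", as.numeric = TRUE))
  gt <- vcfR::extract.gt(x, "GT")
  if (is.null(dim(ad))) { # single site
    ad <- matrix(ad, nrow = 1); dp <- matrix(dp, nrow = 1)
    gt <- matrix(gt, nrow = 1)
  }
  parse_ad <- function(s, k) {
    if (is.na(s) || s == ".") return(NA_integer_)
    v <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
    if (k == 1L) v[1] else sum(v[-1], na.rm = TRUE)
  }
  rc <- matrix(vapply(ad, parse_ad, integer(1), k = 1L), nrow(ad), ncol(ad))
  ac <- matrix(vapply(ad, parse_ad, integer(1), k = 2L), nrow(ad), ncol(ad))
  dp <- matrix(as.integer(dp), nrow(rc), ncol(rc))
  # DP may be absent for a no-call sample even when FORMAT declares it
  dp[is.na(rc)] <- dp[is.na(rc)]
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                fix[, "REF"], fix[, "ALT"],
                rc, ac, dp, gt,
                colnames(x@gt)[-1])
}

#' Write a variant table as VCF 4.2
#'
#' Emits `GT:AD:DP` per sample. Multi-allelic alt depths collapse to the
#' summed alternative count (the table does not keep the per-allele split),
#' so the writer is exactly lossless on biallelic tables.
#'
#' @param vt a [variant_table()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mitolink",
           paste0("##contig=<ID=", unique(vt$sites$contig), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$samples), collapse = "\t"))
  n <- n_sites(vt)
  fld <- function(i, j) {
    g <- vt$gt[i, j]; rc <- vt$ref_count[i, j]; ac <- vt$alt_count[i, j]
    dp <- vt$total_depth[i, j]
    paste0(ifelse(is.na(g), ".", g), ":",
           ifelse(is.na(rc), ".", paste0(rc, ",", ac)), ":",
           ifelse(is.na(dp), ".", dp))
  }
  rows <- vapply(seq_len(n), function(i) {
    paste(c(vt$sites$contig[i], vt$sites$pos[i], ".", vt$sites$ref[i],
            vt$sites$alt[i], ".", "PASS", ".", "GT:AD:DP",
            vapply(seq_along(vt$samples), function(j) fld(i, j),
                   character(1))),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
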