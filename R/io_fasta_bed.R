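#' Read / write FASTA sequences
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain upper-case character
#' vectors keyed by contig name (first whitespace token).
#'
#' @param path FASTA file (wrapped or single-line).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(s))
  if (anyDuplicated(nm)) stop("duplicate contig names in FASTA: ",
                              nm[duplicated(nm)][1])
  setNames(toupper(as.character(s)), nm)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Region masks (genomic intervals to exclude)
#'
#' A normalized set of labelled intervals. Intervals are kept 1-based
#' inclusive (the GRanges convention) and are sorted and merged within each
#' (contig, label) pair; the 0-based half-open BED convention is confined to
#' [read_bed()] / [write_bed()].
#'
#' @param contig,start,end parallel vectors; `start`/`end` 1-based inclusive.
#' @param label mask label, e.g. `"self_repeat"`, `"cross_homology"`,
#'   `"user"`.
#' @return object of class `region_mask` (data.frame with columns
#'   `contig, start, end, label`).
#' @export
region_mask <- function(contig = character(), start = integer(),
                        end = integer(), label = character()) {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (length(label) == 1) label <- rep(label, length(contig))
  df <- data.frame(contig = as.character(contig), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(df$start > df$end)) stop("mask interval start > end")
  out <- df[0, ]
  for (key in unique(paste(df$contig, df$label, sep = "\r"))) {
    sub <- df[paste(df$contig, df$label, sep = "\r") == key, ]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
    out <- rbind(out, data.frame(contig = sub$contig[1],
                                 start = IRanges::start(ir),
                                 end = IRanges::end(ir),
                                 label = sub$label[1],
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$contig, out$start, out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_mask", "data.frame")
  out
}

#' Combine region masks
#' @param ... `region_mask` objects.
#' @return a normalized `region_mask` with all intervals.
#' @export
combine_masks <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) nrow(p) > 0, logical(1))]
  if (length(parts) == 0) return(region_mask())
  df <- do.call(rbind, lapply(parts, as.data.frame))
  region_mask(df$contig, df$start, df$end, df$label)
}

#' Which positions fall inside a mask?
#' @param mask a `region_mask`.
#' @param contig,pos parallel vectors of 1-based positions.
#' @return character vector: the label of the first covering interval, or
#'   `NA` when uncovered.
#' @export
mask_label_at <- function(mask, contig, pos) {
  out <- rep(NA_character_, length(pos))
  if (nrow(mask) == 0) return(out)
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(mask$contig, IRanges::IRanges(mask$start,
                                                            mask$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  first <- !duplicated(S4Vectors::queryHits(hits))
  out[S4Vectors::queryHits(hits)[first]] <-
    mask$label[S4Vectors::subjectHits(hits)[first]]
  out
}

#' Read / write masks as BED
#'
#' BED is 0-based half-open; `chrM 10 20` covers 1-based positions 11..20.
#' Conversion is delegated to [rtracklayer::import()] / `export()`. The BED
#' `name` column carries the mask label.
#'
#' @param path BED file.
#' @return a [region_mask()].
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  lab <- S4Vectors::mcols(gr)$name
  if (is.null(lab)) lab <- rep("user", length(gr))
  lab[is.na(lab)] <- "user"
  region_mask(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr), GenomicRanges::end(gr), lab)
}

#' @rdname read_bed
#' @param mask a [region_mask()].
#' @export
write_bed <- function(mask, path) {
  gr <- GenomicRanges::GRanges(mask$contig,
                               IRanges::IRanges(mask$start, mask$end),
                               name = mask$label)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
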