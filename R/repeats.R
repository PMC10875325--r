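.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1), k:n)
}

.revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

#' Find exact repeated tracts within a genome
#'
#' Marks every position covered by an exact repeated tract of length >=
#' `min_len`, on either strand. Detection is by k-mer identity with
#' `k = min_len`: a position lies in a repeat of length >= `min_len` exactly
#' when some window of length `min_len` covering it occurs elsewhere in the
#' genome (forward or reverse-complement), so the union of duplicated
#' windows is precisely the union of all maximal repeats of that length.
#' This is an exact-match detector; the criterion is a length threshold, and
#' a user-supplied BED mask can augment it where scored (mismatch-tolerant)
#' homology is wanted.
#'
#' @param seqs named character vector of contig sequences (e.g. from
#'   [read_fasta()]).
#' @param min_len minimum repeat length in bp (default 100). Values below 20
#'   are rejected as a guard against masking everything.
#' @return a [region_mask()] with label `self_repeat`.
#' @export
find_self_repeats <- function(seqs, min_len = 100) {
  if (min_len < 20) stop("min_len < 20 would mask near-everything")
  k <- as.integer(min_len)
  contig <- rep(names(seqs), pmax(0L, nchar(seqs) - k + 1L))
  start <- unlist(lapply(nchar(seqs), function(n)
    if (n >= k) seq_len(n - k + 1L) else integer()), use.names = FALSE)
  fwd <- unlist(lapply(seqs, .kmers, k = k), use.names = FALSE)
  if (length(fwd) == 0) return(region_mask())
  cnt <- table(fwd)
  dup <- cnt[fwd] >= 2
  # window i's reverse complement as a forward-coordinate k-mer
  rc_of_fwd <- unlist(lapply(seqs, function(s) rev(.kmers(.revcomp(s), k))),
                      use.names = FALSE)
  n_rc_match <- cnt[rc_of_fwd]
  n_rc_match[is.na(n_rc_match)] <- 0
  palindrome <- rc_of_fwd == fwd
  rc_hit <- ifelse(palindrome, n_rc_match >= 2, n_rc_match >= 1)
  masked <- dup | rc_hit
  if (!any(masked)) return(region_mask())
  region_mask(contig[masked], start[masked], start[masked] + k - 1L,
              "self_repeat")
}

#' Find exact cross-genome homology tracts
#'
#' Reports mitochondrial-coordinate intervals covered by an exact shared
#' tract of length >= `min_len` with another genome (nuclear or plastid),
#' on either strand. Same windowed exact-match semantics as
#' [find_self_repeats()].
#'
#' @param mito_seqs named character vector (mitochondrial contigs).
#' @param other_seqs named character vector (the other genome); empty input
#'   yields an empty mask.
#' @param min_len minimum shared-tract length (default 100).
#' @param label mask label (default `cross_homology`).
#' @return a [region_mask()] in mito coordinates.
#' @export
find_cross_homology <- function(mito_seqs, other_seqs, min_len = 100,
                                label = "cross_homology") {
  if (min_len < 20) stop("min_len < 20 would mask near-everything")
  k <- as.integer(min_len)
  if (length(other_seqs) == 0 || all(nchar(other_seqs) < k))
    return(region_mask())
  contig <- rep(names(mito_seqs), pmax(0L, nchar(mito_seqs) - k + 1L))
  start <- unlist(lapply(nchar(mito_seqs), function(n)
    if (n >= k) seq_len(n - k + 1L) else integer()), use.names = FALSE)
  fwd <- unlist(lapply(mito_seqs, .kmers, k = k), use.names = FALSE)
  if (length(fwd) == 0) return(region_mask())
  other <- unique(c(
    unlist(lapply(other_seqs, .kmers, k = k), use.names = FALSE),
    unlist(lapply(other_seqs, function(s) .kmers(.revcomp(s), k)),
           use.names = FALSE)))
  masked <- fwd %in% other
  if (!any(masked)) return(region_mask())
  region_mask(contig[masked], start[masked], start[masked] + k - 1L, label)
}
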