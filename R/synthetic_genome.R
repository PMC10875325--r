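.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.substr_set <- function(seq, start, replacement) {
  paste0(substr(seq, 1, start - 1), replacement,
         substr(seq, start + nchar(replacement), nchar(seq)))
}

.mismatch_base <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]

#' Simulate a mitochondrial genome with planted repeats and a numt
#'
#' Generates a random mitochondrial contig plus a nuclear decoy contig.
#' Planted repeats are exact duplicate tracts inside the mitochondrial
#' genome; the numt is a mitochondrial tract copied into the decoy. The
#' bases flanking each copy are forced to mismatch the source's flanks so
#' every planted tract is maximal by construction, and the returned truth
#' mask covers each planted copy exactly.
#'
#' @param length mitochondrial genome length (bp).
#' @param planted_repeats list of `c(src_start, dest_start, len)` (1-based,
#'   `len >= 1`); the tract at `src_start` is copied to `dest_start`.
#' @param planted_numt `c(mito_start, len)` or `NULL`; tract copied into the
#'   middle of the nuclear decoy.
#' @param nuclear_length length of the decoy nuclear contig.
#' @param seed integer seed.
#' @return list with `mito` and `nuclear` (named sequences suitable for
#'   [write_fasta()]) and `truth` (a [region_mask()] in mito coordinates,
#'   labels `self_repeat` / `cross_homology`).
#' @export
simulate_mito_genome <- function(length, planted_repeats = list(),
                                 planted_numt = NULL,
                                 nuclear_length = 2L * length, seed = 1) {
  set.seed(seed)
  tracts <- list()
  for (r in planted_repeats) {
    stopifnot(length(r) == 3, r[1] >= 2, r[2] >= 2,
              r[1] + r[3] <= length, r[2] + r[3] <= length)
    tracts <- c(tracts, list(c(r[1], r[1] + r[3] - 1)),
                list(c(r[2], r[2] + r[3] - 1)))
  }
  if (!is.null(planted_numt)) {
    stopifnot(length(planted_numt) == 2, planted_numt[1] >= 2,
              planted_numt[1] + planted_numt[2] <= length)
    tracts <- c(tracts, list(c(planted_numt[1],
                               planted_numt[1] + planted_numt[2] - 1)))
  }
  if (length(tracts) > 1) {
    iv <- do.call(rbind, tracts)
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2] + 1))
      stop("planted tracts overlap or touch")
  }
  mito <- .random_dna(length)
  mask_c <- character(); mask_s <- integer(); mask_e <- integer()
  mask_l <- character()
  for (r in planted_repeats) {
    src <- substr(mito, r[1], r[1] + r[3] - 1)
    mito <- .substr_set(mito, r[2], src)
    # force maximality: dest flanks differ from src flanks
    for (off in c(-1L, r[3])) {
      sp <- r[1] + off; dp <- r[2] + off
      if (dp >= 1 && dp <= length && sp >= 1 && sp <= length)
        if (substr(mito, dp, dp) == substr(mito, sp, sp))
          mito <- .substr_set(mito, dp,
                              .mismatch_base(substr(mito, sp, sp)))
    }
    mask_c <- c(mask_c, "chrM", "chrM")
    mask_s <- c(mask_s, r[1], r[2]); mask_e <- c(mask_e, r[1] + r[3] - 1,
                                                 r[2] + r[3] - 1)
    mask_l <- c(mask_l, "self_repeat", "self_repeat")
  }
  nuc <- .random_dna(nuclear_length)
  if (!is.null(planted_numt)) {
    len <- planted_numt[2]
    tract <- substr(mito, planted_numt[1], planted_numt[1] + len - 1)
    at <- max(2L, nuclear_length %/% 2L)
    nuc <- .substr_set(nuc, at, tract)
    for (off in c(-1L, len)) {
      sp <- planted_numt[1] + off; dp <- at + off
      if (dp >= 1 && dp <= nuclear_length && sp >= 1 && sp <= length)
        if (substr(nuc, dp, dp) == substr(mito, sp, sp))
          nuc <- .substr_set(nuc, dp,
                             .mismatch_base(substr(mito, sp, sp)))
    }
    mask_c <- c(mask_c, "chrM"); mask_s <- c(mask_s, planted_numt[1])
    mask_e <- c(mask_e, planted_numt[1] + len - 1)
    mask_l <- c(mask_l, "cross_homology")
  }
  list(mito = c(chrM = mito), nuclear = c(decoy_nuc = nuc),
       truth = region_mask(mask_c, mask_s, mask_e, mask_l))
}

#' Simulate replicate RNA-editing variant calls plus matched WGS calls
#'
#' At each planted site the edited (alt) read count is binomial at the
#' condition's efficiency, per replicate, at Poisson depth. Sites carry the
#' substitution implied by their host-gene strand (`+`: genomic C>T, `-`:
#' genomic G>A). Decoy records exercise every exclusion rule of the caller:
#' a genomic SNP shared with WGS, a non-C-to-U substitution class, a
#' wrong-strand change, and a site absent from one replicate.
#'
#' @param sites data.frame with `contig`, `pos`, `strand` of true editing
#'   sites (strand = host gene strand).
#' @param wt_efficiency,mut_efficiency editing efficiencies in `[0, 1]`,
#'   recycled over sites.
#' @param n_replicates replicates per condition.
#' @param depth expected read depth.
#' @param decoys include the decoy records.
#' @param seed integer seed.
#' @return list with `wt` and `mut` (lists of single-sample
#'   [variant_table()]s), `wgs` (the whole-genome-sequencing table) and
#'   `truth` (data.frame of all planted records with a `recoverable` flag).
#' @export
simulate_editing_data <- function(sites, wt_efficiency, mut_efficiency,
                                  n_replicates = 3, depth = 50,
                                  decoys = TRUE, seed = 1) {
  stopifnot(all(wt_efficiency >= 0 & wt_efficiency <= 1),
            all(mut_efficiency >= 0 & mut_efficiency <= 1))
  set.seed(seed)
  ns <- nrow(sites)
  ref <- ifelse(sites$strand == "+", "C", "G")
  alt <- ifelse(sites$strand == "+", "T", "A")
  truth <- data.frame(contig = sites$contig, pos = sites$pos,
                      strand = sites$strand, ref = ref, alt = alt,
                      kind = "editing_site", recoverable = TRUE,
                      stringsAsFactors = FALSE)
  dec <- NULL
  if (decoys) {
    # anchored just downstream of the first planted site, inside the same
    # host gene, so only the targeted exclusion rule can remove each decoy
    # (requires >= 4 gene bases after sites$pos[1])
    s1 <- sites$strand[1]
    e_ref <- if (s1 == "+") "C" else "G"   # true editing class on s1
    e_alt <- if (s1 == "+") "T" else "A"
    w_ref <- if (s1 == "+") "G" else "C"   # C>T on the untranscribed strand
    w_alt <- if (s1 == "+") "A" else "T"
    dec <- data.frame(
      contig = sites$contig[1], pos = sites$pos[1] + 1:4,
      strand = s1,
      ref = c(e_ref, "A", w_ref, e_ref), alt = c(e_alt, "G", w_alt, e_alt),
      kind = c("wgs_shared", "non_c2u", "wrong_strand", "missing_replicate"),
      recoverable = FALSE, stringsAsFactors = FALSE)
    if (s1 == "-") { dec$ref[2] <- "T"; dec$alt[2] <- "C" }
  }
  all_rec <- rbind(truth, dec)
  eff_of <- function(eff) rep_len(eff, nrow(all_rec))
  build_rep <- function(eff, rep_id, drop_kind = NULL) {
    keep <- rep(TRUE, nrow(all_rec))
    if (!is.null(drop_kind)) keep <- all_rec$kind != drop_kind
    rec <- all_rec[keep, , drop = FALSE]
    e <- eff_of(eff)[keep]
    e[rec$kind == "wgs_shared"] <- 1        # fixed genomic difference
    e[rec$kind %in% c("non_c2u", "wrong_strand")] <- 0.5
    d <- pmax(1L, rpois(nrow(rec), depth))
    edited <- rbinom(nrow(rec), d, e)
    variant_table(rec$contig, rec$pos, rec$ref, rec$alt,
                  ref_count = matrix(d - edited, ncol = 1),
                  alt_count = matrix(edited, ncol = 1),
                  total_depth = matrix(d, ncol = 1),
                  gt = matrix("0/1", nrow(rec), 1),
                  samples = rep_id)
  }
  reps <- function(eff, cond) lapply(seq_len(n_replicates), function(i)
    build_rep(eff, sprintf("%s_rep%d", cond, i),
              drop_kind = if (i == 1) "missing_replicate" else NULL))
  wt <- reps(wt_efficiency, "wt")
  mut <- reps(mut_efficiency, "mut")
  wgs_rec <- all_rec[all_rec$kind == "wgs_shared", , drop = FALSE]
  wgs <- variant_table(wgs_rec$contig, wgs_rec$pos, wgs_rec$ref, wgs_rec$alt,
                       ref_count = matrix(0L, nrow(wgs_rec), 1),
                       alt_count = matrix(depth, nrow(wgs_rec), 1),
                       total_depth = matrix(depth, nrow(wgs_rec), 1),
                       gt = matrix("1/1", nrow(wgs_rec), 1),
                       samples = "wgs")
  list(wt = wt, mut = mut, wgs = wgs, truth = all_rec)
}
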