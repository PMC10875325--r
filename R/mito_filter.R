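.reason_levels <- c("non_biallelic", "missing_gt", "high_depth",
                    "low_reads_all", "repeat_region", "cross_homology")

.new_report <- function(vt, keep, reason, all_reasons = NULL, extra = list()) {
  removed <- data.frame(contig = vt$sites$contig[!keep],
                        pos = vt$sites$pos[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  removed$all_reasons <- if (is.null(all_reasons)) removed$reason else
    all_reasons[!keep]
  counts <- table(factor(removed$reason, levels = .reason_levels))
  structure(c(list(kept = subset_sites(vt, keep), removed = removed,
                   counts = as.integer(counts) |>
                     setNames(.reason_levels),
                   n_input = n_sites(vt), n_kept = sum(keep)),
              extra),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "sites in,", x$n_kept, "kept\n")
  nz <- x$counts[x$counts > 0]
  for (r in names(nz)) cat("  removed (", r, "): ", nz[r], "\n", sep = "")
  invisible(x)
}

#' Retain biallelic sites with tolerable missingness
#'
#' Sites with more than one alternative allele are removed
#' (`non_biallelic`); sites whose fraction of samples with missing genotype
#' calls exceeds `max_missing` are removed (`missing_gt`). The boundary is
#' inclusive: a site with exactly `max_missing` missing calls is retained.
#'
#' @param vt a [variant_table()] with genotype calls.
#' @param max_missing maximum tolerated missing-call fraction (default 0.40).
#' @return a `filter_report` (fields `kept`, `removed`, `counts`).
#' @export
filter_biallelic_missing <- function(vt, max_missing = 0.40) {
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0,1]")
  multi <- vt$sites$multiallelic
  miss_frac <- rowMeans(is.na(vt$gt))
  reason <- rep(NA_character_, n_sites(vt))
  reason[miss_frac > max_missing] <- "missing_gt"
  reason[multi] <- "non_biallelic"
  .new_report(vt, is.na(reason), reason)
}

#' Depth-based site and observation filtering
#'
#' The genome-wide average depth is the mean over input sites of the
#' per-site mean sample depth (a VCF carries no per-base genome coverage; a
#' precomputed value can be supplied via `genome_mean`). Sites whose
#' per-site mean depth exceeds `depth_factor` times that average are removed
#' (`high_depth`, a multi-copy-region symptom). Per-sample observations with
#' fewer than `min_reads` reads are set missing -- the per-sample phenotype
#' would otherwise rest on a handful of reads -- and a site left with no
#' observation at all is removed (`low_reads_all`).
#'
#' @param vt a [variant_table()].
#' @param depth_factor multiple of the genome average above which a site is
#'   discarded (default 1.5).
#' @param min_reads minimum reads for a per-sample observation (default 4).
#' @param genome_mean optional precomputed genome-wide average depth.
#' @return a `filter_report`; also carries `genome_mean`.
#' @export
filter_depth <- function(vt, depth_factor = 1.5, min_reads = 4,
                         genome_mean = NULL) {
  if (n_sites(vt) == 0)
    return(.new_report(vt, logical(0), character(0),
                       extra = list(genome_mean = genome_mean %||% NA_real_,
                                    masked_observations = 0L)))
  site_mean <- rowMeans(vt$total_depth, na.rm = TRUE)
  if (all(is.na(vt$total_depth)) || all(site_mean == 0, na.rm = TRUE))
    stop("depth table is all zero/missing")
  if (is.null(genome_mean)) genome_mean <- mean(site_mean, na.rm = TRUE)
  reason <- rep(NA_character_, n_sites(vt))
  reason[!is.na(site_mean) & site_mean > depth_factor * genome_mean] <-
    "high_depth"
  low <- !is.na(vt$total_depth) & vt$total_depth < min_reads
  vt$ref_count[low] <- NA; vt$alt_count[low] <- NA; vt$gt[low] <- NA
  all_missing <- rowSums(!is.na(vt$gt)) == 0
  reason[is.na(reason) & all_missing] <- "low_reads_all"
  .new_report(vt, is.na(reason), reason,
              extra = list(genome_mean = genome_mean,
                           masked_observations = sum(low)))
}

#' Remove sites inside masked regions
#'
#' @param vt a [variant_table()].
#' @param masks a [region_mask()] (e.g. from [find_self_repeats()],
#'   [find_cross_homology()], [read_bed()] or [combine_masks()]).
#' @return a `filter_report`; removal reason is `cross_homology` for
#'   intervals labelled so and `repeat_region` otherwise (self repeats and
#'   user-supplied masks).
#' @export
apply_region_mask <- function(vt, masks) {
  lab <- mask_label_at(masks, vt$sites$contig, vt$sites$pos)
  reason <- ifelse(is.na(lab), NA_character_,
                   ifelse(lab == "cross_homology", "cross_homology",
                          "repeat_region"))
  .new_report(vt, is.na(reason), reason)
}

#' The full mitochondrial variant filter cascade
#'
#' Applies, in order: (1) biallelic + missingness filtering, (2) depth
#' filtering with per-observation read masking (after which the missingness
#' rule is re-checked, since masked observations count as missing), and (3)
#' region masking against self-repeats (>= `min_homology` bp), cross-genome
#' homology tracts against each supplied genome, and any user mask. The
#' report attributes each removed site to the first filter that caught it
#' and conserves counts: removed + kept = input.
#'
#' @param vt mitochondrial [variant_table()].
#' @param mito_fasta named sequence vector of the mitochondrial reference,
#'   or `NULL` to skip self-repeat masking.
#' @param other_fastas list of named sequence vectors (nuclear, plastid, ...)
#'   for cross-homology masking.
#' @param user_mask optional extra [region_mask()].
#' @param max_missing,depth_factor,min_reads,genome_mean see the individual
#'   filters.
#' @param min_homology minimum repeat/homology tract length (default 100 bp).
#' @return a `filter_report` with the surviving table in `$kept`, plus the
#'   combined `$mask` and the `$genome_mean` used.
#' @export
filter_mito_variants <- function(vt, mito_fasta = NULL,
                                 other_fastas = list(), user_mask = NULL,
                                 max_missing = 0.40, depth_factor = 1.5,
                                 min_reads = 4, min_homology = 100,
                                 genome_mean = NULL) {
  r1 <- filter_biallelic_missing(vt, max_missing)
  r2 <- filter_depth(r1$kept, depth_factor, min_reads, genome_mean)
  # masked observations may push a site over the missingness threshold
  r2b <- filter_biallelic_missing(r2$kept, max_missing)
  masks <- region_mask()
  if (!is.null(mito_fasta))
    masks <- combine_masks(masks, find_self_repeats(mito_fasta, min_homology))
  if (!is.null(mito_fasta))
    for (g in other_fastas)
      masks <- combine_masks(masks,
                             find_cross_homology(mito_fasta, g, min_homology))
  if (!is.null(user_mask)) masks <- combine_masks(masks, user_mask)
  r3 <- apply_region_mask(r2b$kept, masks)
  removed <- rbind(r1$removed, r2$removed, r2b$removed, r3$removed)
  counts <- r1$counts + r2$counts + r2b$counts + r3$counts
  structure(list(kept = r3$kept, removed = removed, counts = counts,
                 n_input = n_sites(vt), n_kept = n_sites(r3$kept),
                 mask = masks, genome_mean = r2$genome_mean,
                 masked_observations = r2$masked_observations),
            class = "filter_report")
}
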