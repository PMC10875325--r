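.site_key <- function(vt) paste(vt$sites$contig, vt$sites$pos,
                                vt$sites$ref, vt$sites$alt, sep = ":")

#' Codon position of a genomic site within a (possibly spliced) CDS
#'
#' Computes the offset of the site in spliced-transcript coordinates
#' (CDS segments concatenated in transcription order: ascending for `+`
#' genes, descending with reversed within-segment direction for `-` genes),
#' honours the GFF3 `phase` of the first segment, and returns the 1/2/3
#' position within its codon. Segment phases that contradict the cumulative
#' segment lengths raise an error.
#'
#' @param contig,pos site location (1-based).
#' @param ann a [genome_annotation()].
#' @param gene_id host gene; when `NULL` the gene whose CDS contains the
#'   site is looked up.
#' @return integer 1, 2 or 3.
#' @export
codon_position <- function(contig, pos, ann, gene_id = NULL) {
  cds <- ann$cds[ann$cds$contig == contig, , drop = FALSE]
  if (!is.null(gene_id)) cds <- cds[cds$gene_id == gene_id, , drop = FALSE]
  hit <- cds$start <= pos & cds$end >= pos
  if (!any(hit)) stop("site ", contig, ":", pos, " is not inside a CDS")
  gene <- cds$gene_id[hit][1]
  segs <- cds[cds$gene_id == gene, , drop = FALSE]
  fwd <- segs$strand[1] == "+"
  segs <- segs[order(segs$start, decreasing = !fwd), , drop = FALSE]
  len <- segs$end - segs$start + 1L
  cum <- cumsum(c(0L, len[-length(len)]))
  phase1 <- if (is.na(segs$phase[1])) 0L else segs$phase[1]
  expected <- (phase1 - cum) %% 3L
  if (any(!is.na(segs$phase) & segs$phase != expected))
    stop("inconsistent CDS phase annotation for gene ", gene)
  k <- which(segs$start <= pos & segs$end >= pos)[1]
  within <- if (fwd) pos - segs$start[k] else segs$end[k] - pos
  o <- cum[k] + within
  as.integer(((o - phase1) %% 3L) + 1L)
}

#' Call C-to-U RNA-editing sites from replicate RNA-seq variant tables
#'
#' Candidate sites must be variant-called in every biological replicate
#' (matched on contig, position and alleles), absent from the matched
#' whole-genome-sequencing calls (which would mark a genomic SNP, not an
#' editing event), and must be C>T on the transcribed strand: genomic C>T
#' inside a `+` strand gene or genomic G>A inside a `-` strand gene. Sites
#' outside any annotated gene have no defined transcribed strand and are
#' excluded. Surviving sites are annotated with feature class (CDS / intron
#' / other), codon position (CDS sites only) and per-replicate editing
#' efficiency (edited reads / covering reads).
#'
#' @param rna_tables list of single-condition replicate [variant_table()]s.
#' @param wgs_table [variant_table()] of WGS variant calls (or `NULL`).
#' @param ann mitochondrial [genome_annotation()].
#' @param n_replicates required number of replicates (default 3).
#' @return data.frame of editing sites: contig, pos, strand, ref, alt,
#'   gene_id, feature, codon_pos, per-replicate `eff_*` columns, `mean_eff`,
#'   `quantifiable`.
#' @export
call_editing_sites <- function(rna_tables, wgs_table, ann,
                               n_replicates = 3) {
  if (length(rna_tables) != n_replicates)
    stop("expected ", n_replicates, " replicate tables, got ",
         length(rna_tables))
  keys <- lapply(rna_tables, .site_key)
  shared <- Reduce(intersect, keys)
  if (!is.null(wgs_table) && n_sites(wgs_table) > 0) {
    wgs_pos <- paste(wgs_table$sites$contig, wgs_table$sites$pos, sep = ":")
    cand_pos <- vapply(strsplit(shared, ":", fixed = TRUE),
                       function(x) paste(x[1], x[2], sep = ":"),
                       character(1))
    shared <- shared[!cand_pos %in% wgs_pos]
  }
  rows <- lapply(shared, function(key) {
    f <- strsplit(key, ":", fixed = TRUE)[[1]]
    contig <- f[1]; pos <- as.integer(f[2]); ref <- f[3]; alt <- f[4]
    host <- genes_overlapping(ann, contig, pos, pos)
    if (length(host) == 0) return(NULL)
    gene <- ann$genes[ann$genes$gene_id == host[1], ]
    strand <- gene$strand
    c2u <- (strand == "+" && ref == "C" && alt == "T") ||
      (strand == "-" && ref == "G" && alt == "A")
    if (!c2u) return(NULL)
    in_cds <- any(ann$cds$gene_id == gene$gene_id &
                    ann$cds$start <= pos & ann$cds$end >= pos)
    in_intron <- any(ann$introns$gene_id == gene$gene_id &
                       ann$introns$start <= pos & ann$introns$end >= pos)
    feature <- if (in_cds) "CDS" else if (in_intron) "intron" else "other"
    cpos <- if (in_cds) codon_position(contig, pos, ann, gene$gene_id)
    else NA_integer_
    effs <- vapply(rna_tables, function(vt) {
      i <- match(key, .site_key(vt))
      ed <- vt$alt_count[i, 1]; tot <- vt$ref_count[i, 1] + ed
      if (is.na(tot) || tot == 0) NA_real_ else ed / tot
    }, numeric(1))
    out <- data.frame(contig = contig, pos = pos, strand = strand,
                      ref = ref, alt = alt, gene_id = gene$gene_id,
                      feature = feature, codon_pos = cpos,
                      stringsAsFactors = FALSE)
    for (i in seq_along(effs)) out[[paste0("eff_", i)]] <- effs[i]
    out$mean_eff <- mean(effs)
    out$quantifiable <- !anyNA(effs)
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(contig = character(), pos = integer(),
                                      strand = character(), ref = character(),
                                      alt = character(), gene_id = character(),
                                      feature = character(),
                                      codon_pos = integer(),
                                      mean_eff = numeric(),
                                      quantifiable = logical(),
                                      stringsAsFactors = FALSE)
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' Editing efficiency of one site across replicates
#'
#' @param edited edited-read counts, one per replicate.
#' @param total covering-read counts, one per replicate.
#' @return list: `per_replicate` fractions, `mean` (unweighted across
#'   replicates), `quantifiable` (`FALSE` when any replicate has zero
#'   coverage; the mean is then `NA`).
#' @export
editing_efficiency <- function(edited, total) {
  stopifnot(length(edited) == length(total))
  if (any(edited > total, na.rm = TRUE)) stop("edited exceeds total reads")
  fr <- ifelse(is.na(total) | total == 0, NA_real_, edited / total)
  q <- !anyNA(fr)
  list(per_replicate = fr, mean = if (q) mean(fr) else NA_real_,
       quantifiable = q)
}

#' Differential editing between two conditions
#'
#' Matches sites by position, keeps those quantifiable in both conditions,
#' and flags sites whose mean-efficiency difference (mutant minus wild type)
#' reaches `min_abs_diff` in absolute value. A plain effect-size criterion
#' is used rather than a formal test: with the usual 3 replicates per
#' condition a test has essentially no power, so the threshold is the
#' decision rule, configurable and reported per site.
#'
#' @param wt_sites,mut_sites outputs of [call_editing_sites()] for the two
#'   conditions.
#' @param min_abs_diff decision threshold on `|difference|` (default 0.10).
#' @return data.frame: site annotation, `eff_wt`, `eff_mut`, `difference`,
#'   `flagged`, `direction` ("up" = higher in mutant).
#' @export
compare_conditions <- function(wt_sites, mut_sites, min_abs_diff = 0.10) {
  kw <- paste(wt_sites$contig, wt_sites$pos)
  km <- paste(mut_sites$contig, mut_sites$pos)
  shared <- intersect(kw[wt_sites$quantifiable],
                      km[mut_sites$quantifiable])
  if (length(shared) == 0) {
    warning("no shared quantifiable editing sites")
    return(data.frame())
  }
  iw <- match(shared, kw); im <- match(shared, km)
  diff <- mut_sites$mean_eff[im] - wt_sites$mean_eff[iw]
  data.frame(contig = wt_sites$contig[iw], pos = wt_sites$pos[iw],
             strand = wt_sites$strand[iw], gene_id = wt_sites$gene_id[iw],
             feature = wt_sites$feature[iw],
             codon_pos = wt_sites$codon_pos[iw],
             eff_wt = wt_sites$mean_eff[iw], eff_mut = mut_sites$mean_eff[im],
             difference = diff,
             flagged = abs(diff) >= min_abs_diff,
             direction = ifelse(abs(diff) < min_abs_diff, "none",
                                ifelse(diff > 0, "up", "down")),
             stringsAsFactors = FALSE)
}
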