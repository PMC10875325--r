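#' Cluster above-threshold SNPs into association signals
#'
#' A signal is a cluster of SNPs whose `-log10(p)` strictly exceeds the
#' threshold, spanned by its left- and right-most member SNPs. Consecutive
#' above-threshold SNPs on one contig are merged into the same signal when
#' separated by at most `max_gap` bp (the span definition fixes a signal's
#' extent but not when two above-threshold runs are distinct; `max_gap`
#' makes that choice explicit and configurable). The lead SNP is the member
#' with minimal p, ties broken by smallest position.
#'
#' @param assoc association data.frame from [gls_scan()].
#' @param threshold `-log10(p)` significance threshold (default 6, strict
#'   `>`).
#' @param max_gap maximum bp gap between member SNPs of one signal
#'   (default 1 Mb).
#' @param phenotype_id optional mito-variant id stored on each signal.
#' @return list of `signal` objects (fields: phenotype_id, contig, start,
#'   end, members, lead_pos, lead_p, max_neglog10p, genes).
#' @export
call_signals <- function(assoc, threshold = 6, max_gap = 1e6,
                         phenotype_id = NA_character_) {
  hit <- !is.na(assoc$neglog10p) & assoc$neglog10p > threshold
  hits <- assoc[hit, , drop = FALSE]
  hits <- hits[order(hits$contig, hits$pos), , drop = FALSE]
  signals <- list()
  for (ct in unique(hits$contig)) {
    h <- hits[hits$contig == ct, , drop = FALSE]
    grp <- cumsum(c(1, diff(h$pos) > max_gap))
    for (g in unique(grp)) {
      mem <- h[grp == g, , drop = FALSE]
      lead <- mem[order(mem$p, mem$pos), ][1, ]
      signals[[length(signals) + 1]] <- structure(list(
        phenotype_id = phenotype_id, contig = ct,
        start = min(mem$pos), end = max(mem$pos),
        members = mem$pos, n_members = nrow(mem),
        lead_pos = lead$pos, lead_p = lead$p,
        max_neglog10p = max(mem$neglog10p),
        genes = character(), lead_gene = NA_character_),
        class = "signal")
    }
  }
  signals
}

#' Attach overlapping genes to signals
#'
#' Genes whose 1-based inclusive interval intersects the signal span
#' `[start, end]` are attached (whole-gene overlap -- genes encompassed by
#' the peak, not exon-level overlap). The gene hosting the lead SNP, if any,
#' is flagged as the primary candidate.
#'
#' @param signals list of signals from [call_signals()].
#' @param ann a [genome_annotation()].
#' @return the signals, with `genes` and `lead_gene` filled in.
#' @export
assign_genes <- function(signals, ann) {
  lapply(signals, function(s) {
    if (!s$contig %in% ann$genes$contig) {
      warning("contig ", s$contig, " absent from annotation")
      return(s)
    }
    s$genes <- genes_overlapping(ann, s$contig, s$start, s$end)
    host <- genes_overlapping(ann, s$contig, s$lead_pos, s$lead_pos)
    s$lead_gene <- if (length(host)) host[1] else NA_character_
    s
  })
}

#' Signals as a data.frame
#' @param signals list of signals.
#' @return data.frame, one row per signal.
#' @export
signals_table <- function(signals) {
  if (length(signals) == 0)
    return(data.frame(phenotype_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), lead_pos = integer(),
                      lead_p = numeric(), max_neglog10p = numeric(),
                      n_genes = integer(), genes = character(),
                      lead_gene = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(signals, function(s)
    data.frame(phenotype_id = s$phenotype_id, contig = s$contig,
               start = s$start, end = s$end, n_members = s$n_members,
               lead_pos = s$lead_pos, lead_p = s$lead_p,
               max_neglog10p = s$max_neglog10p,
               n_genes = length(s$genes),
               genes = paste(s$genes, collapse = ","),
               lead_gene = s$lead_gene, stringsAsFactors = FALSE)))
}

#' Summarize signals and associated genes across a dataset
#'
#' Counts signals, the de-duplicated union of genes they overlap, and that
#' union as a percentage of all annotated genes.
#'
#' @param signals list of gene-annotated signals (possibly pooled over many
#'   mitochondrial phenotypes).
#' @param ann a [genome_annotation()] defining the gene universe.
#' @return one-row data.frame: n_signals, n_genes, pct_genes.
#' @export
summarize_signals <- function(signals, ann) {
  n_universe <- nrow(ann$genes)
  if (n_universe == 0) stop("annotation contains no genes")
  genes <- unique(unlist(lapply(signals, `[[`, "genes")))
  data.frame(n_signals = length(signals), n_genes = length(genes),
             pct_genes = 100 * length(genes) / n_universe)
}

#' Hypergeometric term enrichment with BH correction
#'
#' For each term, tests over-representation of the target gene set by the
#' one-sided hypergeometric upper tail (equivalently Fisher's exact test on
#' enrichment), then adjusts across terms by Benjamini-Hochberg. Term
#' databases (e.g. GO mappings) are external inputs supplied as a plain
#' gene-to-term map.
#'
#' @param target_genes character vector of hit genes (must lie in
#'   `universe`).
#' @param gene2term data.frame with columns `gene_id`, `term`.
#' @param universe character vector of all annotated genes.
#' @return data.frame per term: term, n_term, n_target, overlap, fold,
#'   p, q (BH), sorted by p. Terms with no gene in the universe are skipped.
#' @export
term_enrichment <- function(target_genes, gene2term, universe) {
  if (!all(target_genes %in% universe))
    stop("target genes outside the universe")
  target_genes <- unique(target_genes)
  universe <- unique(universe)
  gene2term <- gene2term[gene2term$gene_id %in% universe, , drop = FALSE]
  N <- length(universe); n <- length(target_genes)
  terms <- split(gene2term$gene_id, gene2term$term)
  rows <- lapply(names(terms), function(tm) {
    tg <- unique(terms[[tm]])
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, target_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_term = K, n_target = n, overlap = k,
               fold = (k / n) / (K / N), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Manhattan plot of an association scan
#'
#' Per-contig alternating colors, dashed line at the significance threshold,
#' and diamonds at the lead SNP of each supplied signal. The output device
#' is chosen from the file extension (`.png`, `.pdf`, `.svg`).
#'
#' @param assoc association data.frame.
#' @param signals optional list of signals whose lead SNPs are marked.
#' @param out_path output image path.
#' @param threshold threshold line height (default 6).
#' @param main plot title.
#' @return `out_path`, invisibly.
#' @export
manhattan_plot <- function(assoc, signals = list(), out_path,
                           threshold = 6, main = "") {
  assoc <- assoc[!is.na(assoc$neglog10p), , drop = FALSE]
  if (nrow(assoc) == 0) stop("empty association table")
  assoc <- assoc[order(assoc$contig, assoc$pos), , drop = FALSE]
  contigs <- unique(assoc$contig)
  offset <- setNames(numeric(length(contigs)), contigs)
  run <- 0
  for (ct in contigs) {
    offset[ct] <- run
    run <- run + max(assoc$pos[assoc$contig == ct]) + 1
  }
  x <- assoc$pos + offset[assoc$contig]
  ext <- tolower(sub(".*\\.", "", out_path))
  switch(ext,
         png = grDevices::png(out_path, width = 1000, height = 400),
         svg = grDevices::svg(out_path, width = 10, height = 4),
         pdf = grDevices::pdf(out_path, width = 10, height = 4),
         stop("unsupported image extension: ", ext))
  on.exit(grDevices::dev.off())
  col <- c("grey30", "steelblue")[(match(assoc$contig, contigs) %% 2) + 1]
  plot(x, assoc$neglog10p, pch = 20, cex = 0.6, col = col,
       xlab = "genome position", ylab = expression(-log[10](p)),
       main = main, ylim = c(0, max(assoc$neglog10p, threshold) * 1.08))
  graphics::abline(h = threshold, lty = 2, col = "red")
  for (s in signals) {
    xi <- s$lead_pos + offset[s$contig]
    yi <- assoc$neglog10p[assoc$contig == s$contig & assoc$pos == s$lead_pos]
    if (length(yi)) graphics::points(xi, yi[1], pch = 18, cex = 1.6,
                                     col = "darkorange")
  }
  invisible(out_path)
}
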