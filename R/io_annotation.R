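#' Gene annotation with interval indexing
#'
#' Holds gene, exon and CDS intervals (1-based inclusive, as in GFF3) and the
#' introns derived from the gaps between consecutive exons of each
#' transcript. Overlap queries are served by [GenomicRanges::findOverlaps()].
#'
#' @param genes data.frame with columns `gene_id, contig, start, end, strand`.
#' @param exons optional data.frame with `gene_id, transcript_id, contig,
#'   start, end, strand`.
#' @param cds optional data.frame like `exons` plus a `phase` column
#'   (0/1/2; bases to skip before the first complete codon).
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons = NULL, cds = NULL) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in%
                  names(genes)))
  if (nrow(genes) > 0 && any(genes$start > genes$end))
    stop("gene with start > end")
  if (nrow(genes) > 0 && !all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  empty <- data.frame(gene_id = character(), transcript_id = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (is.null(exons)) exons <- empty
  if (is.null(cds)) cds <- cbind(empty, phase = integer())
  if (nrow(cds) > 0 && is.null(cds$phase)) cds$phase <- 0L
  introns <- empty
  if (nrow(exons) > 1) {
    parts <- split(exons, exons$transcript_id)
    ilist <- lapply(parts, function(e) {
      e <- e[order(e$start), ]
      if (nrow(e) < 2) return(NULL)
      data.frame(gene_id = e$gene_id[1], transcript_id = e$transcript_id[1],
                 contig = e$contig[1],
                 start = e$end[-nrow(e)] + 1L, end = e$start[-1] - 1L,
                 strand = e$strand[1], stringsAsFactors = FALSE)
    })
    introns <- do.call(rbind, c(ilist, list(empty)))
    introns <- introns[introns$start <= introns$end, , drop = FALSE]
  }
  structure(list(genes = genes, exons = exons, cds = cds, introns = introns),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,", nrow(x$cds),
      "CDS segments,", nrow(x$introns), "introns\n")
  invisible(x)
}

.df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$contig,
                         IRanges::IRanges(df$start, df$end),
                         strand = df$strand)
}

#' Genes overlapping an interval
#'
#' @param ann a [genome_annotation()].
#' @param contig contig name.
#' @param start,end 1-based inclusive query interval.
#' @return character vector of gene ids whose [start, end] intersects the
#'   query (order of appearance in the annotation).
#' @export
genes_overlapping <- function(ann, contig, start, end) {
  if (nrow(ann$genes) == 0) return(character())
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, .df_to_granges(ann$genes),
                                      ignore.strand = TRUE)
  ann$genes$gene_id[unique(S4Vectors::subjectHits(hits))]
}

#' Read a GFF3 gene annotation
#'
#' Uses [rtracklayer::import()]; gene/mRNA/exon/CDS features are linked by
#' their `Parent` attributes (exons and CDS may point at a transcript or
#' directly at a gene). CDS segments without a resolvable parent are skipped
#' with a warning.
#'
#' @param path GFF3 file.
#' @return a [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3: ",
                                          conditionMessage(e)))
  if (length(gr) == 0) return(genome_annotation(
    data.frame(gene_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(gr))
  parent <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = type, id = id, parent = parent,
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", ]
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  tx2gene <- setNames(tx$parent, tx$id)
  to_gene <- function(p) {
    out <- ifelse(p %in% names(tx2gene), unname(tx2gene[p]), p)
    ifelse(out %in% genes$id, out, NA_character_)
  }
  mk <- function(sub, with_phase = FALSE) {
    g <- to_gene(sub$parent)
    drop <- is.na(g)
    if (any(drop))
      warning(sum(drop), " ", if (with_phase) "CDS" else "exon",
              " feature(s) without resolvable parent skipped")
    sub <- sub[!drop, , drop = FALSE]; g <- g[!drop]
    out <- data.frame(gene_id = g,
                      transcript_id = ifelse(is.na(sub$parent), g, sub$parent),
                      contig = sub$contig, start = sub$start, end = sub$end,
                      strand = sub$strand, stringsAsFactors = FALSE)
    out
  }
  exons <- mk(df[df$type == "exon", ])
  cds_raw <- df[df$type == "CDS", ]
  cds <- mk(cds_raw, with_phase = TRUE)
  if (nrow(cds) > 0) {
    ph <- S4Vectors::mcols(gr)$phase[df$type == "CDS"]
    keep <- !is.na(to_gene(cds_raw$parent))
    cds$phase <- as.integer(ifelse(is.na(ph[keep]), 0L, ph[keep]))
  }
  genome_annotation(
    data.frame(gene_id = genes$id, contig = genes$contig,
               start = genes$start, end = genes$end, strand = genes$strand,
               stringsAsFactors = FALSE),
    exons = exons, cds = cds)
}

#' Write a toy GFF3 from a genome_annotation
#'
#' Minimal serializer used by the synthetic-data generator (gene + mRNA +
#' exon + CDS rows); output is valid input to [read_gff3()].
#'
#' @param ann a [genome_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  row <- function(contig, type, start, end, strand, phase, attr)
    paste(contig, "mitolink", type, start, end, ".", strand,
          phase, attr, sep = "\t")
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               row(g$contig, "gene", g$start, g$end, g$strand, ".",
                   paste0("ID=", g$gene_id)),
               row(g$contig, "mRNA", g$start, g$end, g$strand, ".",
                   paste0("ID=", tid, ";Parent=", g$gene_id)))
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, row(ex$contig[j], "exon", ex$start[j], ex$end[j],
                            ex$strand[j], ".", paste0("Parent=", tid)))
    cd <- ann$cds[ann$cds$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(cd)))
      lines <- c(lines, row(cd$contig[j], "CDS", cd$start[j], cd$end[j],
                            cd$strand[j], cd$phase[j],
                            paste0("Parent=", tid)))
  }
  writeLines(lines, path)
  invisible(path)
}
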