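# Small fixtures built in code.

write_fixture_vcf <- function(path,
                              rows = c(
  "chrM\t5\t.\tA\tT\t.\tPASS\t.\tGT:AD:DP\t0:5,2:8\t1:0,9:9",
  "chrM\t9\t.\tC\tG,T\t.\tPASS\t.\tGT:AD:DP\t0:4,2:6\t.:.:.",
  "chrM\t42\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP\t1:1,7:8\t0:6,0:6"),
                              samples = c("S1", "S2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}

# minimal variant table built directly (counts given as site x sample)
fixture_vt <- function(pos, ref_count, alt_count, depth = NULL, gt = NULL,
                       contig = "chrM", ref = "A", alt = "G",
                       samples = NULL) {
  ref_count <- as.matrix(ref_count); alt_count <- as.matrix(alt_count)
  if (is.null(depth)) depth <- ref_count + alt_count
  depth <- as.matrix(depth)
  if (is.null(gt)) {
    gt <- matrix(ifelse(is.na(ref_count), NA_character_,
                        ifelse(ref_count >= alt_count, "0", "1")),
                 nrow(ref_count), ncol(ref_count))
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(ref_count)))
  variant_table(rep(contig, length(pos)), pos,
                rep_len(ref, length(pos)), rep_len(alt, length(pos)),
                ref_count, alt_count, depth, gt, samples)
}

fixture_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    contig = c("chr1", "chr1", "chr2"),
    start = c(100L, 1000L, 50L), end = c(500L, 2000L, 400L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC"),
    transcript_id = c("gA.t1", "gA.t1", "gB.t1", "gC.t1"),
    contig = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 300L, 1000L, 50L), end = c(200L, 500L, 2000L, 400L),
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  cds <- cbind(exons, phase = c(0L, 1L, 0L, 0L))
  genome_annotation(genes, exons = exons, cds = cds)
}

# small structured panel for mixed-model tests
fixture_panel <- function(seed = 1, n = 150, m = 1200, fst = 0.3,
                          causal = NULL, beta = 0) {
  cfg <- sim_config(n_individuals = n, n_nuclear_snps = m, fst = fst,
                    causal_snp_index = causal, beta = beta, seed = seed)
  pop <- simulate_population(cfg)
  list(cfg = cfg, pop = pop)
}
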