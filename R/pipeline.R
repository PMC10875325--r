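#' Pipeline configuration
#'
#' Collects all input paths and stage parameters with their standard
#' defaults (missingness 0.40, depth factor 1.5, minimum 4 reads,
#' repeat/homology length 100 bp, MAF 0.05, signal threshold
#' `-log10(p) > 6`, 100 kb / 10 kb diversity windows, binarization bounds
#' 0.05 / 0.95). Round-trips through YAML via [read_config()] /
#' [write_config()].
#'
#' @param mito_vcf,nuclear_vcf,mito_fasta,nuclear_fasta,plastid_fasta,gff
#'   input paths (`plastid_fasta` and `user_mask_bed` may be `NULL`).
#' @param user_mask_bed optional extra mask BED.
#' @param out_dir output directory.
#' @param max_missing,depth_factor,min_reads,min_homology,min_maf,threshold,max_gap,window,step,binarize_low,binarize_high
#'   stage parameters (see the stage functions).
#' @param binary also emit and analyze the binarized phenotype matrix.
#' @param seed seed for any stochastic demo stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mito_vcf, nuclear_vcf, mito_fasta,
                            nuclear_fasta, gff, out_dir,
                            plastid_fasta = NULL, user_mask_bed = NULL,
                            max_missing = 0.40, depth_factor = 1.5,
                            min_reads = 4, min_homology = 100,
                            min_maf = 0.05, threshold = 6, max_gap = 1e6,
                            window = 1e5, step = 1e4,
                            binarize_low = 0.05, binarize_high = 0.95,
                            binary = FALSE, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

.jlog <- function(con, stage, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  message("[", stage, "] ", event,
          if (length(list(...))) paste0(" ", paste(names(list(...)),
                                                   unlist(list(...)),
                                                   sep = "=",
                                                   collapse = " ")) else "")
}

#' Generate a self-contained synthetic demo dataset
#'
#' Writes every pipeline input -- mitochondrial and nuclear VCFs, reference
#' FASTAs with planted repeat/numt tracts, a toy gene annotation with a gene
#' over the causal SNP -- plus truth files, and a ready-to-run YAML config.
#'
#' Presets: `"tiny"` (n = 300, 5,000 nuclear SNPs, 20 mitochondrial
#' variants, one causal SNP/gene pair), `"null"` (same, no causal effect),
#' `"micro"` (n = 120, 800 SNPs, 6 variants; for quick checks).
#'
#' @param seed integer seed.
#' @param preset `"tiny"`, `"null"` or `"micro"`.
#' @param dir output directory (created if missing).
#' @return list with `config` (a [pipeline_config()]), `config_path`,
#'   `truth` (causal SNP/gene ids and the planted region mask) and `paths`.
#' @export
make_demo <- function(seed = 1, preset = c("tiny", "null", "micro"),
                      dir = tempfile("mitolink_demo_")) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  cfg_sim <- switch(preset,
    tiny = sim_config(seed = seed, causal_snp_index = NA),
    null = sim_config(seed = seed, causal_snp_index = NULL),
    micro = sim_config(n_individuals = 120, n_nuclear_snps = 800,
                       n_mito_variants = 6, causal_snp_index = NA,
                       seed = seed))
  pop <- simulate_population(cfg_sim)
  if (!is.null(cfg_sim$causal_snp_index) && is.na(cfg_sim$causal_snp_index))
    cfg_sim$causal_snp_index <- choose_causal_snp(pop)
  fr <- simulate_mito_fractions(pop$genotypes, cfg_sim)
  mito_len <- 30000L
  genome <- simulate_mito_genome(mito_len,
                                 planted_repeats = list(c(2001L, 9001L, 150L)),
                                 planted_numt = c(15001L, 120L),
                                 seed = cfg_sim$seed + 3)
  mito_vt <- simulate_read_counts(fr, cfg_sim$mean_depth,
                                  seed = cfg_sim$seed + 2,
                                  contig_length = mito_len,
                                  exclude = genome$truth)
  write_vcf(as_variant_table(pop), p("nuclear.vcf"))
  write_vcf(mito_vt, p("mito.vcf"))
  write_fasta(genome$mito, p("mito.fa"))
  write_fasta(genome$nuclear, p("nuclear.fa"))
  write_bed(genome$truth, p("truth_mask.bed"))
  # toy gene models: single-exon genes tiled over the nuclear contig,
  # plus one gene straddling the causal SNP
  set.seed(cfg_sim$seed + 4)
  span <- max(pop$info$pos)
  starts <- seq(1000L, span - 6000L, length.out = 60)
  starts <- as.integer(round(starts))
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_along(starts)),
                      contig = "chr1", start = starts,
                      end = starts + 4999L,
                      strand = sample(c("+", "-"), length(starts),
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  causal_gene <- NA_character_
  if (!is.null(cfg_sim$causal_snp_index)) {
    cp <- pop$info$pos[cfg_sim$causal_snp_index]
    genes <- genes[genes$end < cp - 5000L | genes$start > cp + 5000L, ]
    genes <- rbind(genes,
                   data.frame(gene_id = "causal_gene", contig = "chr1",
                              start = cp - 2000L, end = cp + 2000L,
                              strand = "+", stringsAsFactors = FALSE))
    causal_gene <- "causal_gene"
  }
  exons <- cbind(genes[, c("gene_id", "contig", "start", "end", "strand")],
                 transcript_id = paste0(genes$gene_id, ".t1"))
  cds <- cbind(exons, phase = 0L)
  ann <- genome_annotation(genes, exons = exons, cds = cds)
  write_gff3(ann, p("genes.gff3"))
  causal_snp <- if (is.null(cfg_sim$causal_snp_index)) NA_character_ else
    paste0("chr1:", pop$info$pos[cfg_sim$causal_snp_index])
  truth <- list(causal_snp = causal_snp, causal_gene = causal_gene,
                causal_variant = if (is.null(cfg_sim$causal_snp_index))
                  NA_character_ else variant_ids(mito_vt)[
                    cfg_sim$causal_variant_index],
                mask = genome$truth, sim_config = cfg_sim)
  config <- pipeline_config(mito_vcf = p("mito.vcf"),
                            nuclear_vcf = p("nuclear.vcf"),
                            mito_fasta = p("mito.fa"),
                            nuclear_fasta = p("nuclear.fa"),
                            gff = p("genes.gff3"),
                            out_dir = p("out"), seed = seed)
  write_config(config, p("config.yaml"))
  list(config = config, config_path = p("config.yaml"), truth = truth,
       paths = list(dir = dir))
}

#' Run the full mitonuclear association pipeline
#'
#' Stages, in fixed order: mitochondrial variant filtering, phenotype
#' construction, kinship mixed-model GWAS (one scan per mitochondrial
#' variant), signal calling + gene assignment + summary, and windowed
#' nucleotide diversity with a target/background contrast. All inputs are
#' validated before the first stage runs; a failure in one phenotype's scan
#' does not abort the others. Every stage logs its parameters and record
#' counts to a JSON-lines run log.
#'
#' @param config a [pipeline_config()] (or path to its YAML file).
#' @return invisibly, a list with the key in-memory results (`filter`,
#'   `phenotypes`, `gwas`, `signals`, `summary`, `pi`) and `out_dir`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_config(config)
  req <- c("mito_vcf", "nuclear_vcf", "mito_fasta", "nuclear_fasta", "gff")
  paths <- unlist(config[req])
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- function(f) file.path(config$out_dir, f)
  log_con <- file(o("run_log.jsonl"), open = "wt")
  on.exit(close(log_con))
  write_config(config, o("run_manifest.yaml"))

  # -- filter ---------------------------------------------------------------
  mito_vt <- read_vcf(config$mito_vcf)
  others <- list(read_fasta(config$nuclear_fasta))
  if (!is.null(config$plastid_fasta))
    others <- c(others, list(read_fasta(config$plastid_fasta)))
  user_mask <- if (!is.null(config$user_mask_bed))
    read_bed(config$user_mask_bed) else NULL
  filt <- filter_mito_variants(mito_vt,
                              mito_fasta = read_fasta(config$mito_fasta),
                              other_fastas = others, user_mask = user_mask,
                              max_missing = config$max_missing,
                              depth_factor = config$depth_factor,
                              min_reads = config$min_reads,
                              min_homology = config$min_homology)
  write_vcf(filt$kept, o("mito.filtered.vcf"))
  write.table(filt$removed, o("filter_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(filt$mask) > 0) write_bed(filt$mask, o("mask.bed"))
  .jlog(log_con, "filter", "done", n_input = filt$n_input,
        n_kept = filt$n_kept, genome_mean_depth = filt$genome_mean)

  # -- phenotype ------------------------------------------------------------
  pheno <- build_phenotype_matrix(filt$kept)
  write_phenotype_tsv(pheno, o("phenotypes.tsv"))
  if (isTRUE(config$binary))
    write_phenotype_tsv(binarize(pheno, config$binarize_low,
                                 config$binarize_high),
                        o("phenotypes.binary.tsv"))
  .jlog(log_con, "phenotype", "done", n_phenotypes = nrow(pheno),
        n_samples = ncol(pheno))

  # -- gwas -----------------------------------------------------------------
  geno <- as_dosage(read_vcf(config$nuclear_vcf))
  n_before <- ncol(geno$genotypes)
  geno <- filter_nuclear_snps(geno, config$max_missing, config$min_maf)
  K <- compute_kinship(geno$genotypes)
  gwas <- run_gwas(pheno, geno, K)
  .jlog(log_con, "gwas", "done", n_snps_in = n_before,
        n_snps_tested = ncol(geno$genotypes),
        n_phenotypes_run = length(gwas$results),
        n_phenotypes_skipped = length(gwas$skipped))
  for (id in names(gwas$results))
    write.table(gwas$results[[id]],
                o(paste0("assoc_", gsub("[^A-Za-z0-9]", "_", id), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  vc_log <- do.call(rbind, lapply(names(gwas$vc), function(id)
    data.frame(phenotype = id, sigma_g2 = gwas$vc[[id]]$sigma_g2,
               sigma_e2 = gwas$vc[[id]]$sigma_e2,
               delta = gwas$vc[[id]]$delta,
               boundary = gwas$vc[[id]]$boundary)))
  if (!is.null(vc_log))
    write.table(vc_log, o("variance_components.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  # -- signals --------------------------------------------------------------
  ann <- read_gff3(config$gff)
  all_signals <- list()
  for (id in names(gwas$results)) {
    s <- call_signals(gwas$results[[id]], threshold = config$threshold,
                      max_gap = config$max_gap, phenotype_id = id)
    s <- assign_genes(s, ann)
    all_signals <- c(all_signals, s)
    if (length(s) > 0)
      manhattan_plot(gwas$results[[id]], s,
                     o(paste0("manhattan_", gsub("[^A-Za-z0-9]", "_", id),
                              ".png")),
                     threshold = config$threshold, main = id)
  }
  st <- signals_table(all_signals)
  write.table(st, o("signals.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  summ <- summarize_signals(all_signals, ann)
  write.table(summ, o("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  .jlog(log_con, "signals", "done", n_signals = summ$n_signals,
        n_genes = summ$n_genes, pct_genes = summ$pct_genes)

  # -- popgen ---------------------------------------------------------------
  nuc_vt <- read_vcf(config$nuclear_vcf)
  track <- windowed_pi(nuc_vt, window = config$window, step = config$step)
  write.table(track, o("pi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  contrast <- NULL
  target <- unique(unlist(lapply(all_signals, `[[`, "genes")))
  if (length(target) >= 3 && nrow(ann$genes) - length(target) >= 3) {
    contrast <- gene_diversity_contrast(track, ann, target)
    write.table(data.frame(group = rownames(contrast$summary),
                           contrast$summary, p = contrast$p),
                o("diversity_contrast.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  .jlog(log_con, "popgen", "done", n_windows = nrow(track),
        contrast_run = !is.null(contrast))

  invisible(list(filter = filt, phenotypes = pheno, gwas = gwas,
                 signals = all_signals, summary = summ, pi = track,
                 contrast = contrast, out_dir = config$out_dir))
}
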