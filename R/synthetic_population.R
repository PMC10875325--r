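#' Simulation settings for the synthetic study population
#'
#' The defaults describe the study conditions the pipeline is validated
#' under: a structured crop-resequencing-style panel (300 individuals in 3
#' subpopulations, Balding-Nichols divergence Fst = 0.3, 5,000 nuclear SNPs),
#' mitochondrial heteroplasmy phenotypes read-sampled at 100x mean depth, a
#' causal nuclear SNP shifting the reference-allele fraction by `beta` per
#' allele copy, and a polygenic background tied to kinship.
#'
#' @param n_individuals panel size.
#' @param n_subpops number of subpopulations (equal split).
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`.
#' @param n_nuclear_snps number of nuclear SNPs.
#' @param maf_range range the ancestral allele frequencies are drawn from.
#' @param missing_rate per-observation genotype missingness.
#' @param causal_snp_index column of the causal nuclear SNP, or `NULL` for a
#'   null (no-association) panel.
#' @param beta shift in mitochondrial reference-allele fraction per causal
#'   allele copy.
#' @param causal_variant_index which mitochondrial variant carries the causal
#'   effect (others are simulated with beta = 0).
#' @param mu baseline reference-allele fraction.
#' @param heritability_background fraction of (pre-clipping) phenotype
#'   variance attributable to the kinship-structured polygenic term.
#' @param noise_sd residual standard deviation of the true fraction.
#' @param mean_depth expected reads per mitochondrial site per individual.
#' @param n_mito_variants number of mitochondrial variants to simulate.
#' @param seed integer seed; fully determines every generator's output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 300, n_subpops = 3, fst = 0.3,
                       n_nuclear_snps = 5000, maf_range = c(0.05, 0.5),
                       missing_rate = 0.02, causal_snp_index = NULL,
                       beta = 0.2, causal_variant_index = 1, mu = 0.5,
                       heritability_background = 0.5, noise_sd = 0.05,
                       mean_depth = 100, n_mito_variants = 20, seed = 1) {
  stopifnot(fst >= 0, fst < 1,
            maf_range[1] > 0, maf_range[2] < 0.5 + 1e-12,
            heritability_background >= 0, heritability_background < 1,
            noise_sd >= 0, mean_depth >= 0)
  if (n_subpops > n_individuals) stop("more subpopulations than individuals")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a structured diploid nuclear SNP panel
#'
#' Ancestral allele frequencies are uniform on `maf_range`; subpopulation
#' frequencies follow the Balding-Nichols model
#' `p_k ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` (with `F = fst`; `fst = 0`
#' collapses to the ancestral frequency), and diploid genotypes are binomial
#' draws. This produces both the stratification and the hidden relatedness
#' the kinship mixed model has to absorb.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (individuals x SNPs dosage matrix, `NA`
#'   missing), `info` (SNP data.frame: contig, pos, ref, alt), `subpop`
#'   (labels), `subpop_freq` and `config`.
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  n <- config$n_individuals; m <- config$n_nuclear_snps
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  subpop <- rep_len(seq_len(config$n_subpops), n)
  pk <- matrix(NA_real_, config$n_subpops, m)
  for (k in seq_len(config$n_subpops)) {
    pk[k, ] <- if (config$fst == 0) p else
      rbeta(m, p * (1 - config$fst) / config$fst,
            (1 - p) * (1 - config$fst) / config$fst)
  }
  g <- matrix(rbinom(n * m, 2L, pk[subpop, ]), n, m)
  if (config$missing_rate > 0)
    g[runif(n * m) < config$missing_rate] <- NA
  samples <- sprintf("S%04d", seq_len(n))
  pos <- sort(sample.int(m * 2000L, m))
  info <- data.frame(contig = "chr1", pos = pos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  dimnames(g) <- list(samples, paste0("chr1:", pos))
  list(genotypes = g, info = info, subpop = subpop,
       subpop_freq = pk, config = config)
}

#' Choose a causal SNP that is actually testable
#'
#' Balding-Nichols drift can push a randomly chosen SNP's realized minor
#' allele frequency below the association scan's MAF filter, in which case a
#' causal effect planted on it is removed before testing and the recovery
#' experiment is vacuous. This picks the SNP nearest `near` (default: the
#' middle of the panel) whose realized MAF and missingness make it a valid
#' common test SNP.
#'
#' @param pop result of [simulate_population()].
#' @param min_maf minimum realized minor allele frequency (default 0.10).
#' @param max_missing maximum missing fraction (default 0.20).
#' @param near preferred SNP index.
#' @return integer SNP index.
#' @export
choose_causal_snp <- function(pop, min_maf = 0.10, max_missing = 0.20,
                              near = NULL) {
  g <- pop$genotypes
  f <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  ok <- which(maf >= min_maf & colMeans(is.na(g)) <= max_missing)
  if (length(ok) == 0) stop("no SNP satisfies the causal-SNP conditions")
  if (is.null(near)) near <- ncol(g) %/% 2
  ok[which.min(abs(ok - near))]
}

#' Centered (VanRaden) genomic relationship matrix used for simulation
#' @param genotypes individuals x SNPs dosage matrix (NA allowed).
#' @return n x n covariance-scale relationship matrix.
#' @keywords internal
.sim_grm <- function(genotypes) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  Z <- sweep(genotypes, 2, 2 * p)
  Z[is.na(Z)] <- 0
  tcrossprod(Z) / (2 * sum(p * (1 - p)))
}

#' Simulate true mitochondrial reference-allele fractions
#'
#' Each mitochondrial variant is an independent quantitative trait on the
#' read-fraction scale:
#' `fraction = clip(mu + beta * g_causal + polygenic + e, 0, 1)`, where the
#' polygenic term is multivariate normal with covariance proportional to the
#' realized kinship of the panel, scaled so it contributes
#' `heritability_background` of the non-causal variance, and
#' `e ~ N(0, noise_sd^2)`. Only the variant at `causal_variant_index`
#' receives the causal term; all others use beta = 0.
#'
#' @param genotypes individuals x SNPs dosage matrix from
#'   [simulate_population()].
#' @param config a [sim_config()].
#' @param seed seed for this step (defaults to `config$seed + 1`).
#' @return matrix of true fractions, mito variants x individuals.
#' @export
simulate_mito_fractions <- function(genotypes, config,
                                    seed = config$seed + 1) {
  set.seed(seed)
  n <- nrow(genotypes); nv <- config$n_mito_variants
  h <- config$heritability_background
  sigma_p <- if (h > 0) config$noise_sd * sqrt(h / (1 - h)) else 0
  L <- NULL
  if (sigma_p > 0) {
    K <- .sim_grm(genotypes)
    L <- chol(K + diag(1e-6, n))
  }
  g_causal <- NULL
  if (!is.null(config$causal_snp_index)) {
    g_causal <- genotypes[, config$causal_snp_index]
    g_causal[is.na(g_causal)] <- mean(g_causal, na.rm = TRUE)
  }
  fr <- matrix(NA_real_, nv, n, dimnames = list(NULL, rownames(genotypes)))
  for (v in seq_len(nv)) {
    y <- rep(config$mu, n)
    if (!is.null(g_causal) && v == config$causal_variant_index)
      y <- y + config$beta * g_causal
    if (sigma_p > 0) y <- y + sigma_p * drop(crossprod(L, rnorm(n)))
    if (config$noise_sd > 0) y <- y + rnorm(n, 0, config$noise_sd)
    fr[v, ] <- pmin(1, pmax(0, y))
  }
  fr
}

#' Sample mitochondrial read counts at the simulated fractions
#'
#' Per-sample depth is Poisson(`mean_depth`); reads supporting the reference
#' allele are binomial at the true fraction. Zero-depth observations are
#' missing (no genotype call, no counts).
#'
#' @param fractions mito variants x individuals matrix in `[0, 1]`.
#' @param mean_depth expected per-site per-sample depth.
#' @param seed integer seed.
#' @param contig contig name for the simulated sites.
#' @param contig_length mitochondrial contig length the site positions are
#'   drawn from.
#' @param exclude optional [region_mask()]; site positions avoid its
#'   intervals (a caller would not report variants in masked tracts).
#' @return a [variant_table()] with one site per row of `fractions`.
#' @export
simulate_read_counts <- function(fractions, mean_depth, seed = 1,
                                 contig = "chrM",
                                 contig_length = 300000L, exclude = NULL) {
  stopifnot(all(fractions >= 0 & fractions <= 1, na.rm = TRUE))
  set.seed(seed)
  nv <- nrow(fractions); n <- ncol(fractions)
  depth <- matrix(rpois(nv * n, mean_depth), nv, n)
  rc <- matrix(rbinom(nv * n, depth, fractions), nv, n)
  ac <- depth - rc
  gt <- matrix(ifelse(rc / depth >= 0.5, "0", "1"), nv, n)
  miss <- depth == 0
  rc[miss] <- NA; ac[miss] <- NA; gt[miss] <- NA
  allowed <- seq_len(max(contig_length, nv * 10L))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    bad <- unlist(lapply(which(exclude$contig == contig), function(i)
      exclude$start[i]:exclude$end[i]))
    allowed <- setdiff(allowed, bad)
  }
  pos <- sort(sample(allowed, nv))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  samples <- colnames(fractions) %||% sprintf("S%04d", seq_len(n))
  variant_table(rep(contig, nv), pos, ref, alt, rc, ac, depth, gt, samples)
}

#' Express a simulated nuclear panel as a variant table
#'
#' Builds VCF-compatible GT/AD/DP fields from the dosage matrix (constant
#' synthetic depth split according to genotype) so the panel can be written
#' with [write_vcf()] and re-enter the pipeline through [read_vcf()].
#'
#' @param pop result of [simulate_population()].
#' @param depth synthetic per-observation read depth.
#' @return a [variant_table()].
#' @export
as_variant_table <- function(pop, depth = 30L) {
  g <- t(pop$genotypes)           # sites x samples
  gt <- matrix(NA_character_, nrow(g), ncol(g))
  gt[g == 0] <- "0/0"; gt[g == 1] <- "0/1"; gt[g == 2] <- "1/1"
  rc <- matrix(NA_integer_, nrow(g), ncol(g))
  rc[g == 0] <- depth; rc[g == 1] <- depth %/% 2L; rc[g == 2] <- 0L
  ac <- ifelse(is.na(rc), NA_integer_, depth - rc)
  dp <- ifelse(is.na(rc), NA_integer_, depth)
  variant_table(pop$info$contig, pop$info$pos, pop$info$ref, pop$info$alt,
                rc, ac, dp, gt, rownames(pop$genotypes))
}
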