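.allele_copies <- function(gt) {
  # per-site ref/alt allele-copy counts from genotype strings
  a <- gsub("[|/]", "", gt)
  alt <- matrix(NA_real_, nrow(gt), ncol(gt))
  tot <- matrix(0, nrow(gt), ncol(gt))
  ok <- !is.na(a) & !grepl("\\.", gt)
  alt[ok] <- vapply(strsplit(a[ok], ""), function(x) sum(x != "0"),
                    numeric(1))
  tot[ok] <- nchar(a[ok])
  list(alt = rowSums(alt, na.rm = TRUE), total = rowSums(tot))
}

#' Sliding-window nucleotide diversity (vcftools semantics)
#'
#' Per-site diversity is the unbiased pairwise heterozygosity
#' `pi_s = 2 c0 c1 / (n (n - 1))` over the non-missing allele copies at the
#' site (diploid calls contribute two copies). Window diversity is the sum
#' of site values divided by the window length in bp, so monomorphic
#' positions dilute the estimate exactly as in `vcftools --window-pi`.
#' Windows slide by `step`; the terminal window is truncated at the contig
#' end.
#'
#' @param vt biallelic [variant_table()] with genotype calls.
#' @param window window size in bp (default 100 kb).
#' @param step step size in bp (default 10 kb); must not exceed `window`.
#' @param contig_lengths named vector of contig lengths; defaults to the
#'   largest variant position per contig.
#' @return data.frame: contig, start, end, n_variants, pi.
#' @export
windowed_pi <- function(vt, window = 100000, step = 10000,
                        contig_lengths = NULL) {
  if (step > window) stop("step must not exceed window")
  ac <- .allele_copies(vt$gt)
  n <- ac$total; c1 <- ac$alt; c0 <- n - c1
  site_pi <- ifelse(n > 1, 2 * c0 * c1 / (n * (n - 1)), 0)
  out <- list()
  for (ct in unique(vt$sites$contig)) {
    sel <- vt$sites$contig == ct
    pos <- vt$sites$pos[sel]; sp <- site_pi[sel]
    L <- if (!is.null(contig_lengths) && ct %in% names(contig_lengths))
      contig_lengths[[ct]] else max(pos)
    starts <- seq(1, L, by = step)
    starts <- starts[starts <= L]
    ends <- pmin(starts + window - 1, L)
    n_var <- pi_w <- numeric(length(starts))
    for (i in seq_along(starts)) {
      inw <- pos >= starts[i] & pos <= ends[i]
      n_var[i] <- sum(inw)
      pi_w[i] <- sum(sp[inw]) / (ends[i] - starts[i] + 1)
    }
    out[[ct]] <- data.frame(contig = ct, start = starts, end = ends,
                            n_variants = n_var, pi = pi_w,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Diversity contrast between target and background gene sets
#'
#' Maps each gene to a diversity value -- by default the mean of the sliding
#' windows overlapping the gene span (switchable to per-gene aggregation of
#' site diversity via `mapping = "site"` with a `site_pi` table) -- and
#' compares target vs background by a two-sided Wilcoxon rank-sum test
#' (exact for combined n <= 30 without ties, normal approximation with tie
#' and continuity correction otherwise).
#'
#' @param track window table from [windowed_pi()].
#' @param ann a [genome_annotation()].
#' @param target_genes gene ids exhibiting association signals.
#' @param background_genes gene ids to compare against (default: all other
#'   annotated genes).
#' @param mapping `"window"` (mean of overlapping windows) or `"site"`.
#' @param site_pi optional data.frame `contig, pos, pi` for `mapping =
#'   "site"`.
#' @return list: `target` / `background` (per-gene values), `summary`
#'   (median and quartiles per group), `p` (two-sided Wilcoxon).
#' @export
gene_diversity_contrast <- function(track, ann, target_genes,
                                    background_genes = NULL,
                                    mapping = c("window", "site"),
                                    site_pi = NULL) {
  mapping <- match.arg(mapping)
  if (is.null(background_genes))
    background_genes <- setdiff(ann$genes$gene_id, target_genes)
  gene_value <- function(gid) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    if (nrow(g) == 0) return(NA_real_)
    if (mapping == "window") {
      w <- track[track$contig == g$contig & track$start <= g$end &
                   track$end >= g$start, , drop = FALSE]
      if (nrow(w) == 0) NA_real_ else mean(w$pi)
    } else {
      s <- site_pi[site_pi$contig == g$contig & site_pi$pos >= g$start &
                     site_pi$pos <= g$end, , drop = FALSE]
      if (nrow(s) == 0) NA_real_ else mean(s$pi)
    }
  }
  tv <- vapply(target_genes, gene_value, numeric(1))
  bv <- vapply(background_genes, gene_value, numeric(1))
  tv <- tv[!is.na(tv)]; bv <- bv[!is.na(bv)]
  if (length(tv) < 3 || length(bv) < 3)
    stop("each group needs at least 3 genes with diversity values")
  nn <- length(tv) + length(bv)
  ties <- anyDuplicated(c(tv, bv)) > 0
  wt <- suppressWarnings(wilcox.test(tv, bv, exact = nn <= 30 && !ties,
                                     correct = TRUE))
  qs <- function(x) setNames(quantile(x, c(0.25, 0.5, 0.75)),
                             c("q1", "median", "q3"))
  list(target = tv, background = bv,
       summary = rbind(target = qs(tv), background = qs(bv)),
       p = wt$p.value)
}

#' Majority-rule consensus coding sequence
#'
#' Replaces the reference base by the most common allele across samples at
#' each variant site (avoiding reference bias before divergence estimation);
#' ties keep the reference. Alleles whose length differs from the reference
#' (indels) would shift the reading frame and are skipped with a warning.
#'
#' @param ref_cds reference coding sequence (character string, in frame).
#' @param variants a [variant_table()] with positions in the same coordinate
#'   frame as `ref_cds` (1-based within the sequence).
#' @return consensus sequence string.
#' @export
consensus_sequence <- function(ref_cds, variants) {
  seq <- toupper(ref_cds)
  if (n_sites(variants) == 0) return(seq)
  ac <- .allele_copies(variants$gt)
  for (i in seq_len(n_sites(variants))) {
    ref <- variants$sites$ref[i]; alt <- variants$sites$alt[i]
    pos <- variants$sites$pos[i]
    if (nchar(ref) != nchar(alt)) {
      warning("length-changing allele at position ", pos, " skipped")
      next
    }
    if (substr(seq, pos, pos + nchar(ref) - 1) != ref)
      warning("reference mismatch at position ", pos)
    if (ac$alt[i] > ac$total[i] - ac$alt[i])   # strict majority for alt
      seq <- paste0(substr(seq, 1, pos - 1), alt,
                    substr(seq, pos + nchar(alt), nchar(seq)))
  }
  seq
}

.perms <- list(`1` = list(1L),
               `2` = list(c(1L, 2L), c(2L, 1L)),
               `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

.codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

.syn_sites_codon <- function(codon) {
  # expected number of synonymous sites in one codon (of its 3 sites);
  # changes creating a stop count as nonsynonymous
  aa <- .codon_aa(codon)
  s <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                   substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- b
    if (.codon_aa(mut) == aa) s <- s + 1 / 3
  }
  s
}

.count_pathways <- function(ca, cb) {
  # pathway-averaged (Nd, Sd) between two codons; orderings passing through
  # a stop codon are excluded unless every ordering does
  diffpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(diffpos)
  if (d == 0) return(c(nd = 0, sd = 0))
  paths <- .perms[[as.character(d)]]
  tally <- function(ord, allow_stop) {
    cur <- ca; nd <- 0; sd <- 0
    for (p in diffpos[ord]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      a1 <- .codon_aa(cur); a2 <- .codon_aa(nxt)
      if (!allow_stop && (a1 == "*" || a2 == "*")) return(NULL)
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(paths, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

#' Nei-Gojobori (1986) Ka/Ks between two aligned coding sequences
#'
#' Synonymous/nonsynonymous site counts are averaged over the two sequences;
#' substitutions in multi-hit codons are classified by averaging over all
#' mutational pathways (orderings of the differing positions), excluding
#' pathways through premature stop codons when any stop-free pathway exists.
#' Proportions are Jukes-Cantor corrected (`K = -3/4 log(1 - 4/3 p)`, valid
#' for `p < 3/4`).
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame coding sequences
#'   (terminal stop codons may be present and are excluded from counting).
#' @return object of class `kaks_result`: `ka`, `ks`, `ratio`,
#'   `ratio_defined`, and the raw counts `Nd`, `Sd`, `N`, `S`, `pN`, `pS`.
#' @export
kaks_ng86 <- function(cds_a, cds_b) {
  a <- toupper(cds_a); b <- toupper(cds_b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3 != 0) stop("length not divisible by 3")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("sequences must be gap-free A/C/G/T")
  nc <- nchar(a) / 3
  cod_a <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cod_b <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  # drop a shared terminal stop; any other stop is an error
  if (nc > 1 && .codon_aa(cod_a[nc]) == "*" && .codon_aa(cod_b[nc]) == "*") {
    cod_a <- cod_a[-nc]; cod_b <- cod_b[-nc]; nc <- nc - 1
  }
  if (any(.codon_aa(cod_a) == "*") || any(.codon_aa(cod_b) == "*"))
    stop("internal stop codon")
  S <- (sum(vapply(cod_a, .syn_sites_codon, numeric(1))) +
          sum(vapply(cod_b, .syn_sites_codon, numeric(1)))) / 2
  N <- 3 * nc - S
  counts <- vapply(seq_len(nc), function(i)
    .count_pathways(cod_a[i], cod_b[i]), numeric(2))
  Nd <- sum(counts["nd", ]); Sd <- sum(counts["sd", ])
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  ka <- jc(pN); ks <- jc(pS)
  defined <- !is.na(ka) && !is.na(ks) && ks > 0
  structure(list(ka = ka, ks = ks,
                 ratio = if (defined) ka / ks else NA_real_,
                 ratio_defined = defined,
                 Nd = Nd, Sd = Sd, N = N, S = S, pN = pN, pS = pS),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("kaks_result: Ka=%.4g Ks=%.4g ratio=%s (Nd=%.2f Sd=%.2f N=%.1f S=%.1f)\n",
              x$ka, x$ks,
              if (x$ratio_defined) sprintf("%.4g", x$ratio) else "undefined",
              x$Nd, x$Sd, x$N, x$S))
  invisible(x)
}
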