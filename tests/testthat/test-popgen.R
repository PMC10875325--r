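test_that("windowed pi matches the vcftools per-site formula", {
  # 4 allele copies split 2/2 at one site: site pi = 2*2*2/(4*3) = 2/3,
  # diluted over a 100 bp window
  vt <- fixture_vt(50, matrix(c(5L, 5L), 1), matrix(c(5L, 5L), 1),
                   gt = matrix(c("0/1", "0/1"), 1))
  tr <- windowed_pi(vt, window = 100, step = 100,
                    contig_lengths = c(chrM = 100))
  expect_equal(tr$pi, (2 * 2 * 2 / (4 * 3)) / 100)
  expect_equal(tr$n_variants, 1)

  # window with no variants has pi 0
  tr2 <- windowed_pi(vt, window = 20, step = 20,
                     contig_lengths = c(chrM = 100))
  expect_equal(tr2$pi[1], 0)
  expect_equal(sum(tr2$pi > 0), 1)

  expect_error(windowed_pi(vt, window = 10, step = 20), "step")
})

test_that("windowed pi equals the direct pairwise-difference oracle", {
  set.seed(81)
  for (rep_i in 1:5) {
    n <- 8
    gt <- matrix(sample(c("0/0", "0/1", "1/1", NA), 10 * n, TRUE,
                        prob = c(.4, .3, .2, .1)), 10, n)
    dos <- matrix(0L, 10, n)
    dos[gt == "0/1"] <- 1L; dos[gt == "1/1"] <- 2L
    rc <- (2L - dos) * 5L; ac <- dos * 5L
    rc[is.na(gt)] <- NA; ac[is.na(gt)] <- NA
    vt <- variant_table(rep("chr1", 10), sort(sample.int(900, 10)),
                        rep("A", 10), rep("G", 10), rc, ac,
                        matrix(10L, 10, n), gt, paste0("S", 1:n))
    tr <- windowed_pi(vt, window = 1000, step = 1000,
                      contig_lengths = c(chr1 = 1000))
    expect_equal(tr$pi, oracle_window_pi(vt, 1, 1000), tolerance = 1e-12)
    # invariant to record order and sample relabeling
    perm <- sample(10)
    vt_shuf <- subset_sites(vt, perm)
    tr_shuf <- windowed_pi(vt_shuf, window = 1000, step = 1000,
                           contig_lengths = c(chr1 = 1000))
    expect_equal(tr_shuf$pi, tr$pi, tolerance = 1e-14)
  }
})

test_that("gene diversity contrast reproduces exact Wilcoxon results", {
  # genes mapped 1:1 onto windows with pi values 1..3 vs 4..6
  track <- data.frame(contig = "chr1",
                      start = seq(1, by = 100, length.out = 6),
                      end = seq(100, by = 100, length.out = 6),
                      n_variants = 1, pi = 1:6)
  genes <- data.frame(gene_id = sprintf("g%d", 1:6), contig = "chr1",
                      start = seq(10, by = 100, length.out = 6),
                      end = seq(20, by = 100, length.out = 6),
                      strand = "+", stringsAsFactors = FALSE)
  ann <- genome_annotation(genes)
  res <- gene_diversity_contrast(track, ann, sprintf("g%d", 1:3))
  expect_equal(unname(res$target), 1:3 + 0)
  expect_equal(res$p, 0.1)     # exact two-sided rank-sum p for (1,2,3)|(4,5,6)
  expect_equal(res$summary["target", "median"], 2)

  res_same <- gene_diversity_contrast(track, ann, sprintf("g%d", 1:6),
                                      background_genes = sprintf("g%d", 1:6))
  expect_gte(res_same$p, 0.99)
  expect_error(gene_diversity_contrast(track, ann, "g1"), "3 genes")
})

test_that("a planted diversity elevation is detected with high power", {
  set.seed(82)
  hits <- vapply(1:20, function(i) {
    m <- 350
    track <- data.frame(contig = "chr1",
                        start = seq(1, by = 100, length.out = m),
                        end = seq(100, by = 100, length.out = m),
                        n_variants = 1,
                        pi = rlnorm(m, log(0.002), 0.5))
    target <- sample(m, 50)
    track$pi[target] <- track$pi[target] * 2
    genes <- data.frame(gene_id = sprintf("g%d", 1:m), contig = "chr1",
                        start = track$start + 5, end = track$start + 20,
                        strand = "+", stringsAsFactors = FALSE)
    ann <- genome_annotation(genes)
    gene_diversity_contrast(track, ann, sprintf("g%d", target))$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("consensus replaces the reference only on a strict alt majority", {
  ref <- "ATGAAACCCGGG"
  expect_equal(consensus_sequence(ref, fixture_vt(integer(), matrix(NA_integer_, 0, 2),
                                                  matrix(NA_integer_, 0, 2))), ref)
  # 9 of 10 samples carry alt at pos 4 (A->G)
  gt_major <- matrix(c(rep("1/1", 9), "0/0"), 1)
  vt <- variant_table("cds", 4, "A", "G", matrix(c(rep(0L, 9), 10L), 1),
                      matrix(c(rep(10L, 9), 0L), 1), matrix(10L, 1, 10),
                      gt_major, paste0("S", 1:10))
  expect_equal(consensus_sequence(ref, vt), "ATGGAACCCGGG")
  # 50/50 tie keeps the reference
  gt_tie <- matrix(c(rep("1/1", 5), rep("0/0", 5)), 1)
  vt2 <- variant_table("cds", 4, "A", "G", matrix(c(rep(0L, 5), rep(10L, 5)), 1),
                       matrix(c(rep(10L, 5), rep(0L, 5)), 1),
                       matrix(10L, 1, 10), gt_tie, paste0("S", 1:10))
  expect_equal(consensus_sequence(ref, vt2), ref)
  # indel skipped with a warning
  vt3 <- variant_table("cds", 4, "A", "AT", matrix(0L, 1, 2),
                       matrix(8L, 1, 2), matrix(8L, 1, 2),
                       matrix("1/1", 1, 2), c("S1", "S2"))
  expect_warning(out <- consensus_sequence(ref, vt3), "skipped")
  expect_equal(out, ref)
})

test_that("NG86 handles the degenerate and single-substitution cases", {
  id <- kaks_ng86("ATGAAACCC", "ATGAAACCC")
  expect_equal(id$ka, 0)
  expect_equal(id$ks, 0)
  expect_false(id$ratio_defined)

  # TTT -> TTC is a synonymous third-position change
  r <- kaks_ng86("TTTGGG", "TTCGGG")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)

  # on a longer sequence the corrected rates behave as expected
  a <- "TTTGGGAAACCCATTGATCGA"
  b <- "TTCGGGAAACCCATTGATCGA"   # 1 synonymous difference
  r2 <- kaks_ng86(a, b)
  expect_gt(r2$ks, 0)
  expect_equal(r2$ka, 0)
  expect_true(r2$ratio_defined)
  expect_equal(r2$ratio, 0)       # purely synonymous divergence
  r3 <- kaks_ng86("ATGAAA", "ATGAGA")  # AAA->AGA  Lys->Arg, nonsynonymous
  expect_equal(r3$Nd, 1)
  expect_gt(r3$ka, 0)
  expect_equal(r3$ks, 0)

  expect_error(kaks_ng86("ATGTAAAAA", "ATGTACAAA"), "stop")
  expect_error(kaks_ng86("ATGA", "ATGA"), "divisible")
  expect_error(kaks_ng86("ATG", "ATGAAA"), "length")
  expect_error(kaks_ng86("AT-", "ATG"), "gap-free")
})

test_that("pathway counting matches exhaustive enumeration on random codons", {
  set.seed(83)
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  tried <- 0
  while (tried < 100) {
    ca <- paste(sample(bases, 3, TRUE), collapse = "")
    cb <- paste(sample(bases, 3, TRUE), collapse = "")
    if (code[[ca]] == "*" || code[[cb]] == "*") next
    tried <- tried + 1
    r <- kaks_ng86(ca, cb)
    o <- oracle_ng86_counts(ca, cb)
    expect_equal(r$Nd, unname(o["nd"]), tolerance = 1e-12)
    expect_equal(r$Sd, unname(o["sd"]), tolerance = 1e-12)
    # site counts partition the codon
    expect_equal(r$N + r$S, 3, tolerance = 1e-9)
  }
})

test_that("NG86 is symmetric in its arguments", {
  set.seed(84)
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  ok <- 0
  while (ok < 10) {
    a <- paste(sample(bases, 12, TRUE), collapse = "")
    b <- paste(sample(bases, 12, TRUE), collapse = "")
    cod <- function(s) substring(s, c(1, 4, 7, 10), c(3, 6, 9, 12))
    if (any(code[cod(a)] == "*") || any(code[cod(b)] == "*")) next
    ok <- ok + 1
    ra <- kaks_ng86(a, b); rb <- kaks_ng86(b, a)
    expect_equal(ra$Nd, rb$Nd)
    expect_equal(ra$Sd, rb$Sd)
    expect_equal(ra$N, rb$N)
  }
})
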