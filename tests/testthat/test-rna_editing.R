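editing_ann <- function() {
  genes <- data.frame(
    gene_id = c("nad7", "rps4"), contig = "chrM",
    start = c(100L, 2000L), end = c(900L, 2600L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("nad7", "nad7", "rps4"),
    transcript_id = c("nad7.t1", "nad7.t1", "rps4.t1"),
    contig = "chrM", start = c(100L, 500L, 2000L),
    end = c(250L, 900L, 2600L), strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  # nad7 exon1 spans 151 bases, so its second CDS segment has GFF phase 2
  cds <- cbind(exons, phase = c(0L, 2L, 0L))
  genome_annotation(genes, exons = exons, cds = cds)
}

test_that("codon positions honour strand, splicing and phase", {
  ann <- editing_ann()
  # + strand: CDS starts at 100
  expect_equal(codon_position("chrM", 100, ann), 1L)
  expect_equal(codon_position("chrM", 101, ann), 2L)
  expect_equal(codon_position("chrM", 102, ann), 3L)
  # - strand: CDS ends at 2600, transcription runs right to left
  expect_equal(codon_position("chrM", 2600, ann), 1L)
  expect_equal(codon_position("chrM", 2599, ann), 2L)
  expect_equal(codon_position("chrM", 2598, ann), 3L)
  # spliced: exon1 is 100..250 (151 bases); first base of exon2 (500) has
  # spliced offset 151 -> 151 %% 3 = 1 -> codon position 2 (hand count)
  expect_equal(codon_position("chrM", 500, ann), 2L)
  expect_equal(codon_position("chrM", 502, ann), 1L)
  expect_error(codon_position("chrM", 1500, ann), "not inside a CDS")
  # inconsistent phase annotation
  bad <- editing_ann()
  bad$cds$phase[2] <- 1L
  expect_error(codon_position("chrM", 500, bad), "inconsistent")
})

test_that("phase offsets shift the codon frame", {
  genes <- data.frame(gene_id = "g", contig = "c", start = 10L, end = 30L,
                      strand = "+", stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = "g", transcript_id = "g.t1", contig = "c",
                    start = 10L, end = 30L, strand = "+", phase = 2L,
                    stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, cds = cds)
  # bases 10,11 are phase overhang; first full codon starts at 12
  expect_equal(codon_position("c", 12, ann), 1L)
  expect_equal(codon_position("c", 14, ann), 3L)
})

test_that("the caller applies replicate-consensus, WGS and strand rules", {
  ann <- editing_ann()
  sites <- data.frame(contig = "chrM", pos = c(150L, 300L, 2100L, 550L),
                      strand = c("+", "+", "-", "+"),
                      stringsAsFactors = FALSE)
  ed <- simulate_editing_data(sites, wt_efficiency = c(0.9, 0.5, 0.7, 0.3),
                              mut_efficiency = 0.5, depth = 60, seed = 91)
  called <- call_editing_sites(ed$wt, ed$wgs, ann)
  # exactly the planted recoverable sites, nothing else
  truth <- ed$truth[ed$truth$recoverable, ]
  expect_setequal(called$pos, truth$pos)
  decoys <- ed$truth[!ed$truth$recoverable, ]
  expect_false(any(decoys$pos %in% called$pos))
  # feature classes: 150 in CDS, 300 in the intron (251..499), 550 in CDS
  expect_equal(called$feature[called$pos == 150], "CDS")
  expect_equal(called$feature[called$pos == 300], "intron")
  expect_true(is.na(called$codon_pos[called$pos == 300]))
  expect_equal(called$codon_pos[called$pos == 150],
               codon_position("chrM", 150, ann))
  expect_error(call_editing_sites(ed$wt[1:2], ed$wgs, ann), "expected 3")
})

test_that("efficiencies are read ratios with an unweighted condition mean", {
  e1 <- editing_efficiency(50, 50)
  expect_equal(e1$mean, 1)
  e2 <- editing_efficiency(c(10, 20, 30), c(40, 40, 40))
  expect_equal(e2$per_replicate, c(0.25, 0.5, 0.75))
  expect_equal(e2$mean, 0.5)
  expect_equal(editing_efficiency(0, 30)$mean, 0)
  e4 <- editing_efficiency(c(5, 0), c(10, 0))
  expect_false(e4$quantifiable)
  expect_true(is.na(e4$mean))
  expect_error(editing_efficiency(9, 5), "exceeds")
})

test_that("differential calls flag exactly the configured threshold", {
  ann <- editing_ann()
  sites <- data.frame(contig = "chrM", pos = c(150L, 300L, 2100L),
                      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  ed <- simulate_editing_data(sites, wt_efficiency = c(0.9, 0.8, 0.8),
                              mut_efficiency = c(0.6, 0.8, 0.5),
                              depth = 5000, seed = 92)
  wt <- call_editing_sites(ed$wt, ed$wgs, ann)
  mut <- call_editing_sites(ed$mut, ed$wgs, ann)
  cmp <- compare_conditions(wt, mut, min_abs_diff = 0.10)
  expect_equal(cmp$flagged, abs(cmp$difference) >= 0.10)
  expect_equal(cmp$flagged[cmp$pos == 150], TRUE)
  expect_equal(cmp$direction[cmp$pos == 150], "down")
  expect_equal(cmp$flagged[cmp$pos == 300], FALSE)
  # empty intersection warns and returns nothing
  expect_warning(out <- compare_conditions(wt[0, ], mut), "no shared")
  expect_equal(nrow(out), 0)
})

test_that("planted editing shifts are recovered and decoys stay quiet", {
  ann <- editing_ann()
  sites <- data.frame(contig = "chrM",
                      pos = c(150L, 200L, 2100L, 2200L),
                      strand = c("+", "+", "-", "-"),
                      stringsAsFactors = FALSE)
  # no-shift decoys sit at the high efficiencies typical of constitutive
  # plant C-to-U sites, where binomial noise at depth 50 stays well inside
  # the 0.10 decision band
  shifted <- c(TRUE, FALSE, TRUE, FALSE)
  flags <- matrix(NA, 20, 4)
  for (s in 1:20) {
    ed <- simulate_editing_data(sites,
                                wt_efficiency = c(0.8, 0.9, 0.9, 0.85),
                                mut_efficiency = c(0.5, 0.9, 0.6, 0.85),
                                depth = 50, seed = 400 + s)
    cmp <- compare_conditions(call_editing_sites(ed$wt, ed$wgs, ann),
                              call_editing_sites(ed$mut, ed$wgs, ann),
                              min_abs_diff = 0.10)
    flags[s, ] <- cmp$flagged[match(sites$pos, cmp$pos)]
  }
  expect_gte(mean(flags[, shifted]), 0.95)   # planted 0.3 shifts recovered
  expect_lt(mean(flags[, !shifted]), 0.05)   # no-shift decoys quiet
})

test_that("mirrored coordinates leave the called site set invariant", {
  ann <- editing_ann()
  sites <- data.frame(contig = "chrM", pos = c(150L, 2100L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  ed <- simulate_editing_data(sites, 0.8, 0.8, depth = 60, decoys = FALSE,
                              seed = 93)
  L <- 3000L
  flip_pos <- function(p) L + 1L - p
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip_strand <- function(s) ifelse(s == "+", "-", "+")
  flip_vt <- function(vt) {
    variant_table(vt$sites$contig, flip_pos(vt$sites$pos),
                  unname(comp[vt$sites$ref]), unname(comp[vt$sites$alt]),
                  vt$ref_count, vt$alt_count, vt$total_depth, vt$gt,
                  vt$samples)
  }
  flip_ann <- function(a) {
    g <- a$genes; e <- a$exons; cd <- a$cds
    sw <- function(df) {
      s <- flip_pos(df$end); df$end <- flip_pos(df$start); df$start <- s
      df$strand <- flip_strand(df$strand); df
    }
    genome_annotation(sw(g), exons = sw(e),
                      cds = { x <- sw(cd); x$phase <- cd$phase; x })
  }
  orig <- call_editing_sites(ed$wt, NULL, ann)
  flipped <- call_editing_sites(lapply(ed$wt, flip_vt), NULL, flip_ann(ann))
  expect_setequal(flip_pos(flipped$pos), orig$pos)
  expect_equal(nrow(flipped), nrow(orig))
})
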