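test_that("nuclear SNP filter enforces MAF and missingness rules", {
  set.seed(51)
  n <- 60
  g <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  # plant violations: 3 low-MAF, 4 over-missing
  g[, 1:3] <- rbinom(n * 3, 2, 0.015)
  for (j in 4:7) g[sample(n, ceiling(0.41 * n)), j] <- NA
  stopifnot(colMeans(g[, 1:3], na.rm = TRUE) / 2 < 0.05)
  geno <- filter_nuclear_snps(list(genotypes = g,
                                   info = data.frame(contig = "chr1",
                                                     pos = 1:100)))
  expect_equal(ncol(geno$genotypes), 93)
  expect_equal(geno$info$pos, 8:100)
  expect_error(filter_nuclear_snps(list(genotypes = g, info = NULL),
                                   min_maf = 0.9), "no SNP survives")
})

test_that("IBS kinship matches the definition and its brute-force oracle", {
  g2 <- rbind(rep(0, 6), rep(2, 6))
  K2 <- compute_kinship(g2)
  expect_equal(K2[1, 2], 0)       # maximal IBS distance
  K1 <- compute_kinship(rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(1, 0, 2, 2)))
  expect_equal(K1[1, 2], 1)       # identical genotype vectors

  set.seed(52)
  gr <- matrix(sample(c(0, 1, 2, NA), 20 * 50, TRUE,
                      prob = c(.3, .3, .3, .1)), 20, 50)
  Kr <- compute_kinship(gr)
  attributes(Kr) <- attributes(Kr)["dim"]
  expect_equal(Kr, oracle_ibs(gr), tolerance = 1e-12)
  expect_error(compute_kinship(gr[, 1, drop = FALSE]), "2 SNPs")
})

test_that("spectral REML equals the dense-matrix likelihood", {
  set.seed(53)
  n <- 12
  g <- matrix(rbinom(n * 60, 2, 0.4), n, 60)
  K <- compute_kinship(g)
  y <- drop(chol(K + diag(0.2, n)) %*% rnorm(n))
  X <- matrix(1, n, 1)
  vc <- estimate_variance_components(y, K = K)
  # spectral profile likelihood vs direct determinant evaluation
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  M <- S %*% K %*% S
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  xi <- pmax(es$values[1:(n - 1)], 0)
  eta <- drop(crossprod(es$vectors[, 1:(n - 1)], y))
  spec_ll <- function(d) 0.5 * ((n - 1) * log((n - 1) / (2 * pi)) - (n - 1) -
                                  (n - 1) * log(sum(eta^2 / (xi + d))) -
                                  sum(log(xi + d)))
  for (d in 10^seq(-3, 3, length.out = 10))
    expect_equal(spec_ll(d), oracle_reml_ll(y, X, K, d), tolerance = 1e-6)
  # the fitted optimum beats every dense-likelihood grid value
  dense_best <- max(vapply(10^seq(-5, 5, length.out = 60), function(d)
    oracle_reml_ll(y, X, K, d), numeric(1)))
  expect_gte(vc$reml_loglik + 1e-8, dense_best)
})

test_that("pure-noise traits drive the variance ratio to the boundary", {
  set.seed(54)
  panel <- fixture_panel(seed = 54, n = 80, m = 400)
  K <- compute_kinship(panel$pop$genotypes)
  sg <- vapply(1:20, function(i) {
    y <- rnorm(80)
    vc <- estimate_variance_components(y, K = K)
    vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2)
  }, numeric(1))
  expect_lt(median(sg), 0.05)
})

test_that("with identity kinship the fitted total variance tracks var(y)", {
  set.seed(55)
  ratio <- vapply(1:100, function(i) {
    y <- rnorm(60, sd = 2)
    vc <- estimate_variance_components(y, K = diag(60))
    (vc$sigma_g2 + vc$sigma_e2) / var(y)
  }, numeric(1))
  expect_lt(abs(median(ratio) - 1), 0.1)
})

test_that("variance component estimation rejects degenerate inputs", {
  expect_error(estimate_variance_components(rep(1, 10), K = diag(10)),
               "constant")
  expect_error(estimate_variance_components(c(1, NA, 2), K = diag(3)),
               "missing")
  K_bad <- diag(5); K_bad[1, 2] <- K_bad[2, 1] <- 3
  expect_error(estimate_variance_components(rnorm(5), K = K_bad),
               "positive semidefinite")
})

test_that("the scan reduces to per-SNP OLS when K = I with no genetic variance", {
  set.seed(56)
  n <- 50; m <- 40
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rnorm(n)
  res <- gls_scan(y, K = diag(n), vc = list(sigma_g2 = 0, sigma_e2 = 1),
                  genotypes = G)
  for (j in seq_len(m)) {
    ols <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(res$p[j], ols[2, 4], tolerance = 1e-8)
    expect_equal(res$beta[j], ols[2, 1], tolerance = 1e-8)
  }
})

test_that("the scan equals dense per-SNP GLS on small structured fixtures", {
  set.seed(57)
  n <- 18
  panel <- fixture_panel(seed = 57, n = n, m = 150)
  G <- panel$pop$genotypes
  G[is.na(G)] <- 1
  K <- compute_kinship(G)
  y <- drop(chol(0.5 * K + 0.5 * diag(n) + diag(1e-8, n)) %*% rnorm(n))
  vc <- estimate_variance_components(y, K = K)
  res <- gls_scan(y, K = K, vc = vc, genotypes = G[, 1:25])
  X <- matrix(1, n, 1)
  for (j in 1:25) {
    if (!is.na(res$skipped[j])) next
    o <- oracle_gls(y, X, K, vc, G[, j])
    expect_equal(res$beta[j], o$beta, tolerance = 1e-8)
    expect_equal(res$se[j], o$se, tolerance = 1e-8)
    expect_equal(res$p[j], o$p, tolerance = 1e-8)
  }
})

test_that("monomorphic SNPs are skipped with a reason, not tested", {
  set.seed(58)
  n <- 40
  G <- cbind(rep(1, n), matrix(rbinom(n * 5, 2, 0.4), n, 5))
  y <- rnorm(n)
  res <- gls_scan(y, K = diag(n), vc = list(sigma_g2 = 0.1, sigma_e2 = 1),
                  genotypes = G)
  expect_equal(res$skipped[1], "zero_genotype_variance")
  expect_true(is.na(res$p[1]))
  expect_true(all(is.na(res$skipped[-1])))
})

test_that("permuted-phenotype null p-values are calibrated", {
  set.seed(59)
  panel <- fixture_panel(seed = 59, n = 200, m = 2000)
  cfg <- panel$cfg; pop <- panel$pop
  fr <- simulate_mito_fractions(pop$genotypes, cfg)
  y <- fr[1, ]
  y <- sample(y)                      # break any genotype link
  geno <- filter_nuclear_snps(list(genotypes = pop$genotypes,
                                   info = pop$info))
  K <- compute_kinship(geno$genotypes)
  vc <- estimate_variance_components(y, K = K)
  res <- gls_scan(y, K = K, vc = vc, genotypes = geno$genotypes,
                  info = geno$info)
  # reduced-size sanity band; the full-scale calibration check runs at the
  # study conditions in the acceptance suite
  expect_gt(mean(res$p < 0.05, na.rm = TRUE), 0.025)
  expect_lt(mean(res$p < 0.05, na.rm = TRUE), 0.075)
})

test_that("run_gwas loops phenotypes with aligned outputs and isolation", {
  set.seed(60)
  panel <- fixture_panel(seed = 60, n = 100, m = 300, causal = 150,
                         beta = 0.25)
  cfg <- panel$cfg; pop <- panel$pop
  cfg$n_mito_variants <- 3
  fr <- simulate_mito_fractions(pop$genotypes, cfg)
  vt <- simulate_read_counts(fr, 100, seed = 61)
  pheno <- build_phenotype_matrix(vt)
  geno <- filter_nuclear_snps(list(genotypes = pop$genotypes,
                                   info = pop$info))
  K <- compute_kinship(geno$genotypes)
  g <- run_gwas(pheno, geno, K)
  expect_equal(length(g$results), 3)
  snp_sets <- lapply(g$results, function(r) paste(r$contig, r$pos))
  expect_true(all(vapply(snp_sets, identical, logical(1), snp_sets[[1]])))

  # affine transformation of the phenotype leaves p-values unchanged
  y <- pheno[1, ]; idx <- !is.na(y)
  vc1 <- estimate_variance_components(y[idx], K = K[idx, idx])
  r1 <- gls_scan(y[idx], K = K[idx, idx], vc = vc1,
                 genotypes = geno$genotypes[idx, ])
  y2 <- 3.7 * y - 1.2
  vc2 <- estimate_variance_components(y2[idx], K = K[idx, idx])
  r2 <- gls_scan(y2[idx], K = K[idx, idx], vc = vc2,
                 genotypes = geno$genotypes[idx, ])
  expect_equal(r1$p, r2$p, tolerance = 1e-10)

  # phenotypes with too few observations are skipped with a warning
  pheno_bad <- pheno
  pheno_bad[2, -(1:10)] <- NA
  expect_warning(g2 <- run_gwas(pheno_bad, geno, K), "skipped")
  expect_equal(length(g2$results), 2)
  expect_equal(unname(g2$skipped), "too_few_samples")
})

test_that("binarized bimodal phenotypes find the same lead SNP as continuous", {
  set.seed(62)
  panel <- fixture_panel(seed = 62, n = 200, m = 500)
  pop <- panel$pop
  causal <- choose_causal_snp(pop)
  g <- pop$genotypes[, causal]
  g[is.na(g)] <- round(mean(g, na.rm = TRUE))
  # bimodal heteroplasmy: near-zero baseline, near-one with >= 1 causal copy
  y <- ifelse(g >= 1, rbeta(200, 40, 2), rbeta(200, 2, 40))
  geno <- filter_nuclear_snps(list(genotypes = pop$genotypes,
                                   info = pop$info))
  K <- compute_kinship(geno$genotypes)
  vc_c <- estimate_variance_components(y, K = K)
  lead_c <- function(r) r$pos[which.min(r$p)]
  rc <- gls_scan(y, K = K, vc = vc_c, genotypes = geno$genotypes,
                 info = geno$info)
  yb <- drop(binarize(matrix(y, 1)))
  idx <- !is.na(yb)
  vc_b <- estimate_variance_components(yb[idx], K = K[idx, idx])
  rb <- gls_scan(yb[idx], K = K[idx, idx], vc = vc_b,
                 genotypes = geno$genotypes[idx, ], info = geno$info)
  expect_equal(lead_c(rb), lead_c(rc))
  expect_equal(lead_c(rc), pop$info$pos[causal])
})

test_that("genomic control lambda is the median chi-square ratio", {
  assoc <- data.frame(t = qnorm(seq(0.001, 0.999, length.out = 999)))
  expect_equal(genomic_lambda(assoc), median(assoc$t^2) / qchisq(0.5, 1))
})
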