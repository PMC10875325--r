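#' Filter a nuclear SNP panel on missingness and MAF
#'
#' SNPs with a missing-genotype fraction above `max_missing` or a minor
#' allele frequency below `min_maf` are removed (strict inequalities:
#' missing > 40% and MAF < 0.05 are the removal conditions).
#'
#' @param geno list with `genotypes` (individuals x SNPs dosage matrix,
#'   `NA` = missing) and `info` (per-SNP data.frame), as produced by
#'   [simulate_population()] or [as_dosage()].
#' @param max_missing maximum tolerated missing fraction (default 0.40).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return `geno` restricted to the surviving SNPs.
#' @export
filter_nuclear_snps <- function(geno, max_missing = 0.40, min_maf = 0.05) {
  g <- geno$genotypes
  miss <- colMeans(is.na(g))
  f <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  keep <- miss <= max_missing & maf >= min_maf
  if (!any(keep))
    stop("no SNP survives filtering (", sum(miss > max_missing),
         " over-missing, ", sum(maf < min_maf), " low-MAF of ", ncol(g), ")")
  list(genotypes = g[, keep, drop = FALSE],
       info = geno$info[keep, , drop = FALSE])
}

#' Kinship matrix from nuclear genotypes
#'
#' Default is identity-by-state: `K_ij = 1 - mean_s |g_is - g_js| / 2` over
#' SNPs, after per-SNP mean imputation of missing dosages (the convention of
#' the EMMAX kinship tool). A centered (VanRaden) relationship matrix is
#' available behind `method = "centered"`. The result is symmetrized and any
#' negative eigenvalues are clipped at zero so the downstream variance
#' component model sees a positive semidefinite matrix.
#'
#' The IBS sum is computed by decomposing `|a - b|` over genotype-category
#' indicator matrices, so the cost is a handful of BLAS products rather than
#' an `O(n^2 m)` loop.
#'
#' @param genotypes individuals x SNPs dosage matrix (0/1/2, `NA` missing).
#' @param method `"ibs"` (default) or `"centered"`.
#' @return n x n kinship matrix with attribute `method`.
#' @export
compute_kinship <- function(genotypes, method = c("ibs", "centered")) {
  method <- match.arg(method)
  g <- as.matrix(genotypes)
  n <- nrow(g); m <- ncol(g)
  if (m < 2) stop("need at least 2 SNPs")
  if (method == "centered") {
    p <- colMeans(g, na.rm = TRUE) / 2
    Z <- sweep(g, 2, 2 * p)
    Z[is.na(Z)] <- 0
    K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  } else {
    mns <- colMeans(g, na.rm = TRUE)
    miss <- is.na(g)
    ind <- function(b) { x <- (!miss) & (g == b); x[is.na(x)] <- FALSE
                         storage.mode(x) <- "double"; x }
    A0 <- ind(0); A1 <- ind(1); A2 <- ind(2)
    M <- miss; storage.mode(M) <- "double"
    D <- matrix(0, n, n)
    B <- (A0 + A2) %*% t(A1);  D <- D + B + t(B)
    B <- A0 %*% t(A2);         D <- D + 2 * (B + t(B))
    for (b in 0:2) {
      w <- abs(mns - b)
      Ab <- list(A0, A1, A2)[[b + 1]]
      B <- (M * rep(w, each = n)) %*% t(Ab)
      D <- D + B + t(B)
    }
    K <- 1 - D / (2 * m)
  }
  K <- (K + t(K)) / 2
  es <- eigen(K, symmetric = TRUE)
  if (es$values[n] < 0) {
    if (es$values[n] < -1e-6)
      warning("kinship has eigenvalue ", signif(es$values[n], 3),
              "; clipping to 0")
    v <- pmax(es$values, 0)
    K <- es$vectors %*% (v * t(es$vectors))
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- list(rownames(g), rownames(g))
  attr(K, "method") <- method
  K
}

#' REML variance components of the kinship mixed model
#'
#' Fits `y = X b + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood, profiling the
#' variance ratio `delta = sigma_e^2 / sigma_g^2`. One eigendecomposition of
#' the projected kinship `S K S` (with `S` the residual-maker of `X`) turns
#' the REML log-likelihood into a cheap one-dimensional function of `delta`,
#' which is maximized on a 100-point grid over `log10(delta) in [-5, 5]`
#' followed by local refinement; an optimum pinned at a grid edge is
#' reported via the `boundary` flag (e.g. a pure-noise trait drifts to the
#' upper edge, i.e. `sigma_g^2 ~ 0`).
#'
#' @param y numeric phenotype vector (no missing values; subset first).
#' @param X covariate matrix; default intercept-only.
#' @param K kinship matrix matching `y`.
#' @param grid_points grid resolution (default 100).
#' @return object of class `variance_components` with fields `sigma_g2`,
#'   `sigma_e2`, `delta`, `reml_loglik`, `boundary`.
#' @export
estimate_variance_components <- function(y, X = NULL, K,
                                         grid_points = 100) {
  n <- length(y)
  if (anyNA(y)) stop("y contains missing values; drop them first")
  if (sd(y) == 0) stop("constant phenotype")
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)
  if (n <= q) stop("more covariates than samples")
  stopifnot(nrow(K) == n, ncol(K) == n)
  Kmin <- min(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (Kmin < -1e-6) stop("K is not positive semidefinite (min eig ",
                         signif(Kmin, 3), ")")
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  M <- S %*% K %*% S
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  xi <- pmax(es$values[seq_len(n - q)], 0)
  eta <- drop(crossprod(es$vectors[, seq_len(n - q), drop = FALSE], y))
  ll <- function(log10d) {
    d <- 10^log10d
    r <- sum(eta^2 / (xi + d))
    0.5 * ((n - q) * log((n - q) / (2 * pi)) - (n - q) -
             (n - q) * log(r) - sum(log(xi + d)))
  }
  grid <- seq(-5, 5, length.out = grid_points)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_points, i + 1)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  log10d <- if (opt$objective > vals[i]) opt$maximum else grid[i]
  boundary <- log10d < -5 + 1e-3 || log10d > 5 - 1e-3
  delta <- 10^log10d
  sigma_g2 <- sum(eta^2 / (xi + delta)) / (n - q)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
                 delta = delta, reml_loglik = ll(log10d),
                 boundary = boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance_components: sigma_g2=%.4g sigma_e2=%.4g delta=%.4g loglik=%.3f%s\n",
    x$sigma_g2, x$sigma_e2, x$delta, x$reml_loglik,
    if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' EMMAX-style generalized least squares scan over nuclear SNPs
#'
#' Variance components are fixed at the no-SNP null fit (`vc`), the model is
#' rotated once by `Sigma^{-1/2}` with `Sigma = sigma_g2 K + sigma_e2 I`,
#' and each SNP (mean-imputed per SNP) is tested as an added regressor by
#' ordinary least squares in the rotated space: a two-sided t test with
#' `n - q - 1` degrees of freedom. SNPs with zero genotype variance after
#' imputation are reported as skipped rather than tested.
#'
#' @param y phenotype vector (no missing values).
#' @param X covariate matrix; default intercept-only.
#' @param K kinship matrix.
#' @param vc a [estimate_variance_components()] fit.
#' @param genotypes individuals x SNPs dosage matrix aligned with `y`.
#' @param info optional per-SNP data.frame with `contig` and `pos`.
#' @return data.frame (one row per SNP): contig, pos, beta, se, t, p,
#'   neglog10p, n, maf, skipped.
#' @export
gls_scan <- function(y, X = NULL, K, vc, genotypes, info = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)
  G <- as.matrix(genotypes)
  stopifnot(nrow(G) == n, nrow(K) == n)
  f <- colMeans(G, na.rm = TRUE)
  maf <- pmin(f / 2, 1 - f / 2)
  for (j in which(colSums(is.na(G)) > 0))
    G[is.na(G[, j]), j] <- f[j]
  es <- eigen((K + t(K)) / 2, symmetric = TRUE)
  w <- 1 / sqrt(vc$sigma_g2 * pmax(es$values, 0) + vc$sigma_e2)
  Ut <- t(es$vectors)
  ys <- w * drop(Ut %*% y)
  Xs <- w * (Ut %*% X)
  Gs <- w * (Ut %*% G)
  qrX <- qr(Xs)
  ry <- qr.resid(qrX, ys)
  RG <- qr.resid(qrX, Gs)
  gg <- colSums(RG^2)
  ok <- gg > 1e-10 * max(gg, 1)
  beta <- se <- tstat <- p <- nl10 <- rep(NA_real_, ncol(G))
  df <- n - q - 1
  gy <- colSums(RG * ry)
  beta[ok] <- gy[ok] / gg[ok]
  rss <- pmax(sum(ry^2) - beta[ok]^2 * gg[ok], 0)
  se[ok] <- sqrt(rss / df / gg[ok])
  tstat[ok] <- beta[ok] / se[ok]
  p[ok] <- 2 * pt(-abs(tstat[ok]), df)
  p[ok] <- pmax(p[ok], .Machine$double.xmin)
  nl10[ok] <- -(pt(abs(tstat[ok]), df, lower.tail = FALSE, log.p = TRUE) +
                  log(2)) / log(10)
  if (is.null(info)) {
    key <- colnames(G) %||% paste0("snp:", seq_len(ncol(G)))
    parts <- strsplit(key, ":", fixed = TRUE)
    info <- data.frame(
      contig = vapply(parts, `[`, character(1), 1),
      pos = suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2))),
      stringsAsFactors = FALSE)
    if (anyNA(info$pos)) info$pos <- seq_len(ncol(G))
  }
  data.frame(contig = info$contig, pos = info$pos,
             beta = beta, se = se, t = tstat, p = p, neglog10p = nl10,
             n = n, maf = maf,
             skipped = ifelse(ok, NA_character_, "zero_genotype_variance"),
             stringsAsFactors = FALSE)
}

#' Run the mitonuclear association scan for every mitochondrial phenotype
#'
#' Loops [estimate_variance_components()] plus [gls_scan()] over the rows of
#' the phenotype matrix (continuous fractions or their binarized version).
#' Samples missing a phenotype are dropped for that variant, and the kinship
#' is subset accordingly. A failure in one phenotype's fit is isolated: it
#' is recorded and the remaining phenotypes still run.
#'
#' @param pheno phenotype matrix, mito variants x samples.
#' @param geno list with `genotypes` (samples x SNPs) and `info`.
#' @param K kinship matrix; computed from the genotypes when `NULL`.
#' @param min_samples minimum non-missing samples per phenotype (default
#'   30); phenotypes below it are skipped with a warning.
#' @return object of class `gwas_result`: list with `results` (named list of
#'   association data.frames), `vc` (variance components per phenotype) and
#'   `skipped` (named reasons).
#' @export
run_gwas <- function(pheno, geno, K = NULL, min_samples = 30) {
  G <- geno$genotypes
  if (!is.null(colnames(pheno)) && !is.null(rownames(G))) {
    if (!all(colnames(pheno) %in% rownames(G)))
      stop("phenotype samples missing from genotype matrix")
    G <- G[colnames(pheno), , drop = FALSE]
  } else if (ncol(pheno) != nrow(G))
    stop("sample dimension mismatch between phenotypes and genotypes")
  if (is.null(K)) K <- compute_kinship(G)
  results <- list(); vcs <- list(); skipped <- character()
  for (v in seq_len(nrow(pheno))) {
    id <- rownames(pheno)[v] %||% paste0("pheno", v)
    y <- pheno[v, ]
    idx <- which(!is.na(y))
    if (length(idx) < min_samples) {
      warning("phenotype ", id, ": only ", length(idx),
              " non-missing samples; skipped")
      skipped[id] <- "too_few_samples"
      next
    }
    res <- tryCatch({
      vc <- estimate_variance_components(y[idx],
                                         K = K[idx, idx, drop = FALSE])
      list(vc = vc,
           tab = gls_scan(y[idx], K = K[idx, idx, drop = FALSE], vc = vc,
                          genotypes = G[idx, , drop = FALSE],
                          info = geno$info))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("phenotype ", id, " failed: ", conditionMessage(res))
      skipped[id] <- conditionMessage(res)
    } else {
      results[[id]] <- res$tab
      vcs[[id]] <- res$vc
    }
  }
  structure(list(results = results, vc = vcs, skipped = skipped),
            class = "gwas_result")
}

#' Genomic-control inflation factor
#'
#' `lambda = median(t^2) / qchisq(0.5, 1)`: the ratio of the observed median
#' association chi-square to its null expectation. Values near 1 indicate a
#' calibrated scan; inflation above ~1.2 is the classic stratification
#' signature the kinship term is there to remove.
#'
#' @param assoc an association data.frame from [gls_scan()].
#' @return numeric lambda.
#' @export
genomic_lambda <- function(assoc) {
  t2 <- assoc$t[!is.na(assoc$t)]^2
  median(t2) / qchisq(0.5, 1)
}
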