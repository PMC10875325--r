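# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (dense linear algebra, explicit loops,
# exhaustive enumeration) and never call the implementation paths they check.

# O(n^2 m) IBS kinship with per-SNP mean imputation
oracle_ibs <- function(g) {
  mns <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mns[j]
  n <- nrow(g)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- 1 - mean(abs(g[i, ] - g[j, ])) / 2
  K
}

# dense REML log-likelihood (determinant form, incl. the log|X'X| constant)
oracle_reml_ll <- function(y, X, K, delta) {
  n <- length(y); q <- ncol(X)
  H <- K + delta * diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  P <- Hi - Hi %*% X %*% solve(XtHiX, t(X) %*% Hi)
  as.numeric(0.5 * ((n - q) * log((n - q) / (2 * pi)) - (n - q) -
                (n - q) * log(t(y) %*% P %*% y) -
                determinant(H)$modulus -
                determinant(XtHiX)$modulus +
                determinant(crossprod(X))$modulus))

}

# per-SNP dense GLS with estimated residual scale (matches a t test with
# n - q - 1 df after the EMMAX rotation)
oracle_gls <- function(y, X, K, vc, g_snp) {
  n <- length(y)
  Sigma <- vc$sigma_g2 * K + vc$sigma_e2 * diag(n)
  Si <- solve(Sigma)
  Z <- cbind(X, g_snp)
  A <- solve(t(Z) %*% Si %*% Z)
  b <- A %*% t(Z) %*% Si %*% y
  r <- y - Z %*% b
  df <- n - ncol(Z)
  s2 <- drop(t(r) %*% Si %*% r) / df
  j <- ncol(Z)
  se <- sqrt(s2 * A[j, j])
  tt <- b[j] / se
  list(beta = b[j], se = se, t = tt, p = 2 * pt(-abs(tt), df))
}

# Hudson Fst estimator (ratio of averages) for two subpopulations
oracle_hudson_fst <- function(g, subpop) {
  stopifnot(length(unique(subpop)) == 2)
  i1 <- subpop == unique(subpop)[1]
  num <- den <- numeric(ncol(g))
  for (s in seq_len(ncol(g))) {
    x1 <- g[i1, s]; x2 <- g[!i1, s]
    n1 <- 2 * sum(!is.na(x1)); n2 <- 2 * sum(!is.na(x2))
    p1 <- sum(x1, na.rm = TRUE) / n1; p2 <- sum(x2, na.rm = TRUE) / n2
    num[s] <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den[s] <- p1 * (1 - p2) + p2 * (1 - p1)
  }
  sum(num) / sum(den)
}

# window diversity as the literal mean of per-pair per-bp differences:
# expand every sample's genotype into allele copies and compare all pairs
oracle_window_pi <- function(vt, start, end) {
  sel <- which(vt$sites$pos >= start & vt$sites$pos <= end)
  total <- 0
  for (i in sel) {
    gt <- vt$gt[i, ]
    copies <- unlist(lapply(gt[!is.na(gt)], function(s)
      strsplit(gsub("[|/]", "", s), "")[[1]]))
    n <- length(copies)
    if (n < 2) next
    diff <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      diff <- diff + (copies[a] != copies[b])
    total <- total + diff / choose(n, 2)
  }
  unname(total / (end - start + 1))
}

# exhaustive NG86 substitution-pathway counts between two codons
oracle_ng86_counts <- function(ca, cb) {
  code <- Biostrings::GENETIC_CODE
  d <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(d) == 0) return(c(nd = 0, sd = 0))
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  walk <- function(ord, allow) {
    cur <- ca; nd <- 0; sd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (!allow && (code[[cur]] == "*" || code[[nxt]] == "*")) return(NULL)
      if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  res <- Filter(Negate(is.null), lapply(perm(d), walk, allow = FALSE))
  if (length(res) == 0) res <- lapply(perm(d), walk, allow = TRUE)
  colMeans(do.call(rbind, res))
}

# brute-force interval overlap scan
oracle_overlapping_genes <- function(genes, contig, start, end) {
  hits <- character()
  for (i in seq_len(nrow(genes)))
    if (genes$contig[i] == contig && genes$start[i] <= end &&
        genes$end[i] >= start)
      hits <- c(hits, genes$gene_id[i])
  hits
}

# brute-force clustering of above-threshold SNPs
oracle_signal_spans <- function(assoc, threshold, max_gap) {
  hits <- assoc[!is.na(assoc$neglog10p) & assoc$neglog10p > threshold, ]
  spans <- list()
  for (ct in sort(unique(hits$contig))) {
    ps <- sort(hits$pos[hits$contig == ct])
    cur <- c(ps[1], ps[1])
    for (p in ps[-1]) {
      if (p - cur[2] <= max_gap) cur[2] <- p
      else { spans <- c(spans, list(c(ct, cur))); cur <- c(p, p) }
    }
    spans <- c(spans, list(c(ct, cur)))
  }
  spans
}
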