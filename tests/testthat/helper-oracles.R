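# independent brute-force oracles; deliberately naive implementations kept
# apart from the package's code paths

# two-pass Pearson correlation matrix
oracleCor <- function(m) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- m[i, ]; xj <- m[j, ]
    ci <- xi - sum(xi) / length(xi)
    cj <- xj - sum(xj) / length(xj)
    out[i, j] <- sum(ci * cj) / sqrt(sum(ci^2) * sum(cj^2))
  }
  out
}

# triple-loop topological overlap
oracleTom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# loop connectivity
oracleConnectivity <- function(a) {
  vapply(seq_len(nrow(a)), function(i) sum(a[i, -i]), 0)
}

# naive UPGMA returning the cophenetic matrix
oracleUpgmaCophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  dm <- d
  coph <- matrix(0, n, n)
  sizes <- rep(1L, n)
  idx <- seq_len(n)
  dmat <- dm
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    best <- c(NA, NA); bestd <- Inf
    for (a in act) for (b in act) {
      if (a < b && dmat[a, b] < bestd) { bestd <- dmat[a, b]; best <- c(a, b) }
    }
    a <- best[1L]; b <- best[2L]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- coph[j, i] <- bestd
    }
    # average-linkage update into slot a
    for (c in act) {
      if (c == a || c == b) next
      dmat[a, c] <- dmat[c, a] <-
        (sizes[a] * dmat[a, c] + sizes[b] * dmat[b, c]) / (sizes[a] + sizes[b])
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# first principal component over samples by power iteration on Z' Z
oraclePc1 <- function(m) {
  z <- t(scale(t(m)))
  g <- crossprod(z) # samples x samples
  v <- rep(1, ncol(g))
  for (i in 1:2000) {
    v2 <- g %*% v
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
    v <- v2
  }
  drop(v)
}

# exact hypergeometric upper tail by enumeration
oracleHyper <- function(m, K, N, q) {
  js <- m:min(K, q)
  sum(choose(K, js) * choose(N - K, q - js)) / choose(N, q)
}

# Benjamini-Hochberg step-up
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Spearman rho with average ranks, from first principles
oracleSpearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  ca <- ra - mean(ra); cb <- rb - mean(rb)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# two-sided correlation-test p via the incomplete beta relation
oracleCorP <- function(r, n) {
  df <- n - 2
  t2 <- r^2 * df / (1 - r^2)
  pbeta(df / (df + t2), df / 2, 0.5)
}

# least squares by normal equations
oracleLsq <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- X %*% beta
  r2 <- 1 - sum((y - fit)^2) / sum((y - mean(y))^2)
  list(slope = beta[2L], r2 = r2)
}

# equal-width binning mirror of the scale-free fit contract
oracleScaleFree <- function(k, nBins = 10L) {
  breaks <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE)
  freq <- tabulate(bin, nbins = nBins)
  meanK <- sapply(seq_len(nBins), function(b)
    if (freq[b] > 0) mean(k[bin == b]) else NA)
  use <- freq > 0 & !is.na(meanK) & meanK > 0
  oracleLsq(log10(meanK[use]), log10(freq[use]))
}
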