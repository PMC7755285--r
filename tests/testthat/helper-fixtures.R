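# shared fixtures, built in code

# small planted-module design: 3 modules x 60 genes + 60 background
smallDesign <- function(seed = 7L, ...) {
  syntheticDesign(moduleSizes = rep(60L, 3L), nBackground = 60L,
                  seed = seed, ...)
}

# near-noise-free design used for exact-recovery limit checks
limitDesign <- function(seed = 7L) {
  syntheticDesign(moduleSizes = rep(60L, 3L), nBackground = 60L,
                  kmeRange = c(0.995, 0.999), noiseSd = 1e-3, seed = seed)
}

randomExpr <- function(nGenes, nSamples, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  m
}

# random valid adjacency with unit diagonal
randomAdjacency <- function(n, seed = 1L) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# block-structured dissimilarity: `sizes` blocks, tight within, far between
blockDissimilarity <- function(sizes, within = 0.05, between = 0.95,
                               seed = 1L) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n) + matrix(runif(n * n, 0, 0.02), n, n)
  d <- (d + t(d)) / 2
  for (b in seq_along(sizes)) {
    i <- which(lab == b)
    d[i, i] <- within + (d[i, i] - between) # keep the jitter
  }
  diag(d) <- 0
  d[d < 0] <- 0; d[d > 1] <- 1
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  list(d = d, labels = lab)
}
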