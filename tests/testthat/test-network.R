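test_that("correlation matrix is exact Pearson and rejects bad input", {
  m <- randomExpr(4, 6, seed = 3)
  cc <- correlationMatrix(m)
  expect_lt(max(abs(cc - oracleCor(m))), 1e-12)
  expect_lt(max(abs(cc - t(cc))), 1e-12)
  expect_equal(unname(diag(cc)), rep(1, 4))
  # affine invariance: g2 = 2 g1 + 5
  m2 <- rbind(g1 = 1:6, g2 = 2 * (1:6) + 5, g3 = rnorm(6))
  colnames(m2) <- sprintf("s%d", 1:6)
  expect_equal(correlationMatrix(m2)["g1", "g2"], 1)
  # zero-variance gene named in the error
  m3 <- rbind(gA = rnorm(5), flat = rep(2, 5))
  colnames(m3) <- sprintf("s%d", 1:5)
  expect_error(correlationMatrix(m3), "flat")
  expect_error(correlationMatrix(m[, 1:2]), "3 samples")
})

test_that("soft adjacency follows the unsigned and signed formulas", {
  r <- matrix(c(1, -0.5, -0.5, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(adjacency(softAdjacency(r, 4))["a", "b"], 0.0625)
  expect_equal(adjacency(softAdjacency(r, 1))["a", "b"], 0.5) # |r| at beta=1
  rs <- matrix(c(1, -1, -1, 1), 2, dimnames = dimnames(r))
  expect_equal(adjacency(softAdjacency(rs, 2, "signed"))["a", "b"], 0)
  expect_error(softAdjacency(r, 0), "power")
  expect_equal(diag(adjacency(softAdjacency(r, 7))), c(a = 1, b = 1))
})

test_that("adjacency is monotone non-increasing in the power", {
  set.seed(11)
  for (rep in 1:5) {
    cc <- correlationMatrix(randomExpr(8, 10, seed = rep))
    a1 <- adjacency(softAdjacency(cc, rep + 1L))
    a2 <- adjacency(softAdjacency(cc, rep + 2L))
    off <- upper.tri(a1)
    expect_true(all(a2[off] <= a1[off] + 1e-15))
    # connectivity inherits the monotonicity
    expect_true(all(connectivity(a2) <= connectivity(a1) + 1e-12))
  }
})

test_that("connectivity equals the loop oracle and handles edge cases", {
  a <- randomAdjacency(5, seed = 2)
  expect_lt(max(abs(connectivity(a) - oracleConnectivity(a))), 1e-12)
  two <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(connectivity(two), c(a = 1, b = 1))
  z <- diag(2); dimnames(z) <- dimnames(two)
  expect_equal(connectivity(z), c(a = 0, b = 0))
})

test_that("TOM matches the triple-loop oracle and its closed forms", {
  a <- randomAdjacency(6, seed = 5)
  expect_lt(max(abs(tomSimilarity(a) - oracleTom(a))), 1e-12)
  # blocked computation agrees with the single-shot one
  a2 <- randomAdjacency(23, seed = 6)
  expect_lt(max(abs(tomSimilarity(a2, blockSize = 7L) -
                    tomSimilarity(a2, blockSize = 1000L))), 1e-12)
  # isolated perfect pair
  two <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(tomSimilarity(two)["a", "b"], 1)
  # empty off-diagonal stays empty
  z <- diag(3)
  dimnames(z) <- list(letters[1:3], letters[1:3])
  expect_equal(unique(tomSimilarity(z)[upper.tri(z)]), 0)
  # range and symmetry on a larger random case
  tom <- tomSimilarity(randomAdjacency(40, seed = 9))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_lt(max(abs(tom - t(tom))), 1e-12)
})

test_that("scale-free fit reproduces exact power laws and the lsq oracle", {
  # frequencies 2520/i over bin means i give an exactly linear log-log law
  k <- rep(1:10, times = 2520 / (1:10))
  fit <- scaleFreeFit(k)
  expect_equal(fit$rSquared, 1)
  expect_equal(fit$slope, -1)
  expect_equal(fit$meanConnectivity, mean(k))
  # constant connectivity cannot be binned
  expect_error(scaleFreeFit(rep(3, 50)), "constant")
  # random vector agrees with an independent normal-equations oracle
  set.seed(13)
  k2 <- rexp(100, rate = 0.2)
  fit2 <- scaleFreeFit(k2)
  or <- oracleScaleFree(k2)
  expect_lt(abs(fit2$rSquared - or$r2), 1e-10)
  expect_lt(abs(fit2$slope - or$slope), 1e-10)
})

test_that("power selection returns the smallest passing power", {
  sim <- simulateExpression(smallDesign())
  expr <- logTransform(SummarizedExperiment::assay(
    filterGenes(sim$expression)))
  cc <- correlationMatrix(expr)
  pick <- pickSoftThreshold(cc, isCorrelation = TRUE)
  tab <- pick$fitTable
  passing <- tab$power[!is.na(tab$signedRSquared) & tab$signedRSquared > 0.8]
  if (length(passing)) {
    expect_false(pick$flagged)
    expect_identical(pick$power, min(passing))
  } else {
    expect_true(pick$flagged)
  }
  # r2Cut = 0 boundary: first candidate with any negative-slope fit wins
  pick0 <- pickSoftThreshold(cc, r2Cut = 0, isCorrelation = TRUE)
  expect_identical(pick0$power,
                   tab$power[which(tab$signedRSquared > 0)[1L]])
  # gene-order invariance
  perm <- sample(nrow(cc))
  pickP <- pickSoftThreshold(cc[perm, perm], isCorrelation = TRUE)
  expect_identical(pickP$power, pick$power)
  expect_equal(pickP$fitTable$rSquared, pick$fitTable$rSquared,
               tolerance = 1e-12)
})

test_that("plateau fallback engages and warns when no power passes", {
  sim <- simulateExpression(smallDesign())
  expr <- logTransform(SummarizedExperiment::assay(
    filterGenes(sim$expression)))
  cc <- correlationMatrix(expr)
  expect_warning(
    pick <- pickSoftThreshold(cc, r2Cut = 0.999, isCorrelation = TRUE),
    "plateau")
  expect_true(pick$flagged)
  gain <- diff(pick$fitTable$signedRSquared)
  first <- which(!is.na(gain) & gain < 0.01)[1L]
  expect_identical(pick$power, pick$fitTable$power[first + 1L])
})
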