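test_that("average linkage matches a naive UPGMA oracle cophenetically", {
  set.seed(21)
  for (rep in 1:3) {
    d <- matrix(runif(64), 8, 8)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(letters[1:8], letters[1:8])
    dend <- averageLinkageCluster(d)
    coph <- as.matrix(cophenetic(dend))[letters[1:8], letters[1:8]]
    expect_lt(max(abs(coph - oracleUpgmaCophenetic(d))), 1e-12)
  }
  # forced first merge and zero-distance twins
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.8, 0.9, 0.8, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  dend3 <- averageLinkageCluster(d3)
  expect_equal(dend3$height[1L], 0.1)
  expect_identical(sort(dend3$merge[1L, ]), c(-2L, -1L)) # x joins y first
  d0 <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3,
               dimnames = dimnames(d3))
  expect_equal(averageLinkageCluster(d0)$height[1L], 0)
  # non-symmetric input rejected
  dbad <- d3; dbad[1, 2] <- 0.4
  expect_error(averageLinkageCluster(dbad), "symmetric")
})

test_that("cutTree recovers perfectly separated blocks exactly", {
  bl <- blockDissimilarity(c(20, 20, 20))
  dend <- averageLinkageCluster(bl$d)
  part <- cutTree(dend, bl$d, minSize = 10L)
  lab <- moduleLabels(part)[rownames(bl$d)]
  expect_identical(length(moduleSizes(part)), 3L)
  expect_identical(sum(lab == "0"), 0L)
  expect_equal(adjustedRand(lab, bl$labels), 1)
  # static cut agrees on this clean structure
  partS <- cutTree(dend, bl$d, minSize = 10L, method = "static",
                   cutHeight = 0.5)
  expect_equal(adjustedRand(moduleLabels(partS)[rownames(bl$d)],
                            bl$labels), 1)
})

test_that("minSize larger than n leaves everything unassigned", {
  bl <- blockDissimilarity(c(10, 10))
  dend <- averageLinkageCluster(bl$d)
  part <- cutTree(dend, bl$d, minSize = 50L)
  expect_identical(length(moduleSizes(part)), 0L)
  expect_true(all(moduleLabels(part) == "0"))
  expect_error(cutTree(dend, bl$d, cutHeight = 1.5), "cutHeight")
})

test_that("partitions are invariant to gene input order", {
  sim <- simulateExpression(smallDesign())
  expr <- logTransform(SummarizedExperiment::assay(
    filterGenes(sim$expression)))
  tom <- tomSimilarity(softAdjacency(correlationMatrix(expr), 6))
  d <- 1 - tom
  dend <- averageLinkageCluster(d)
  part <- cutTree(dend, d, minSize = 30L)
  set.seed(99)
  perm <- sample(nrow(d))
  dendP <- averageLinkageCluster(d[perm, perm])
  partP <- cutTree(dendP, d[perm, perm], minSize = 30L)
  g <- rownames(d)
  expect_equal(adjustedRand(moduleLabels(part)[g],
                            moduleLabels(partP)[g]), 1)
})

test_that("in the noise-free limit the planted partition is recovered", {
  sim <- simulateExpression(limitDesign())
  expr <- logTransform(SummarizedExperiment::assay(
    filterGenes(sim$expression)))
  tom <- tomSimilarity(softAdjacency(correlationMatrix(expr), 6))
  dend <- averageLinkageCluster(1 - tom)
  part <- cutTree(dend, 1 - tom, minSize = 50L)
  truth <- sim$truth
  lab <- moduleLabels(part)[truth@gene]
  expect_equal(adjustedRand(lab, truth@module), 1)
})

test_that("module eigengenes match a PCA oracle and its closed cases", {
  m <- randomExpr(50, 12, seed = 31)
  me <- moduleEigengene(m)
  expect_lt(abs(mean(me)), 1e-8)
  expect_equal(sd(me), 1, tolerance = 1e-8)
  pc <- oraclePc1(m)
  expect_gt(abs(cor(me, pc)), 1 - 1e-10)
  # single-gene module: the standardized gene itself
  one <- m[1, , drop = FALSE]
  expect_equal(unname(moduleEigengene(one)),
               unname((one[1, ] - mean(one[1, ])) / sd(one[1, ])))
  # rank-1 module: affine copies of one profile
  prof <- rnorm(12)
  rk1 <- outer(runif(8, 0.5, 2), prof) + runif(8, -3, 3)
  dimnames(rk1) <- list(sprintf("g%d", 1:8), sprintf("s%d", 1:12))
  expect_equal(abs(cor(moduleEigengene(rk1), prof)), 1, tolerance = 1e-10)
  # orientation: positively correlated with the module mean profile
  z <- t(scale(t(m)))
  expect_gte(cor(me, colMeans(z)), 0)
  expect_error(moduleEigengene(rbind(m, flat = rep(1, 12))), "flat")
})

test_that("eigengene columns are standardized across a whole partition", {
  sim <- simulateExpression(smallDesign())
  expr <- logTransform(SummarizedExperiment::assay(sim$expression))
  truth <- sim$truth
  labels <- ifelse(truth@module == "background", "0", truth@module)
  names(labels) <- truth@gene
  part <- new("ModulePartition", labels = labels, colorMap = character())
  me <- moduleEigengenes(expr, part)
  expect_identical(dim(me), c(21L, 3L))
  expect_lt(max(abs(colMeans(me))), 1e-8)
  expect_lt(max(abs(apply(me, 2, var) - 1)), 1e-8)
})

test_that("modules with near-identical eigengenes merge; others persist", {
  set.seed(41)
  prof <- rnorm(10)
  mk <- function(n, p, noise = 0.01) {
    t(replicate(n, p * runif(1, 0.8, 1.2) + rnorm(10, sd = noise)))
  }
  other <- rnorm(10)
  m <- rbind(mk(30, prof), mk(30, prof), mk(30, other))
  dimnames(m) <- list(sprintf("g%03d", 1:90), sprintf("s%d", 1:10))
  labels <- setNames(rep(c("1", "2", "3"), each = 30), rownames(m))
  part <- new("ModulePartition", labels = labels, colorMap = character())
  res <- mergeCloseModules(m, part)
  expect_identical(length(moduleSizes(res$partition)), 2L)
  expect_identical(unname(moduleSizes(res$partition)), c(60L, 30L))
  # merging is idempotent
  res2 <- mergeCloseModules(m, res$partition)
  expect_identical(moduleLabels(res2$partition),
                   moduleLabels(res$partition))
  # fixed point when all eigengene correlations sit below the threshold
  labelsB <- setNames(rep(c("1", "2"), c(60, 30)), rownames(m))
  partB <- new("ModulePartition", labels = labelsB, colorMap = character())
  resB <- mergeCloseModules(m, partB)
  expect_identical(unname(moduleSizes(resB$partition)), c(60L, 30L))
})

test_that("size-ranked color naming reproduces the published size order", {
  sizes <- c(10378L, 3166L, 2958L, 1305L, 494L, 439L, 305L, 293L, 236L, 62L)
  genes <- sprintf("g%05d", seq_len(sum(sizes)))
  labels <- setNames(rep(as.character(1:10), sizes), genes)
  part <- assignColors(new("ModulePartition", labels = labels,
                           colorMap = character()))
  got <- part@colorMap[as.character(1:10)]
  expect_identical(unname(got),
                   c("turquoise", "blue", "brown", "yellow", "green",
                     "red", "black", "pink", "magenta", "purple"))
  # single module
  p1 <- assignColors(new("ModulePartition",
                         labels = c(a = "1", b = "1"),
                         colorMap = character()))
  expect_identical(unname(p1@colorMap["1"]), "turquoise")
  expect_identical(unname(p1@colorMap["0"]), "grey")
  # ties broken by the lexicographically first member gene
  pt <- assignColors(new("ModulePartition",
                         labels = c(zz = "1", zy = "1", aa = "2", ab = "2"),
                         colorMap = character()))
  expect_identical(unname(pt@colorMap["2"]), "turquoise")
  expect_identical(unname(pt@colorMap["1"]), "blue")
})

test_that("partition accessors expose labels, sizes and colors", {
  labels <- setNames(c("1", "1", "2", "0"), c("a", "b", "c", "d"))
  part <- assignColors(new("ModulePartition", labels = labels,
                           colorMap = character()))
  expect_identical(moduleSizes(part), c(`1` = 2L, `2` = 1L))
  expect_identical(unname(moduleColors(part)),
                   c("turquoise", "turquoise", "blue", "grey"))
  expect_error(moduleColors(new("ModulePartition", labels = labels,
                                colorMap = character())), "assignColors")
})
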