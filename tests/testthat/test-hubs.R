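test_that("target-module selection maximizes the eigengene target mean", {
  me <- cbind(up = c(-1, -1, 1, 1), down = c(1, 1, -1, -1),
              flat = c(0.1, -0.1, 0.1, -0.1))
  rownames(me) <- sprintf("s%d", 1:4)
  sel <- selectTargetModule(me, c("s3", "s4"))
  expect_identical(sel$module, "up")
  expect_identical(sel$ranking$module[1L], "up")
  expect_equal(sel$ranking$targetMean[1L], 1)
  # invariant to column order
  sel2 <- selectTargetModule(me[, c(3, 1, 2)], c("s3", "s4"))
  expect_identical(sel2$module, "up")
  expect_error(selectTargetModule(me, c("s3", "nope")), "nope")
  expect_error(selectTargetModule(me, character()), "non-empty")
})

test_that("the planted late-peaking module is selected on synthetic data", {
  sim <- simulateExpression(smallDesign())
  se <- logTransform(filterGenes(sim$expression))
  expr <- SummarizedExperiment::assay(se)
  truth <- sim$truth
  labels <- ifelse(truth@module == "background", "0", truth@module)
  names(labels) <- truth@gene
  part <- new("ModulePartition",
              labels = labels[rownames(expr)], colorMap = character())
  me <- moduleEigengenes(expr, part)
  cd <- SummarizedExperiment::colData(se)
  targets <- rownames(cd)[cd$stage_day %in% c(115L, 135L)]
  sel <- selectTargetModule(me, targets)
  expect_identical(sel$module, "1") # the planted target module index
})

test_that("kME t statistics and p-values follow the Student t closed forms", {
  # r = 0.9, n = 21: t = 0.9 * sqrt(19) / sqrt(0.19) = 9 exactly
  r <- 0.9; n <- 21
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(t, 9)
  set.seed(51)
  m <- randomExpr(10, 21, seed = 51)
  me <- cbind(me1 = rnorm(21), me2 = rnorm(21))
  rownames(me) <- colnames(m)
  kp <- kmeWithP(m, me)
  expect_identical(dim(kp$kme), c(10L, 2L))
  # against an independent incomplete-beta oracle
  for (i in 1:10) for (j in 1:2) {
    expect_lt(abs(kp$p[i, j] - oracleCorP(kp$kme[i, j], 21)), 1e-10)
  }
  # r = 0 gives p = 1; |r| = 1 gives p = 0
  mz <- rbind(g1 = c(1, -1, 1, -1, 1, -1), g2 = c(1, 2, 3, 4, 5, 6))
  colnames(mz) <- sprintf("s%d", 1:6)
  mez <- cbind(a = c(1, 2, 3, 3, 2, 1), b = c(1, 2, 3, 4, 5, 6))
  rownames(mez) <- colnames(mz)
  kz <- kmeWithP(mz, mez)
  expect_equal(kz$kme["g1", "a"], 0)
  expect_equal(kz$p["g1", "a"], 1)
  expect_equal(kz$kme["g2", "b"], 1)
  expect_equal(kz$p["g2", "b"], 0)
  expect_error(kmeWithP(mz[, 1:2], mez[1:2, ]), "3 samples")
})

test_that("the dual-threshold screen intersects inclusively and reports Venn", {
  kme <- matrix(c(0.95, 0.9, 0.85, 0.92, 0.5), ncol = 1,
                dimnames = list(sprintf("g%d", 1:5), "blue"))
  stats <- new("GeneModuleStats", gene = rownames(kme),
               module = rep("blue", 5),
               connectivity = c(950, 800, 1000, 900, 990),
               kme = kme, p = kme * 0, nSamples = 21L)
  res <- screenHubs(stats, "blue", kMin = 900, kmeMin = 0.9)
  expect_identical(sort(res@setK), c("g1", "g3", "g4", "g5"))
  expect_identical(sort(res@setKme), c("g1", "g2", "g4")) # 0.9 inclusive
  expect_identical(sort(hubGenes(res)), c("g1", "g4"))
  expect_identical(res@vennCounts,
                   c(onlyK = 2L, onlyKme = 1L, both = 2L))
  # impossible kME threshold empties the hub set
  expect_identical(hubGenes(screenHubs(stats, "blue", kmeMin = 1.1)),
                   character())
  # monotone in both thresholds
  base <- hubGenes(screenHubs(stats, "blue", kMin = 800, kmeMin = 0.85))
  for (k in c(850, 950, 1200)) for (km in c(0.88, 0.92, 0.96)) {
    expect_true(all(hubGenes(screenHubs(stats, "blue", k, km)) %in% base))
  }
  # quantile-based connectivity threshold
  rq <- screenHubs(stats, "blue", kQuantile = 0.5)
  expect_equal(rq@kMin, unname(quantile(stats@connectivity, 0.5)))
})

test_that("hub screening runs on supplementary-shaped result tables", {
  # synthetic stand-in tables shaped like published connectivity/kME files
  set.seed(61)
  genes <- sprintf("g%03d", 1:40)
  kTab <- data.frame(gene = genes, module = "blue",
                     connectivity = runif(40, 500, 1500))
  rTab <- data.frame(gene = genes, blue = runif(40, 0.5, 1))
  kf <- withr::local_tempfile(fileext = ".tsv")
  rf <- withr::local_tempfile(fileext = ".tsv")
  write.table(kTab, kf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rTab, rf, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- screenHubsFromTables(kf, rf, "blue")
  oracle <- intersect(genes[kTab$connectivity >= 900],
                      genes[rTab$blue >= 0.9])
  expect_identical(sort(hubGenes(res)), sort(oracle))
  expect_identical(res@vennCounts[["both"]], length(oracle))
})

test_that("Spearman concordance bands follow |Rs| with average ranks", {
  expect_equal(spearmanConcordance(1:7, 1:7),
               list(rho = 1, band = "extremely strong"))
  expect_equal(spearmanConcordance(1:7, 7:1),
               list(rho = -1, band = "extremely strong"))
  # tie handled by average ranks, against a first-principles oracle
  a <- c(3, 1, 4, 1, 5, 9, 2)
  b <- c(2, 7, 1, 8, 2, 8, 1)
  sc <- spearmanConcordance(a, b)
  expect_lt(abs(sc$rho - oracleSpearman(a, b)), 1e-12)
  expect_error(spearmanConcordance(1:4, 1:5), "length")
  expect_error(spearmanConcordance(1:2, 2:1), "3")
  # band boundaries
  bandOf <- function(x) {
    n <- 100
    set.seed(71)
    repeat {
      u <- rnorm(n); v <- x * scale(u)[, 1] + sqrt(1 - x^2) * rnorm(n)
      r <- suppressWarnings(cor(u, v, method = "spearman"))
      if (abs(r - x) < 0.05) return(spearmanConcordance(u, v)$band)
    }
  }
  expect_identical(bandOf(0.95), "extremely strong")
  expect_identical(bandOf(0.7), "strong")
  expect_identical(bandOf(0.5), "medium")
})

test_that("observed kME tracks planted kME within sampling noise", {
  d <- syntheticDesign(moduleSizes = c(220L, 120L), nBackground = 40L)
  sim <- simulateExpression(d)
  expr <- logTransform(SummarizedExperiment::assay(sim$expression))
  truth <- sim$truth
  labels <- ifelse(truth@module == "background", "0", truth@module)
  names(labels) <- truth@gene
  part <- new("ModulePartition", labels = labels[rownames(expr)],
              colorMap = character())
  me <- moduleEigengenes(expr, part)
  kp <- kmeWithP(expr, me)
  mod1 <- truth@gene[truth@module == "1"]
  dev <- kp$kme[mod1, "1"] - truth@kme[mod1]
  expect_gt(length(mod1), 200L)
  expect_lt(abs(mean(dev)), 0.05)
  expect_lt(quantile(abs(dev), 0.5), 0.1)
})
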