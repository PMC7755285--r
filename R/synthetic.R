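#' Construct a synthetic study design
#'
#' Defaults emulate a 7-stage x 3-replicate fetal skin developmental series:
#' five planted modules of 200 genes, 500 unstructured background genes,
#' per-gene module membership (kME) drawn uniformly in `[0.6, 0.95]`, and
#' module 1 given a strictly increasing stage profile peaking in the last
#' two stages (the maturation-stage target). With 7 stages the stage days
#' are 45, 55, 65, 75, 95, 115 and 135.
#'
#' @param nStages,nReps,moduleSizes,kmeRange,nBackground,targetModule,noiseSd,seed
#'   see [SyntheticDesign-class].
#' @return A validated [SyntheticDesign-class].
#' @examples
#' syntheticDesign(moduleSizes = rep(50L, 3), nBackground = 100L)
#' @export
syntheticDesign <- function(nStages = 7L, nReps = 3L,
                            moduleSizes = rep(200L, 5L),
                            kmeRange = c(0.6, 0.95), nBackground = 500L,
                            targetModule = 1L, noiseSd = 0.25, seed = 7L) {
  new("SyntheticDesign", nStages = as.integer(nStages),
      nReps = as.integer(nReps), moduleSizes = as.integer(moduleSizes),
      kmeRange = as.numeric(kmeRange), nBackground = as.integer(nBackground),
      targetModule = as.integer(targetModule), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

# stage days: the 7-stage default uses the gestational-day grid of the
# emulated design; other stage counts fall back to 1..nStages
.stageDays <- function(nStages) {
  if (nStages == 7L) c(45L, 55L, 65L, 75L, 95L, 115L, 135L)
  else seq_len(nStages)
}

.sampleIds <- function(design) {
  days <- .stageDays(design@nStages)
  as.vector(vapply(days, function(d)
    sprintf("d%d_r%d", d, seq_len(design@nReps)),
    character(design@nReps)))
}

# stage-level module profiles; target strictly increasing, the others
# smooth random curves orthogonalized (Gram-Schmidt, after centering)
# against all earlier profiles, so planted modules are mutually distinct:
# stage-level profile correlations are exactly zero
.stageProfiles <- function(design) {
  S <- design@nStages
  M <- length(design@moduleSizes)
  if (S < 2L) {
    stop("at least 2 stages are required: a single stage gives ",
         "zero-variance (constant) profiles")
  }
  if (M > S - 1L) {
    stop("cannot plant more than nStages - 1 mutually uncorrelated modules")
  }
  prof <- matrix(NA_real_, S, M,
                 dimnames = list(NULL, paste0("module", seq_len(M))))
  std <- function(v) (v - mean(v)) / stats::sd(v)
  # target: cumulative positive increments => strictly increasing,
  # so its two largest values sit in the last two stages
  prof[, design@targetModule] <- std(cumsum(stats::runif(S, 0.5, 1.5)))
  smooth3 <- function(v) {
    vp <- c(v[1L], v, v[length(v)])
    0.25 * vp[seq_len(length(v))] + 0.5 * v + 0.25 * vp[seq_len(length(v)) + 2L]
  }
  done <- design@targetModule
  for (m in setdiff(seq_len(M), design@targetModule)) {
    for (try in seq_len(100L)) {
      cand <- smooth3(stats::rnorm(S))
      cand <- cand - mean(cand)
      for (j in done) { # orthogonalize against accepted (centered) profiles
        cand <- cand - sum(cand * prof[, j]) / sum(prof[, j]^2) * prof[, j]
      }
      if (stats::sd(cand) > 1e-8) break
    }
    if (stats::sd(cand) <= 1e-8) {
      stop("failed to draw a stage profile orthogonal to existing modules")
    }
    prof[, m] <- std(cand)
    done <- c(done, m)
  }
  prof
}

# expand stage profiles to samples (replicate + jitter), standardized
.sampleProfiles <- function(design, stageProf) {
  idx <- rep(seq_len(design@nStages), each = design@nReps)
  prof <- stageProf[idx, , drop = FALSE] +
    matrix(stats::rnorm(length(idx) * ncol(stageProf), sd = design@noiseSd),
           length(idx), ncol(stageProf))
  prof <- apply(prof, 2L, function(v) (v - mean(v)) / stats::sd(v))
  rownames(prof) <- .sampleIds(design)
  prof
}

#' Simulate stage-indexed module profiles
#'
#' Each module receives a smooth stage-level profile, replicated within
#' stage with jitter of sd `noiseSd`, then standardized to zero mean and
#' unit variance across samples. The target module's stage profile is
#' strictly increasing, so its two largest values fall in the last two
#' stages. Pure function of the design (seeded internally).
#'
#' @param design A [SyntheticDesign-class].
#' @return samples x modules numeric matrix with the stage-level profiles
#'   attached as `attr(, "stageProfiles")`.
#' @examples
#' p <- simulateProfiles(syntheticDesign(moduleSizes = rep(10L, 2)))
#' dim(p)
#' @export
simulateProfiles <- function(design) {
  stopifnot(methods::validObject(design))
  .withSeed(design@seed, {
    stageProf <- .stageProfiles(design)
    prof <- .sampleProfiles(design, stageProf)
    attr(prof, "stageProfiles") <- stageProf
    prof
  })
}

#' Simulate an expression matrix with planted modules
#'
#' Gene *g* of module *m* with planted membership \eqn{r_g} is generated on
#' a standardized latent scale as
#' \deqn{x_g = r_g \, p_m + \sqrt{1 - r_g^2}\, \varepsilon,\qquad
#'   \varepsilon \sim N(0, 1),}
#' so its population correlation with the module profile \eqn{p_m} equals
#' \eqn{r_g} exactly, making parameter recovery quantitative. Background
#' genes are pure noise. The latent values are mapped to a non-negative
#' FPKM-like scale as \eqn{\max(2^{(b_g + x)} - 1, 0)} with per-gene
#' baselines \eqn{b_g \sim U(3, 8)}, so [logTransform()] is an approximate
#' inverse.
#'
#' @param design A [SyntheticDesign-class].
#' @return list with elements `expression` (a `SummarizedExperiment`, assay
#'   `"expr"` on the FPKM-like scale, colData `stage_day`/`replicate`) and
#'   `truth` (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateExpression(syntheticDesign(moduleSizes = rep(20L, 2),
#'                                           nBackground = 10L))
#' dim(sim$expression)
#' @export
simulateExpression <- function(design) {
  stopifnot(methods::validObject(design))
  .withSeed(design@seed, {
    stageProf <- .stageProfiles(design)
    prof <- .sampleProfiles(design, stageProf)
    nSamples <- nrow(prof)
    M <- length(design@moduleSizes)
    nGenes <- sum(design@moduleSizes) + design@nBackground
    geneIds <- sprintf("g%05d", seq_len(nGenes))

    latent <- matrix(NA_real_, nGenes, nSamples,
                     dimnames = list(geneIds, rownames(prof)))
    module <- character(nGenes)
    kme <- rep(NA_real_, nGenes)
    row <- 0L
    for (m in seq_len(M)) {
      for (i in seq_len(design@moduleSizes[m])) {
        row <- row + 1L
        r <- stats::runif(1L, design@kmeRange[1L], design@kmeRange[2L])
        latent[row, ] <- r * prof[, m] +
          sqrt(1 - r^2) * stats::rnorm(nSamples)
        module[row] <- as.character(m)
        kme[row] <- r
      }
    }
    if (design@nBackground > 0L) {
      bg <- row + seq_len(design@nBackground)
      latent[bg, ] <- matrix(stats::rnorm(length(bg) * nSamples),
                             length(bg), nSamples)
      module[bg] <- "background"
    }

    baseline <- stats::runif(nGenes, 3, 8)
    fpkm <- pmax(2^(baseline + latent) - 1, 0)

    days <- .stageDays(design@nStages)
    colData <- S4Vectors::DataFrame(
      stage_day = rep(days, each = design@nReps),
      replicate = rep(seq_len(design@nReps), design@nStages),
      row.names = rownames(prof))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = fpkm), colData = colData)

    names(module) <- names(kme) <- geneIds
    hubGenes <- lapply(seq_len(M), function(m)
      geneIds[module == as.character(m) & kme >= 0.9])
    names(hubGenes) <- colnames(prof)
    tgt <- geneIds[module == as.character(design@targetModule)]
    nominee <- tgt[which.max(kme[tgt])]
    truth <- new("SyntheticTruth", gene = geneIds, module = module,
                 kme = kme, stageProfiles = stageProf, hubGenes = hubGenes,
                 nominee = nominee)
    list(expression = se, truth = truth)
  })
}

# selected-term annotation around the planted nominee: three BP-like and
# three pathway-like terms; the nominee joins all six, every other target
# hub joins at most two of each, so the nominee is the unique gene in all
# three BP terms and >= 3 pathways
.nomineeAnnotation <- function(sim, design) {
  truth <- sim$truth
  tgt <- as.character(design@targetModule)
  hubs <- truth@hubGenes[[design@targetModule]]
  others <- setdiff(hubs, truth@nominee)
  modGenes <- setdiff(truth@gene[truth@module == tgt], hubs)
  ids <- c(paste0("bp_term_", 1:3), paste0("pathway_term_", 1:3))
  ns <- rep(c("BP", "pathway"), each = 3L)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  genes <- vector("list", 6L)
  for (block in c(0L, 3L)) {
    sets <- list(character(), character(), character())
    for (i in seq_along(others)) {
      pick <- pairs[[1L + (i - 1L) %% 3L]]
      if (block == 3L) pick <- pairs[[1L + i %% 3L]][1L] # <=1 pathway each
      for (j in pick) sets[[j]] <- c(sets[[j]], others[i])
    }
    filler <- if (length(modGenes)) {
      split(modGenes, 1L + (seq_along(modGenes) - 1L) %% 3L)
    } else list()
    for (j in 1:3) {
      fill <- if (length(filler)) filler[[min(j, length(filler))]]
              else character()
      genes[[block + j]] <- unique(c(truth@nominee, sets[[j]], fill))
    }
  }
  AnnotationSet(termId = ids, termName = paste("synthetic", ids),
                namespace = ns, genes = genes)
}

#' Write a self-contained synthetic fixture bundle
#'
#' Writes the simulated expression TSV, sample sheet, ground-truth table,
#' a module GMT (one term per planted module holding that module's hub
#' genes, planted kME >= 0.9), two selected-term GMTs built around the
#' planted nominee gene (three BP-like and three pathway-like terms; the
#' nominee is the only gene present in all of them), and a ready-to-run
#' pipeline config, enabling the enrichment-intersection test end to end.
#'
#' @param design A [SyntheticDesign-class].
#' @param outDir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeFixtureBundle <- function(design, outDir) {
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outDir)
  }
  sim <- simulateExpression(design)
  truth <- sim$truth
  paths <- c(expression = file.path(outDir, "expression.tsv"),
             sampleSheet = file.path(outDir, "sample_sheet.tsv"),
             truth = file.path(outDir, "ground_truth.tsv"),
             moduleGmt = file.path(outDir, "module_terms.gmt"),
             bpGmt = file.path(outDir, "selected_bp_terms.gmt"),
             pathwayGmt = file.path(outDir, "selected_pathway_terms.gmt"),
             config = file.path(outDir, "config.yaml"))

  writeExpression(sim$expression, paths[["expression"]])
  cd <- SummarizedExperiment::colData(sim$expression)
  utils::write.table(
    data.frame(sample_id = rownames(cd), stage_day = cd$stage_day,
               replicate = cd$replicate),
    paths[["sampleSheet"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = truth@gene, module = truth@module,
               true_kme = format(truth@kme, digits = 17, trim = TRUE)),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)

  modTerms <- truth@hubGenes[lengths(truth@hubGenes) > 0L]
  writeGmt(AnnotationSet(termId = paste0(names(modTerms), "_hubs"),
                         termName = paste("hub genes of", names(modTerms)),
                         namespace = "pathway", genes = modTerms),
           paths[["moduleGmt"]])
  sel <- .nomineeAnnotation(sim, design)
  isBP <- sel@namespace == "BP"
  writeGmt(AnnotationSet(sel@termId[isBP], sel@termName[isBP], "BP",
                         sel@genes[isBP]), paths[["bpGmt"]])
  writeGmt(AnnotationSet(sel@termId[!isBP], sel@termName[!isBP], "pathway",
                         sel@genes[!isBP]), paths[["pathwayGmt"]])

  cd <- SummarizedExperiment::colData(sim$expression)
  lastTwo <- rownames(cd)[cd$stage_day %in% utils::tail(sort(unique(cd$stage_day)), 2L)]
  config <- list(
    expression = paths[["expression"]],
    sampleSheet = paths[["sampleSheet"]],
    logTransform = TRUE,
    filter = list(minValue = 1, minFraction = 0.5, minMad = 0),
    # the bundle pins the conventional unsigned default power so the
    # planted-structure benchmark is reproducible independent of the
    # scale-free sweep (see pickSoftThreshold for the data-driven route)
    network = list(power = 6L, type = "unsigned", r2Cut = 0.8),
    modules = list(minSize = 50L, mergeSimilarity = 0.85,
                   cutMethod = "dynamic", deepSplit = 2L, cutHeight = 0.995),
    targetSamples = lastTwo,
    hub = list(kmeMin = 0.9, kQuantile = 0.25),
    enrichment = list(
      gmt = list(list(path = paths[["bpGmt"]], namespace = "BP"),
                 list(path = paths[["pathwayGmt"]], namespace = "pathway")),
      selectedGo = paste0("bp_term_", 1:3),
      selectedPathways = paste0("pathway_term_", 1:3),
      pathwayMin = 3L),
    outDir = file.path(outDir, "results"),
    seed = design@seed)
  yaml::write_yaml(config, paths[["config"]])
  invisible(paths)
}
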