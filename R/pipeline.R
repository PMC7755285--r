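#' Run the full co-expression analysis pipeline
#'
#' Executes filter -> log transform -> soft-threshold selection ->
#' adjacency -> TOM -> average-linkage clustering -> tree cut -> eigengene
#' merge -> color naming -> target-module selection -> kME/connectivity ->
#' dual-threshold hub screen -> enrichment -> multi-term intersection,
#' logging one line per stage with the counts needed to audit the run, and
#' writing every result table plus a checksum manifest. With a fixed seed
#' and fixed inputs the outputs are byte-identical across runs.
#'
#' @param config named list or path to a YAML config file. Recognised
#'   fields (defaults in parentheses): `expression` (path, required unless
#'   `data` is given), `sampleSheet`, `delimiter`, `logTransform` (TRUE),
#'   `filter` = list(minValue = 1, minFraction = 0.5, minMad = 0),
#'   `network` = list(power = "auto", type = "unsigned", r2Cut = 0.8,
#'   blockSize = 1000), `modules` = list(minSize = 50, mergeSimilarity =
#'   0.85, cutMethod = "dynamic", deepSplit = 2, cutHeight = 0.995),
#'   `targetSamples` (sample ids; default: samples of the two largest
#'   stage days), `hub` = list(kMin = 900, kmeMin = 0.9, kQuantile = NULL),
#'   `enrichment` = list(gmt = list(list(path, namespace), ...),
#'   selectedGo, selectedPathways, pathwayMin = 3), `outDir` (required),
#'   `seed` (1).
#' @param data optional `SummarizedExperiment` to analyse directly instead
#'   of reading `config$expression`.
#' @param verbose print one log line per stage (default TRUE).
#' @return Invisible list with the key objects (`expression`, `power`,
#'   `fitTable`, `network`, `partition`, `eigengenes`, `targetModule`,
#'   `stats`, `hubs`, `enrichment`, `intersection`) and `manifest`
#'   (data.frame of written files with md5 checksums).
#' @export
runPipeline <- function(config, data = NULL, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- .fillConfig(config)
  if (is.null(cfg$outDir)) stop("config$outDir is required")
  log <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  se <- if (!is.null(data)) data else {
    if (is.null(cfg$expression)) stop("config$expression is required")
    readExpression(cfg$expression, delimiter = cfg$delimiter,
                   sampleSheet = cfg$sampleSheet)
  }
  log("input", "%d genes x %d samples", nrow(se), ncol(se))

  se <- filterGenes(se, cfg$filter$minValue, cfg$filter$minFraction,
                    cfg$filter$minMad)
  fl <- S4Vectors::metadata(se)$filterLog
  log("filter", "kept %d genes, dropped %d (minValue=%g, minFraction=%g, minMad=%g)",
      fl$kept, fl$dropped, fl$minValue, fl$minFraction, fl$minMad)

  if (isTRUE(cfg$logTransform)) {
    se <- logTransform(se)
    log("transform", "log2(x + 1) applied")
  }
  expr <- .exprMatrix(se)

  corr <- correlationMatrix(expr)
  if (identical(cfg$network$power, "auto")) {
    pick <- pickSoftThreshold(corr, r2Cut = cfg$network$r2Cut,
                              networkType = cfg$network$type,
                              isCorrelation = TRUE)
    power <- pick$power
    fitTable <- pick$fitTable
    log("power", "auto-selected beta=%d (flagged=%s)", power, pick$flagged)
  } else {
    power <- as.integer(cfg$network$power)
    fitTable <- NULL
    log("power", "using beta=%d from config", power)
  }

  net <- softAdjacency(corr, power, cfg$network$type)
  tom <- tomSimilarity(net, blockSize = cfg$network$blockSize)
  log("network", "%s adjacency and TOM over %d genes", cfg$network$type,
      nrow(tom))

  dend <- averageLinkageCluster(1 - tom)
  part <- cutTree(dend, 1 - tom, minSize = cfg$modules$minSize,
                  method = cfg$modules$cutMethod,
                  cutHeight = cfg$modules$cutHeight,
                  deepSplit = cfg$modules$deepSplit)
  log("cut", "%d modules, %d genes unassigned",
      length(moduleSizes(part)),
      sum(moduleLabels(part) == .unassignedLabel))

  merged <- mergeCloseModules(expr, part, cfg$modules$mergeSimilarity)
  part <- assignColors(merged$partition)
  me <- moduleEigengenes(expr, part)
  log("merge", "%d modules after merging at similarity %g: %s",
      length(moduleSizes(part)), cfg$modules$mergeSimilarity,
      paste(sprintf("%s=%d", unname(part@colorMap[names(moduleSizes(part))]),
                    moduleSizes(part)), collapse = ", "))

  targetSamples <- cfg$targetSamples
  if (is.null(targetSamples)) {
    cd <- SummarizedExperiment::colData(se)
    lastDays <- utils::tail(sort(unique(cd$stage_day)), 2L)
    targetSamples <- rownames(cd)[cd$stage_day %in% lastDays]
  }
  target <- selectTargetModule(me, targetSamples)
  log("target", "module '%s' highest over %d target samples",
      target$module, length(targetSamples))

  stats <- geneModuleStats(expr, me, net, part)
  hubs <- screenHubs(stats, target$module, kMin = cfg$hub$kMin,
                     kmeMin = cfg$hub$kmeMin, kQuantile = cfg$hub$kQuantile)
  log("hubs", "k>=%.3g: %d genes; kME>=%.3g: %d genes; intersection: %d",
      hubs@kMin, length(hubs@setK) , hubs@kmeMin, length(hubs@setKme),
      length(hubs@hubs))

  enrichment <- NULL
  intersection <- NULL
  ecfg <- cfg$enrichment
  if (!is.null(ecfg) && length(ecfg$gmt)) {
    missing <- vapply(ecfg$gmt, function(g) !file.exists(g$path), TRUE)
    if (any(missing)) {
      warning("GMT file missing (",
              ecfg$gmt[[which(missing)[1L]]]$path,
              "); enrichment stage skipped")
    } else {
      sets <- lapply(ecfg$gmt, function(g)
        readGmt(g$path, namespace = g$namespace))
      ann <- .bindAnnotations(sets)
      enrichment <- hypergeomEnrich(intersect(hubGenes(hubs), rownames(se)),
                                    ann, rownames(se))
      log("enrichment", "%d terms tested, %d significant",
          nrow(enrichment), sum(enrichment$significant))
      if (length(ecfg$selectedGo) || length(ecfg$selectedPathways)) {
        intersection <- intersectTerms(
          enrichment, ecfg$selectedGo,
          if (is.null(ecfg$selectedPathways)) character()
          else ecfg$selectedPathways,
          pathwayMin = if (is.null(ecfg$pathwayMin)) 3L else ecfg$pathwayMin)
        log("intersection", "final nominee(s): %s",
            if (length(intersection$finalGenes))
              paste(intersection$finalGenes, collapse = ", ") else "(none)")
      }
    }
  }

  paths <- writeResults(cfg$outDir, part, me, stats, hubs, enrichment)
  if (!is.null(fitTable)) {
    p <- file.path(cfg$outDir, "scale_free_fit.tsv")
    utils::write.table(fitTable, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["fitTable"] <- p
  }
  if (!is.null(intersection)) {
    p <- file.path(cfg$outDir, "intersection_counts.tsv")
    utils::write.table(intersection$geneTermCounts, p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["intersection"] <- p
    p <- file.path(cfg$outDir, "final_genes.tsv")
    utils::write.table(data.frame(gene = intersection$finalGenes), p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths["finalGenes"] <- p
  }
  manifest <- data.frame(file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         row.names = NULL)
  mp <- file.path(cfg$outDir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log("done", "%d files in %s", length(paths) + 1L, cfg$outDir)

  invisible(list(expression = se, power = power, fitTable = fitTable,
                 network = net, partition = part, eigengenes = me,
                 targetModule = target, stats = stats, hubs = hubs,
                 enrichment = enrichment, intersection = intersection,
                 manifest = manifest, paths = paths))
}

# defaults for every pipeline parameter
.fillConfig <- function(config) {
  def <- list(
    expression = NULL, sampleSheet = NULL, delimiter = NULL,
    logTransform = TRUE,
    filter = list(minValue = 1, minFraction = 0.5, minMad = 0),
    network = list(power = "auto", type = "unsigned", r2Cut = 0.8,
                   blockSize = 1000L),
    modules = list(minSize = 50L, mergeSimilarity = 0.85,
                   cutMethod = "dynamic", deepSplit = 2L,
                   cutHeight = 0.995),
    targetSamples = NULL,
    hub = list(kMin = 900, kmeMin = 0.9, kQuantile = NULL),
    enrichment = NULL,
    outDir = NULL, seed = 1L)
  merge <- function(d, c) {
    for (nm in names(c)) {
      d[[nm]] <- if (is.list(c[[nm]]) && is.list(d[[nm]]) &&
                     !is.null(names(d[[nm]]))) {
        merge(d[[nm]], c[[nm]])
      } else c[[nm]]
    }
    d
  }
  merge(def, config)
}
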