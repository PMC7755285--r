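#' Select the target module from eigengene sample patterns
#'
#' Ranks modules by their mean eigengene value over a set of target samples
#' (e.g. the samples of the two most mature stages) and returns the module
#' expressed highest there — the eigengene analogue of reading the sample
#' expression-pattern heat map.
#'
#' @param me samples x modules eigengene matrix.
#' @param targetSamples character vector of sample ids (non-empty subset of
#'   `rownames(me)`).
#' @return list with `module` (the winning column name) and `ranking`
#'   (data.frame of all modules and their target-sample means, descending).
#' @export
selectTargetModule <- function(me, targetSamples) {
  if (!length(targetSamples)) stop("targetSamples must be non-empty")
  unknown <- setdiff(targetSamples, rownames(me))
  if (length(unknown)) stop("unknown sample id: ", unknown[1L])
  means <- colMeans(me[targetSamples, , drop = FALSE])
  ord <- order(means, decreasing = TRUE)
  list(module = colnames(me)[ord[1L]],
       ranking = data.frame(module = colnames(me)[ord],
                            targetMean = unname(means[ord])))
}

#' Gene-eigengene correlations with Student t p-values
#'
#' For every gene and every module eigengene, the Pearson correlation
#' (module membership, kME) and the two-sided p-value from
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} degrees of freedom
#' (\eqn{p = 0} at \eqn{r = \pm 1}).
#'
#' @param x genes x samples matrix or `SummarizedExperiment` (>= 3 samples).
#' @param me samples x modules eigengene matrix.
#' @return list with matrices `kme` and `p` (genes x modules).
#' @examples
#' # r = 0.9 with n = 21 samples gives t = 9 exactly
#' @export
kmeWithP <- function(x, me) {
  m <- .exprMatrix(x)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  if (!identical(colnames(m), rownames(me))) {
    me <- me[colnames(m), , drop = FALSE]
  }
  n <- ncol(m)
  r <- stats::cor(t(m), me)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  list(kme = r, p = p)
}

#' Assemble per-gene module statistics
#'
#' Combines whole-network connectivity with kME and p-values into a
#' [GeneModuleStats-class], the in-memory analogue of the connectivity and
#' gene-eigengene correlation result tables.
#'
#' @param x genes x samples matrix or `SummarizedExperiment`.
#' @param me samples x modules eigengene matrix.
#' @param network [CoexNetwork-class] (or adjacency matrix) over the same
#'   genes.
#' @param partition [ModulePartition-class] giving each gene's module.
#' @return A [GeneModuleStats-class].
#' @export
geneModuleStats <- function(x, me, network, partition) {
  m <- .exprMatrix(x)
  k <- connectivity(network)
  if (!identical(names(k), rownames(m))) k <- k[rownames(m)]
  lab <- moduleLabels(partition)[rownames(m)]
  if (length(partition@colorMap)) {
    lab <- stats::setNames(unname(partition@colorMap[lab]), names(lab))
  }
  kp <- kmeWithP(m, me)
  new("GeneModuleStats", gene = rownames(m), module = unname(lab),
      connectivity = unname(k), kme = kp$kme, p = kp$p,
      nSamples = ncol(m))
}

#' Dual-threshold hub screen
#'
#' Within one module, takes the genes with whole-network connectivity at
#' least `kMin` and the genes with kME to that module's eigengene at least
#' `kmeMin` (both thresholds inclusive; kME is signed — the screen asks for
#' positive association), and intersects the two sets.
#'
#' @param stats A [GeneModuleStats-class].
#' @param module module label (or color) to screen.
#' @param kMin connectivity threshold (default 900, the full-data
#'   convention; scale-dependent, see `kQuantile`).
#' @param kmeMin kME threshold (default 0.9).
#' @param kQuantile optional quantile in `[0, 1]`; when given, `kMin` is
#'   replaced by that quantile of the module genes' connectivity (useful
#'   when the absolute scale of k differs from the full-data setting).
#' @return A [HubScreenResult-class].
#' @export
screenHubs <- function(stats, module, kMin = 900, kmeMin = 0.9,
                       kQuantile = NULL) {
  if (!module %in% colnames(stats@kme)) {
    stop("module '", module, "' has no eigengene column in stats")
  }
  inMod <- stats@module == module
  if (!any(inMod)) stop("module '", module, "' contains no genes")
  k <- stats@connectivity[inMod]
  r <- stats@kme[inMod, module]
  genes <- stats@gene[inMod]
  if (!is.null(kQuantile)) {
    kMin <- unname(stats::quantile(k, kQuantile))
  }
  setK <- genes[k >= kMin]
  setKme <- genes[r >= kmeMin]
  hubs <- intersect(setK, setKme)
  new("HubScreenResult", module = module, kMin = kMin, kmeMin = kmeMin,
      setK = setK, setKme = setKme, hubs = hubs,
      vennCounts = c(onlyK = length(setdiff(setK, hubs)),
                     onlyKme = length(setdiff(setKme, hubs)),
                     both = length(hubs)))
}

#' Spearman concordance between two expression series
#'
#' Spearman rank correlation (average ranks for ties) between two ordered
#' series — e.g. qPCR versus RNA-seq stage means — with the conventional
#' strength band of `|Rs|`: (0.8, 1] extremely strong, (0.6, 0.8] strong,
#' (0.4, 0.6] medium, (0.2, 0.4] weak, `[0, 0.2]` none.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return list with `rho` and `band`.
#' @examples
#' spearmanConcordance(1:5, c(2, 3, 1, 5, 6))
#' @export
spearmanConcordance <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 paired observations")
  rho <- stats::cor(a, b, method = "spearman")
  abs_r <- abs(rho)
  band <- if (abs_r > 0.8) "extremely strong"
          else if (abs_r > 0.6) "strong"
          else if (abs_r > 0.4) "medium"
          else if (abs_r > 0.2) "weak"
          else "none"
  list(rho = rho, band = band)
}

#' Read supplementary-shaped connectivity / kME tables
#'
#' Loaders for externally produced result tables shaped like the package's
#' own outputs: a connectivity table (columns `gene`, `connectivity`,
#' optionally `module`) and a gene-eigengene correlation table (column
#' `gene` plus one numeric column per module). Together with
#' [screenHubs()] these allow the dual-threshold screen to be run on
#' published tables rather than a fresh network.
#'
#' @param connectivityPath,kmePath TSV paths.
#' @param module module column to screen.
#' @param kMin,kmeMin inclusive thresholds.
#' @return A [HubScreenResult-class].
#' @export
screenHubsFromTables <- function(connectivityPath, kmePath, module,
                                 kMin = 900, kmeMin = 0.9) {
  kt <- utils::read.delim(connectivityPath, stringsAsFactors = FALSE)
  rt <- utils::read.delim(kmePath, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("gene", "connectivity") %in% colnames(kt))) {
    stop("connectivity table needs columns 'gene' and 'connectivity'")
  }
  if (!"gene" %in% colnames(rt) || !module %in% colnames(rt)) {
    stop("kME table needs columns 'gene' and '", module, "'")
  }
  common <- intersect(kt$gene, rt$gene)
  k <- stats::setNames(kt$connectivity, kt$gene)[common]
  r <- stats::setNames(rt[[module]], rt$gene)[common]
  modCol <- if ("module" %in% colnames(kt)) {
    stats::setNames(kt$module, kt$gene)[common]
  } else rep(module, length(common))
  kme <- matrix(r, ncol = 1L, dimnames = list(common, module))
  stats <- new("GeneModuleStats", gene = common, module = unname(modCol),
               connectivity = unname(k), kme = kme,
               p = matrix(NA_real_, length(common), 1L,
                          dimnames = list(common, module)),
               nSamples = NA_integer_)
  screenHubs(stats, module, kMin = kMin, kmeMin = kmeMin)
}

#' @describeIn hubGenes hub genes of a screen result
#' @export
setMethod("hubGenes", "HubScreenResult", function(object) object@hubs)
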