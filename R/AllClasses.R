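#' @import methods
#' @importFrom stats cor mad sd quantile pt phyper p.adjust hclust cutree
#'   as.dist cophenetic runif rnorm setNames lm coef
#' @importFrom utils read.delim write.table head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Gene-set annotation collection
#'
#' Holds a collection of gene sets (GO-like terms or pathways) read from a
#' GMT file or built in code. Each term carries an identifier, a free-text
#' name and a namespace (`"BP"`, `"CC"`, `"MF"` or `"pathway"`) used to
#' batch the Benjamini-Hochberg correction in [hypergeomEnrich()].
#'
#' @slot termId character vector of unique term identifiers.
#' @slot termName character vector of term descriptions.
#' @slot namespace character vector; one of `BP`, `CC`, `MF`, `pathway`.
#' @slot genes list of character vectors, one non-empty, duplicate-free
#'   gene-id set per term.
#'
#' @seealso [readGmt()], [hypergeomEnrich()]
#' @export
setClass("AnnotationSet",
  representation(
    termId = "character",
    termName = "character",
    namespace = "character",
    genes = "list"
  )
)

setValidity("AnnotationSet", function(object) {
  n <- length(object@termId)
  if (length(object@termName) != n || length(object@namespace) != n ||
      length(object@genes) != n) {
    return("termId, termName, namespace and genes must have equal length")
  }
  if (anyDuplicated(object@termId)) {
    return(sprintf("duplicate term id: %s",
                   object@termId[duplicated(object@termId)][1L]))
  }
  bad <- !object@namespace %in% c("BP", "CC", "MF", "pathway")
  if (any(bad)) {
    return(sprintf("unknown namespace '%s'", object@namespace[bad][1L]))
  }
  sizes <- lengths(object@genes)
  if (any(sizes == 0L)) {
    return(sprintf("term '%s' has an empty gene set",
                   object@termId[sizes == 0L][1L]))
  }
  if (any(vapply(object@genes, anyDuplicated, 0L) > 0L)) {
    return("gene sets must not contain duplicates")
  }
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param termId,termName,namespace,genes see the class slots; `genes` is a
#'   list of character vectors (duplicates are removed).
#' @return An [AnnotationSet-class] object.
#' @examples
#' AnnotationSet("t1", "demo term", "BP", list(c("g1", "g2")))
#' @export
AnnotationSet <- function(termId, termName = termId,
                          namespace = "pathway", genes) {
  namespace <- rep_len(namespace, length(termId))
  termName <- rep_len(termName, length(termId))
  genes <- lapply(genes, function(g) unique(as.character(g)))
  names(genes) <- termId
  new("AnnotationSet", termId = as.character(termId),
      termName = as.character(termName),
      namespace = namespace, genes = genes)
}

#' Weighted co-expression network
#'
#' A soft-thresholded adjacency matrix \eqn{a_{ij} = |r_{ij}|^\beta}
#' (unsigned) or \eqn{a_{ij} = ((1 + r_{ij})/2)^\beta} (signed), with unit
#' diagonal, plus the power and network type that produced it.
#'
#' @slot adjacency symmetric numeric matrix in `[0, 1]` with unit diagonal
#'   and gene ids as dimnames.
#' @slot power integer soft-threshold power \eqn{\beta}.
#' @slot networkType `"unsigned"` or `"signed"`.
#'
#' @seealso [softAdjacency()], [connectivity()], [tomSimilarity()]
#' @export
setClass("CoexNetwork",
  representation(
    adjacency = "matrix",
    power = "integer",
    networkType = "character"
  )
)

setValidity("CoexNetwork", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a))) {
    return("adjacency needs identical gene-id row and column names")
  }
  if (anyNA(a) || any(!is.finite(a))) return("adjacency must be finite")
  if (any(a < 0) || any(a > 1)) return("adjacency values must lie in [0, 1]")
  if (max(abs(a - t(a))) > 1e-10) return("adjacency must be symmetric")
  if (max(abs(diag(a) - 1)) > 1e-10) return("adjacency diagonal must be 1")
  if (object@power < 1L) return("power must be >= 1")
  if (!object@networkType %in% c("unsigned", "signed")) {
    return("networkType must be 'unsigned' or 'signed'")
  }
  TRUE
})

#' Gene-to-module partition
#'
#' Maps every gene to a module label. Labels are `"1"`, `"2"`, ... in
#' decreasing module-size order, with `"0"` reserved for unassigned genes.
#' [assignColors()] attaches the conventional size-ranked color names
#' (turquoise, blue, brown, ...; unassigned mapped to grey).
#'
#' @slot labels named character vector, gene id -> module label.
#' @slot colorMap named character vector, module label -> color name; empty
#'   until [assignColors()] is called.
#'
#' @seealso [cutTree()], [mergeCloseModules()], [assignColors()]
#' @export
setClass("ModulePartition",
  representation(
    labels = "character",
    colorMap = "character"
  )
)

setValidity("ModulePartition", function(object) {
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels))) {
    return("labels must be uniquely named by gene id")
  }
  if (anyNA(object@labels)) return("labels must not contain NA")
  if (length(object@colorMap)) {
    lab <- setdiff(unique(object@labels), names(object@colorMap))
    if (length(lab)) {
      return(sprintf("colorMap is missing label '%s'", lab[1L]))
    }
  }
  TRUE
})

#' Per-gene module statistics
#'
#' Whole-network connectivity, per-module eigengene correlation (kME) and
#' the matching two-sided Student t p-values for every gene.
#'
#' @slot gene character vector of gene ids.
#' @slot module character vector; module label of each gene.
#' @slot connectivity numeric; \eqn{k_i = \sum_{j \ne i} a_{ij}}.
#' @slot kme genes x modules matrix of Pearson correlations with the
#'   module eigengenes.
#' @slot p genes x modules matrix of two-sided p-values
#'   (\eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} df).
#' @slot nSamples integer; number of samples the correlations used.
#'
#' @seealso [geneModuleStats()], [screenHubs()]
#' @export
setClass("GeneModuleStats",
  representation(
    gene = "character",
    module = "character",
    connectivity = "numeric",
    kme = "matrix",
    p = "matrix",
    nSamples = "integer"
  )
)

setValidity("GeneModuleStats", function(object) {
  n <- length(object@gene)
  if (length(object@module) != n || length(object@connectivity) != n ||
      nrow(object@kme) != n || nrow(object@p) != n) {
    return("gene, module, connectivity, kme and p sizes disagree")
  }
  if (!identical(dim(object@kme), dim(object@p))) {
    return("kme and p must have identical dimensions")
  }
  if (any(abs(object@kme) > 1 + 1e-8, na.rm = TRUE)) {
    return("|kME| must be <= 1")
  }
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE)) {
    return("p-values must lie in [0, 1]")
  }
  TRUE
})

#' Dual-threshold hub screen result
#'
#' Genes of one module passing the connectivity threshold, the kME
#' threshold, and both (the hub set), with the Venn counts.
#'
#' @slot module module label screened.
#' @slot kMin,kmeMin inclusive thresholds.
#' @slot setK genes with connectivity >= kMin.
#' @slot setKme genes with kME >= kmeMin.
#' @slot hubs intersection of the two sets.
#' @slot vennCounts named integer vector (`onlyK`, `onlyKme`, `both`).
#'
#' @seealso [screenHubs()]
#' @export
setClass("HubScreenResult",
  representation(
    module = "character",
    kMin = "numeric",
    kmeMin = "numeric",
    setK = "character",
    setKme = "character",
    hubs = "character",
    vennCounts = "integer"
  )
)

setValidity("HubScreenResult", function(object) {
  if (!all(object@hubs %in% object@setK) ||
      !all(object@hubs %in% object@setKme)) {
    return("hubs must be contained in both threshold sets")
  }
  vc <- object@vennCounts
  ok <- identical(sort(names(vc)), sort(c("onlyK", "onlyKme", "both"))) &&
    vc[["both"]] == length(object@hubs) &&
    vc[["onlyK"]] == length(setdiff(object@setK, object@hubs)) &&
    vc[["onlyKme"]] == length(setdiff(object@setKme, object@hubs))
  if (!ok) return("vennCounts inconsistent with the gene sets")
  TRUE
})

#' Synthetic study design
#'
#' Parameters of the planted-module expression simulator: an ordered
#' multi-stage design with replicates, several modules whose members are
#' noisy scalings of a shared stage profile with known per-gene correlation
#' (kME), one module whose profile rises to a peak in the last two stages
#' (the maturation-stage target), and unstructured background genes.
#'
#' @slot nStages integer; ordered sample groups (default 7).
#' @slot nReps integer; replicates per stage (default 3).
#' @slot moduleSizes integer vector; genes per planted module.
#' @slot kmeRange numeric length-2; per-gene kME drawn uniformly in
#'   `[low, high]`, `0 < low <= high < 1`.
#' @slot nBackground integer; genes with no module structure.
#' @slot targetModule integer; index of the late-peaking module.
#' @slot noiseSd positive numeric; within-stage replicate jitter of the
#'   module profiles (on the standardized latent scale).
#' @slot seed integer; RNG seed, making generation a pure function of the
#'   design.
#'
#' @seealso [syntheticDesign()], [simulateExpression()]
#' @export
setClass("SyntheticDesign",
  representation(
    nStages = "integer",
    nReps = "integer",
    moduleSizes = "integer",
    kmeRange = "numeric",
    nBackground = "integer",
    targetModule = "integer",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticDesign", function(object) {
  if (object@nStages < 1L) return("nStages must be >= 1")
  if (object@nReps < 1L) return("nReps must be >= 1")
  if (length(object@moduleSizes) < 1L || any(object@moduleSizes < 1L)) {
    return("moduleSizes must all be >= 1")
  }
  kr <- object@kmeRange
  if (length(kr) != 2L || kr[1L] <= 0 || kr[1L] > kr[2L] || kr[2L] >= 1) {
    return("kmeRange must satisfy 0 < low <= high < 1")
  }
  if (object@nBackground < 0L) return("nBackground must be >= 0")
  if (object@targetModule < 1L ||
      object@targetModule > length(object@moduleSizes)) {
    return("targetModule must index a planted module")
  }
  if (object@noiseSd <= 0) return("noiseSd must be positive")
  TRUE
})

#' Ground truth of a simulated data set
#'
#' @slot gene character; all generated gene ids.
#' @slot module character; planted module index as character, or
#'   `"background"`.
#' @slot kme numeric; planted gene-profile correlation (NA for background).
#' @slot stageProfiles stages x modules matrix of the noise-free module
#'   profiles.
#' @slot hubGenes list (per module) of genes with planted kME >= 0.9.
#' @slot nominee character; the target-module gene planted into every
#'   selected enrichment term by [writeFixtureBundle()].
#'
#' @seealso [simulateExpression()]
#' @export
setClass("SyntheticTruth",
  representation(
    gene = "character",
    module = "character",
    kme = "numeric",
    stageProfiles = "matrix",
    hubGenes = "list",
    nominee = "character"
  )
)

setValidity("SyntheticTruth", function(object) {
  n <- length(object@gene)
  if (anyDuplicated(object@gene)) return("gene ids must be unique")
  if (length(object@module) != n || length(object@kme) != n) {
    return("gene, module and kme lengths disagree")
  }
  TRUE
})
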