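#' Whole-network connectivity
#'
#' Connectivity of gene *i* is the sum of its adjacency weights to all other
#' genes, \eqn{k_i = \sum_{j \ne i} a_{ij}} (diagonal excluded).
#'
#' @param object A [CoexNetwork-class] or a symmetric adjacency matrix.
#' @return Named numeric vector of per-gene connectivities.
#' @examples
#' a <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
#' connectivity(a)
#' @export
setGeneric("connectivity", function(object) standardGeneric("connectivity"))

#' Topological overlap matrix
#'
#' Transforms an adjacency matrix into the topological overlap measure
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
#'   \quad l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},}
#' with unit diagonal. Two genes overlap strongly when they are directly
#' connected and share neighbours.
#'
#' @param object A [CoexNetwork-class] or adjacency matrix.
#' @param blockSize integer; columns are processed in blocks of this size so
#'   large networks never materialize more than one `n x blockSize` product
#'   at a time.
#' @return Symmetric numeric matrix in `[0, 1]` with unit diagonal.
#' @examples
#' a <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
#' tomSimilarity(a) # isolated perfect pair: TOM = 1
#' @export
setGeneric("tomSimilarity", function(object, blockSize = 1000L)
  standardGeneric("tomSimilarity"))

#' Keep well-measured genes before network construction
#'
#' Keeps genes whose expression is at least `minValue` in at least
#' `minFraction` of the samples and whose median absolute deviation exceeds
#' `minMad`. Gene order is preserved; a log record with kept/dropped counts
#' is attached (see Details).
#'
#' @details For a `SummarizedExperiment` the log is stored in
#'   `metadata(x)$filterLog`; for a matrix it is attached as
#'   `attr(x, "filterLog")`. Filtering is idempotent.
#'
#' @param x `SummarizedExperiment` (genes in rows) or numeric matrix.
#' @param minValue,minFraction,minMad non-negative thresholds; defaults keep
#'   genes with expression >= 1 (FPKM) in >= 50% of samples and MAD > 0.
#' @return Filtered object of the same class as `x`.
#' @examples
#' m <- rbind(keep = c(2, 3, 4, 5), zero = c(0, 0, 0, 0))
#' colnames(m) <- paste0("s", 1:4)
#' filterGenes(m)
#' @export
setGeneric("filterGenes", function(x, minValue = 1, minFraction = 0.5,
                                   minMad = 0) standardGeneric("filterGenes"))

#' Log2 transform expression values
#'
#' Replaces values by `log2(value + 1)`; ids and metadata are unchanged.
#' Correlations downstream are computed on this variance-stabilized scale
#' by default.
#'
#' @param x `SummarizedExperiment` or non-negative numeric matrix.
#' @return Object of the same class as `x`.
#' @examples
#' logTransform(matrix(c(0, 1, 7), 1, dimnames = list("g", c("a", "b", "c"))))
#' @export
setGeneric("logTransform", function(x) standardGeneric("logTransform"))

#' Pearson correlation matrix across samples
#'
#' @param x `SummarizedExperiment` or genes x samples numeric matrix; at
#'   least 3 samples, no zero-variance gene (run [filterGenes()] first).
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8.5))
#' colnames(m) <- paste0("s", 1:4)
#' correlationMatrix(m)
#' @export
setGeneric("correlationMatrix", function(x) standardGeneric("correlationMatrix"))

#' Module sizes, labels and colors
#'
#' Accessors for [ModulePartition-class]: per-gene labels, module sizes in
#' decreasing order (unassigned excluded), and the label -> color map.
#'
#' @param object A [ModulePartition-class].
#' @return `moduleLabels`: named character vector (gene -> label);
#'   `moduleSizes`: named integer vector; `moduleColors`: named character
#'   vector gene -> color (requires [assignColors()]).
#' @name partition-accessors
NULL

#' @rdname partition-accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname partition-accessors
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))

#' @rdname partition-accessors
#' @export
setGeneric("moduleColors", function(object) standardGeneric("moduleColors"))

#' Adjacency matrix accessor
#' @param object A [CoexNetwork-class].
#' @return Numeric matrix.
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' Soft-threshold power accessor
#' @param object A [CoexNetwork-class].
#' @return Integer power.
#' @export
setGeneric("softPower", function(object) standardGeneric("softPower"))

#' AnnotationSet term accessors
#' @param object An [AnnotationSet-class].
#' @return `termIds`: character vector; `termGenes`: named list of gene-id
#'   vectors.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("termIds", function(object) standardGeneric("termIds"))

#' @rdname annotation-accessors
#' @export
setGeneric("termGenes", function(object) standardGeneric("termGenes"))

#' Hub set accessor
#' @param object A [HubScreenResult-class].
#' @return Character vector of hub gene ids.
#' @export
setGeneric("hubGenes", function(object) standardGeneric("hubGenes"))
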