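#' @describeIn AnnotationSet-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet with", length(object@termId), "terms\n")
  tab <- table(object@namespace)
  cat("  namespaces:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  gene-set sizes:", paste(range(lengths(object@genes)),
                                 collapse = "-"), "\n")
})

#' @describeIn CoexNetwork-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "CoexNetwork", function(object) {
  cat(sprintf("CoexNetwork: %d genes, %s, beta = %d\n",
              nrow(object@adjacency), object@networkType, object@power))
  k <- connectivity(object)
  cat(sprintf("  connectivity: mean %.3g, max %.3g\n", mean(k), max(k)))
})

#' @describeIn ModulePartition-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "ModulePartition", function(object) {
  sizes <- moduleSizes(object)
  unas <- sum(object@labels == .unassignedLabel)
  cat(sprintf("ModulePartition: %d genes, %d modules, %d unassigned\n",
              length(object@labels), length(sizes), unas))
  if (length(sizes)) {
    nm <- if (length(object@colorMap)) {
      unname(object@colorMap[names(sizes)])
    } else names(sizes)
    cat("  sizes:", paste(sprintf("%s=%d", nm, sizes), collapse = ", "),
        "\n")
  }
})

#' @describeIn GeneModuleStats-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "GeneModuleStats", function(object) {
  cat(sprintf("GeneModuleStats: %d genes x %d modules (n = %d samples)\n",
              length(object@gene), ncol(object@kme), object@nSamples))
})

#' @describeIn HubScreenResult-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "HubScreenResult", function(object) {
  cat(sprintf("HubScreenResult for module '%s'\n", object@module))
  cat(sprintf("  k >= %.4g: %d genes; kME >= %.3g: %d genes; hubs: %d\n",
              object@kMin, length(object@setK), object@kmeMin,
              length(object@setKme), length(object@hubs)))
})

#' @describeIn SyntheticDesign-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(
    "SyntheticDesign: %d stages x %d reps, %d modules (%s genes), %d background\n",
    object@nStages, object@nReps, length(object@moduleSizes),
    paste(object@moduleSizes, collapse = "+"), object@nBackground))
  cat(sprintf("  kME in [%.2f, %.2f], target module %d, seed %d\n",
              object@kmeRange[1L], object@kmeRange[2L], object@targetModule,
              object@seed))
})

#' @describeIn SyntheticTruth-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "SyntheticTruth", function(object) {
  tab <- table(object@module)
  cat("SyntheticTruth:", length(object@gene), "genes;",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  nominee:", object@nominee, "\n")
})

#' @describeIn annotation-accessors term ids
#' @export
setMethod("termIds", "AnnotationSet", function(object) object@termId)

#' @describeIn annotation-accessors named list of gene sets
#' @export
setMethod("termGenes", "AnnotationSet", function(object) {
  stats::setNames(object@genes, object@termId)
})
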