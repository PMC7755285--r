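#' Hypergeometric gene-set enrichment
#'
#' For every term, tests whether the query (e.g. the hub-gene set) overlaps
#' the term's genes more than expected when drawing `q` genes from a
#' universe of `N` with `K` marked: the one-sided upper-tail hypergeometric
#' probability \eqn{P(X \ge m)}. P-values are Benjamini-Hochberg adjusted
#' within each namespace batch (BP, CC, MF, pathway) and results are sorted
#' by p-value.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param annotation An [AnnotationSet-class]; term gene sets are
#'   intersected with the universe, terms that vanish are dropped.
#' @param universe character vector of background gene ids (conventionally
#'   all genes surviving [filterGenes()]).
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05).
#' @return data.frame with columns `termId`, `termName`, `namespace`,
#'   `overlap`, `termSize`, `querySize`, `universeSize`, `pValue`,
#'   `adjustedP`, `significant`, `genes` (comma-separated overlap).
#' @examples
#' ann <- AnnotationSet("t1", "demo", "BP", list(c("g1", "g2", "g3")))
#' hypergeomEnrich(c("g1", "g2"), ann, paste0("g", 1:10))
#' @export
hypergeomEnrich <- function(query, annotation, universe, alpha = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stop("query gene set is empty")
  if (!length(universe)) stop("universe gene set is empty")
  bad <- setdiff(query, universe)
  if (length(bad)) {
    stop("query gene not in universe: ", bad[1L])
  }
  N <- length(universe)
  q <- length(query)
  termSets <- lapply(annotation@genes, intersect, universe)
  keep <- lengths(termSets) > 0L
  if (!any(keep)) stop("no annotation term overlaps the universe")
  termSets <- termSets[keep]

  overlapSets <- lapply(termSets, intersect, query)
  K <- lengths(termSets)
  m <- lengths(overlapSets)
  p <- stats::phyper(m - 1L, K, N - K, q, lower.tail = FALSE)
  res <- data.frame(
    termId = annotation@termId[keep],
    termName = annotation@termName[keep],
    namespace = annotation@namespace[keep],
    overlap = m,
    termSize = K,
    querySize = q,
    universeSize = N,
    pValue = p,
    adjustedP = NA_real_,
    genes = vapply(overlapSets, paste, "", collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (ns in unique(res$namespace)) {
    sel <- res$namespace == ns
    res$adjustedP[sel] <- stats::p.adjust(res$pValue[sel], method = "BH")
  }
  res$significant <- res$adjustedP <= alpha
  res[order(res$pValue, res$termId), c(
    "termId", "termName", "namespace", "overlap", "termSize", "querySize",
    "universeSize", "pValue", "adjustedP", "significant", "genes")]
}

#' Multi-term intersection nominating final hub genes
#'
#' Given an enrichment table and user-selected GO terms and pathways,
#' returns the genes present in the overlap of *every* selected GO term and
#' in at least `pathwayMin` selected pathways — the intersection logic that
#' narrows a hub candidate list to its final nominee(s).
#'
#' @param results data.frame from [hypergeomEnrich()].
#' @param selectedGoTerms,selectedPathways character vectors of term ids
#'   present in `results`.
#' @param pathwayMin minimum number of selected pathways a final gene must
#'   appear in (default 3).
#' @return list with `finalGenes`, `geneTermCounts` (data.frame: gene,
#'   goCount, pathwayCount) and `selectedTerms`.
#' @export
intersectTerms <- function(results, selectedGoTerms,
                           selectedPathways = character(), pathwayMin = 3L) {
  selected <- c(selectedGoTerms, selectedPathways)
  unknown <- setdiff(selected, results$termId)
  if (length(unknown)) stop("unknown term id: ", unknown[1L])
  geneList <- function(ids) {
    sets <- strsplit(results$genes[match(ids, results$termId)], ",",
                     fixed = TRUE)
    lapply(sets, function(g) g[nzchar(g)])
  }
  goSets <- geneList(selectedGoTerms)
  pwSets <- geneList(selectedPathways)
  allGenes <- unique(unlist(c(goSets, pwSets)))
  goCount <- vapply(allGenes, function(g)
    sum(vapply(goSets, function(s) g %in% s, TRUE)), 0L)
  pwCount <- vapply(allGenes, function(g)
    sum(vapply(pwSets, function(s) g %in% s, TRUE)), 0L)
  final <- allGenes[goCount == length(goSets) & pwCount >= pathwayMin]
  counts <- data.frame(gene = allGenes, goCount = goCount,
                       pathwayCount = pwCount, row.names = NULL)
  counts <- counts[order(-counts$goCount, -counts$pathwayCount,
                         counts$gene), ]
  list(finalGenes = sort(final), geneTermCounts = counts,
       selectedTerms = selected)
}
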