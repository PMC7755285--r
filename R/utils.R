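# internal helpers shared across modules

# evaluate `code` under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# genes-in-rows numeric matrix from SummarizedExperiment or matrix input
.exprMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, 1L)
  } else if (is.matrix(x) && is.numeric(x)) {
    m <- x
  } else {
    stop("expected a SummarizedExperiment or a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  m
}

.checkSymmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be square")
  }
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric")
  }
  invisible(m)
}

# replace a label's occurrences, used when merging modules
.relabel <- function(labels, from, to) {
  labels[labels == from] <- to
  labels
}

# standardize matrix rows to zero mean, unit variance
.standardizeRows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  if (any(s == 0)) {
    stop("zero-variance gene: ", rownames(m)[which(s == 0)[1L]])
  }
  (m - mu) / s
}

.unassignedLabel <- "0"

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same genes,
#' used to score recovery of planted modules. 1 means identical partitions
#' (up to label permutation), 0 is the expected value under independence.
#'
#' @param a,b vectors of labels of equal length (coerced to character).
#' @return Numeric scalar.
#' @examples
#' adjustedRand(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjustedRand <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(as.character(a), as.character(b))
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}
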