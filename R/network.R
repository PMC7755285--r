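#' @describeIn correlationMatrix genes x samples numeric matrix
#' @export
setMethod("correlationMatrix", "matrix", function(x) {
  if (ncol(x) < 3L) stop("need at least 3 samples to correlate genes")
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0)) {
    stop("zero-variance gene: ", rownames(x)[which(s == 0)[1L]],
         "; run filterGenes() first")
  }
  r <- stats::cor(t(x))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
})

#' @describeIn correlationMatrix `SummarizedExperiment` (assay 1)
#' @export
setMethod("correlationMatrix", "SummarizedExperiment", function(x) {
  correlationMatrix(.exprMatrix(x))
})

#' Soft-threshold adjacency
#'
#' Raises correlation-based similarity to the power \eqn{\beta}:
#' unsigned networks use \eqn{a_{ij} = |r_{ij}|^\beta}, signed networks
#' \eqn{a_{ij} = ((1 + r_{ij})/2)^\beta}. The diagonal is forced to 1.
#' Soft thresholding preserves the continuous nature of co-expression while
#' pushing the degree distribution toward scale-free topology.
#'
#' @param correlation symmetric genes x genes correlation matrix.
#' @param power integer soft-threshold power, >= 1.
#' @param networkType `"unsigned"` (default; the historical default of the
#'   method) or `"signed"`.
#' @return A [CoexNetwork-class].
#' @examples
#' r <- matrix(c(1, -0.5, -0.5, 1), 2,
#'             dimnames = list(c("g1", "g2"), c("g1", "g2")))
#' adjacency(softAdjacency(r, 4))["g1", "g2"] # 0.0625
#' @export
softAdjacency <- function(correlation, power,
                          networkType = c("unsigned", "signed")) {
  networkType <- match.arg(networkType)
  .checkSymmetric(correlation, "correlation matrix")
  if (length(power) != 1L || !is.finite(power) || power < 1) {
    stop("power must be a single number >= 1")
  }
  a <- if (networkType == "unsigned") {
    abs(correlation)^power
  } else {
    ((1 + correlation) / 2)^power
  }
  diag(a) <- 1
  new("CoexNetwork", adjacency = a, power = as.integer(power),
      networkType = networkType)
}

#' @describeIn connectivity from a raw adjacency matrix
#' @export
setMethod("connectivity", "matrix", function(object) {
  .checkSymmetric(object, "adjacency matrix")
  rowSums(object) - diag(object)
})

#' @describeIn connectivity from a [CoexNetwork-class]
#' @export
setMethod("connectivity", "CoexNetwork", function(object) {
  connectivity(object@adjacency)
})

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivities into `nBins` equal-width bins and regresses
#' log10(frequency) on log10(mean connectivity) over the non-empty bins.
#' A scale-free network shows an approximately linear relation with
#' negative slope; `rSquared` is the coefficient of determination of that
#' regression.
#'
#' @param k numeric vector of per-gene connectivities.
#' @param nBins number of equal-width bins (default 10).
#' @return list with `rSquared`, `slope`, `meanConnectivity`, and
#'   `signedRSquared` (`rSquared` when the slope is negative, else its
#'   negation — the usual sign convention for power selection).
#' @examples
#' k <- rep(1:10, times = round(100 * (1:10)^-2))
#' scaleFreeFit(k)$rSquared
#' @export
scaleFreeFit <- function(k, nBins = 10L) {
  if (length(k) < 2L || !all(is.finite(k))) {
    stop("k must be a finite vector of length >= 2")
  }
  if (min(k) == max(k)) {
    stop("connectivity is constant: a single bin cannot be regressed")
  }
  breaks <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE)
  freq <- tabulate(bin, nbins = nBins)
  meanK <- vapply(seq_len(nBins), function(b)
    if (freq[b] > 0L) mean(k[bin == b]) else NA_real_, 0)
  use <- freq > 0L & meanK > 0
  if (sum(use) < 2L) {
    stop("fewer than 2 usable bins; connectivity distribution is degenerate")
  }
  x <- log10(meanK[use])
  y <- log10(freq[use])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fitted <- mean(y) + slope * (x - mean(x))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - sum((y - fitted)^2) / tss
  list(rSquared = r2, slope = slope, meanConnectivity = mean(k),
       signedRSquared = if (is.na(slope)) NA_real_ else sign(-slope) * r2)
}

#' Choose the soft-threshold power
#'
#' Sweeps candidate powers, computing the scale-free fit of the resulting
#' connectivity distribution for each, and returns the smallest power whose
#' fit R-squared (with negative slope) exceeds `r2Cut`. If no power
#' reaches the cut, the first power at which the R-squared curve plateaus
#' (increase over the previous power < 0.01) is returned and flagged.
#'
#' @param x `SummarizedExperiment` or genes x samples matrix (already
#'   filtered and, conventionally, log-transformed).
#' @param powers integer candidates (default 1:20).
#' @param r2Cut R-squared threshold (default 0.8).
#' @param networkType `"unsigned"` or `"signed"`.
#' @param nBins bins for [scaleFreeFit()].
#' @param isCorrelation set `TRUE` when `x` is already a genes x genes
#'   correlation matrix.
#' @return list with `power` (selected), `flagged` (`TRUE` when the plateau
#'   fallback was used) and `fitTable` (data.frame: power, rSquared, slope,
#'   signedRSquared, meanConnectivity).
#' @export
pickSoftThreshold <- function(x, powers = 1:20, r2Cut = 0.8,
                              networkType = c("unsigned", "signed"),
                              nBins = 10L, isCorrelation = FALSE) {
  networkType <- match.arg(networkType)
  if (!length(powers)) stop("powers must be non-empty")
  r <- if (isCorrelation) {
    .checkSymmetric(x, "correlation matrix")
  } else {
    correlationMatrix(x)
  }
  base <- if (networkType == "unsigned") abs(r) else (1 + r) / 2
  diag(base) <- NA # excluded from connectivity

  rows <- lapply(powers, function(p) {
    a <- base^p
    k <- rowSums(a, na.rm = TRUE)
    fit <- tryCatch(scaleFreeFit(k, nBins), error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(power = p, rSquared = NA_real_, slope = NA_real_,
                 signedRSquared = NA_real_, meanConnectivity = mean(k))
    } else {
      data.frame(power = p, rSquared = fit$rSquared, slope = fit$slope,
                 signedRSquared = fit$signedRSquared,
                 meanConnectivity = fit$meanConnectivity)
    }
  })
  fitTable <- do.call(rbind, rows)

  passes <- !is.na(fitTable$signedRSquared) & fitTable$signedRSquared > r2Cut
  if (any(passes)) {
    return(list(power = fitTable$power[which(passes)[1L]], flagged = FALSE,
                fitTable = fitTable))
  }
  # plateau fallback: first power whose signed R^2 gain drops below 0.01
  s <- fitTable$signedRSquared
  gain <- diff(s)
  plateau <- which(!is.na(gain) & gain < 0.01)
  pw <- if (length(plateau)) fitTable$power[plateau[1L] + 1L]
        else fitTable$power[nrow(fitTable)]
  warning("no candidate power reached R^2 > ", r2Cut,
          "; returning plateau power ", pw)
  list(power = pw, flagged = TRUE, fitTable = fitTable)
}

#' @describeIn tomSimilarity from a raw adjacency matrix
#' @export
setMethod("tomSimilarity", "matrix", function(object, blockSize = 1000L) {
  a <- object
  .checkSymmetric(a, "adjacency matrix")
  if (any(a < 0) || any(a > 1)) stop("adjacency values must lie in [0, 1]")
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  dg <- diag(a)
  tom <- matrix(0, n, n, dimnames = dimnames(a))
  # shared-neighbour sums via one matrix product per column block:
  # (A %*% A)[i, j] = sum_u a_iu a_uj; subtract the u = i and u = j terms
  for (start in seq(1L, n, by = blockSize)) {
    cols <- start:min(start + blockSize - 1L, n)
    ab <- a %*% a[, cols, drop = FALSE]
    l <- ab - dg * a[, cols, drop = FALSE] -
      a[, cols, drop = FALSE] * rep(dg[cols], each = n)
    kmin <- pmin(matrix(k, n, length(cols)),
                 matrix(k[cols], n, length(cols), byrow = TRUE))
    tom[, cols] <- (l + a[, cols, drop = FALSE]) /
      (kmin + 1 - a[, cols, drop = FALSE])
  }
  diag(tom) <- 1
  (tom + t(tom)) / 2
})

#' @describeIn tomSimilarity from a [CoexNetwork-class]
#' @export
setMethod("tomSimilarity", "CoexNetwork", function(object, blockSize = 1000L) {
  tomSimilarity(object@adjacency, blockSize = blockSize)
})
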