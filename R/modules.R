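#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' Clusters the TOM dissimilarity `1 - TOM` with average linkage, the
#' standard choice for co-expression dendrograms.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal, values in
#'   `[0, 1]`, gene ids as dimnames.
#' @return An `hclust` object.
#' @export
averageLinkageCluster <- function(d) {
  .checkSymmetric(d, "dissimilarity matrix")
  if (max(abs(diag(d))) > 1e-10) stop("dissimilarity diagonal must be 0")
  if (any(d < -1e-10) || any(d > 1 + 1e-10)) {
    stop("dissimilarity values must lie in [0, 1]")
  }
  stats::hclust(stats::as.dist(d), method = "average")
}

# per-node bookkeeping for a hclust tree: leaf members and subtree height
# of every internal node, plus each node's parent
.treeIndex <- function(dend) {
  n <- length(dend$order)
  merge <- dend$merge
  members <- vector("list", n - 1L)
  maxHeight <- numeric(n - 1L)
  parent <- integer(n - 1L)
  leafParent <- integer(n)
  for (i in seq_len(n - 1L)) {
    pick <- function(j) {
      if (j < 0L) {
        leafParent[-j] <<- i
        list(m = -j, h = 0)
      } else {
        parent[j] <<- i
        list(m = members[[j]], h = maxHeight[j])
      }
    }
    a <- pick(merge[i, 1L]); b <- pick(merge[i, 2L])
    members[[i]] <- c(a$m, b$m)
    maxHeight[i] <- max(dend$height[i], a$h, b$h)
  }
  list(members = members, maxHeight = maxHeight, parent = parent,
       leafParent = leafParent, n = n)
}

# recursively split an internal node into branches; a join is broken when
# both children are large enough and the join height clears each child's
# internal height by a deepSplit-controlled gap. Returns a list of
# branches, each list(members, height = the branch root's merge height).
.splitNode <- function(node, dend, idx, minSize, gapFrac) {
  merge <- dend$merge
  children <- merge[node, ]
  childInfo <- lapply(children, function(j) {
    if (j < 0L) list(node = NA_integer_, members = -j, h = 0)
    else list(node = j, members = idx$members[[j]], h = idx$maxHeight[j])
  })
  sizes <- vapply(childInfo, function(c) length(c$members), 0L)
  h <- dend$height[node]
  gapOk <- all(vapply(childInfo, function(c) (h - c$h) >= gapFrac * h,
                      TRUE))
  if (all(sizes >= minSize) && gapOk) {
    unlist(lapply(childInfo, function(c) {
      if (is.na(c$node)) list(list(members = c$members, height = 0))
      else .splitNode(c$node, dend, idx, minSize, gapFrac)
    }), recursive = FALSE)
  } else {
    list(list(members = idx$members[[node]], height = dend$height[node]))
  }
}

# iterated branch trimming: a genuine member must sit decisively closer to
# its module than the most dissimilar pairs in the whole tree. Members
# whose average dissimilarity to the (shrinking) core exceeds the fence
# med + 0.6 * (hMax - med) -- i.e. past 60% of the way from the core
# median to the tree's top height -- are demoted; typically these are
# noise genes chained into the branch late in the agglomeration. A
# homogeneous tight branch has every member far below the fence and is
# never trimmed.
.trimBranch <- function(members, height, d, minSize, hMax) {
  fence <- hMax
  avgd <- NULL
  for (it in seq_len(25L)) {
    avgd <- (rowSums(d[members, members, drop = FALSE])) /
      (length(members) - 1L)
    med <- stats::median(avgd)
    q1 <- stats::quantile(avgd, 0.25, names = FALSE)
    q3 <- stats::quantile(avgd, 0.75, names = FALSE)
    fenceMid <- med + 0.6 * (hMax - med)
    # gross outliers: if the sorted scatter above the median shows a jump
    # dwarfing the core spread, everything beyond the jump is foreign
    fenceGap <- Inf
    upper <- sort(avgd[avgd >= med])
    if (length(upper) >= 3L) {
      gaps <- diff(upper)
      big <- gaps > max(3 * (q3 - q1), 0.02 * hMax)
      if (any(big)) fenceGap <- upper[which(big)[1L]]
    }
    fence <- min(fenceMid, fenceGap)
    out <- avgd > fence + 1e-12
    if (!any(out) || length(members) - sum(out) < minSize) break
    members <- members[!out]
  }
  # adoption radius: a stray may only join if it sits within the observed
  # member scatter and could have merged below the branch root
  list(members = members,
       fence = min(fence, max(avgd[avgd <= fence + 1e-12]),
                   if (height > 0) height else hMax))
}

#' Cut a co-expression dendrogram into modules
#'
#' Two cutting modes. `"static"` severs the tree at the absolute height
#' `cutHeight` and discards clusters below `minSize` as unassigned.
#' `"dynamic"` implements the core of the dynamic-hybrid approach: branches
#' are first separated at `cutHeight` (interpreted as a fraction of the top
#' merge height), each branch is recursively split wherever both
#' sub-branches hold at least `minSize` genes and their internal merge
#' heights dip below the join height by a gap controlled by `deepSplit`
#' (0 = conservative ... 3 = aggressive), and leftover genes are then
#' assigned to the nearest module by average dissimilarity when they fall
#' within that module's radius (its largest member-to-module average
#' dissimilarity), else left unassigned.
#'
#' @param dend `hclust` tree from [averageLinkageCluster()].
#' @param d the dissimilarity matrix the tree was built from.
#' @param minSize minimum module size (default 50).
#' @param method `"dynamic"` (default) or `"static"`.
#' @param cutHeight in `[0, 1]`; absolute height for `"static"`, fraction
#'   of the top merge height for `"dynamic"` (default 0.995).
#' @param deepSplit integer 0-3 (default 2).
#' @return A [ModulePartition-class]; labels `"1"`, `"2"`, ... by
#'   decreasing size, `"0"` for unassigned genes.
#' @export
cutTree <- function(dend, d, minSize = 50L,
                    method = c("dynamic", "static"), cutHeight = 0.995,
                    deepSplit = 2L) {
  method <- match.arg(method)
  if (minSize < 1L) stop("minSize must be >= 1")
  if (cutHeight < 0 || cutHeight > 1) stop("cutHeight must lie in [0, 1]")
  if (!deepSplit %in% 0:3) stop("deepSplit must be 0, 1, 2 or 3")
  genes <- dend$labels
  n <- length(genes)
  d <- d[genes, genes] # align with leaf order

  labels <- rep(.unassignedLabel, n)
  names(labels) <- genes

  if (method == "static") {
    cl <- stats::cutree(dend, h = cutHeight)
    clusters <- split(seq_len(n), cl)
    keep <- clusters[lengths(clusters) >= minSize]
    keep <- keep[order(lengths(keep), decreasing = TRUE)]
    for (i in seq_along(keep)) labels[keep[[i]]] <- as.character(i)
    return(new("ModulePartition", labels = labels, colorMap = character()))
  }

  hCut <- cutHeight * max(dend$height)
  idx <- .treeIndex(dend)
  gapFrac <- c(0.20, 0.10, 0.05, 0.025)[deepSplit + 1L]
  # branch roots: maximal nodes at or below the cut height
  roots <- which(idx$maxHeight <= hCut &
                   (idx$parent == 0L | idx$maxHeight[pmax(idx$parent, 1L)] > hCut))
  branches <- list()
  for (v in roots) {
    branches <- c(branches, .splitNode(v, dend, idx, minSize, gapFrac))
  }
  branches <- branches[order(vapply(branches, function(b)
    length(b$members), 0L), decreasing = TRUE)]

  cores <- list()
  fences <- numeric()
  for (b in branches) {
    if (length(b$members) < minSize) next
    tr <- .trimBranch(b$members, b$height, d, minSize, max(dend$height))
    if (length(tr$members) >= minSize) {
      cores[[length(cores) + 1L]] <- tr$members
      fences[length(fences) + 1L] <- tr$fence
    }
  }
  if (length(cores)) {
    for (i in seq_along(cores)) labels[cores[[i]]] <- as.character(i)
    # hybrid stage: adopt stray genes that fall within a module's fence
    leftover <- which(labels == .unassignedLabel)
    for (g in leftover) {
      avg <- vapply(cores, function(m) mean(d[g, m]), 0)
      best <- which.min(avg)
      if (avg[best] <= fences[best]) labels[g] <- as.character(best)
    }
  }
  new("ModulePartition", labels = labels, colorMap = character())
}

#' Module eigengene of one gene set
#'
#' Standardizes each gene to zero mean and unit variance across samples and
#' returns the first principal component over samples (first right singular
#' vector), rescaled to zero mean and unit variance and sign-oriented so
#' that its correlation with the module's mean standardized expression is
#' non-negative. It is the one-dimensional summary that explains the most
#' module variance.
#'
#' @param x genes x samples matrix (or `SummarizedExperiment`) restricted
#'   to one module; >= 2 samples, no zero-variance gene.
#' @return Named numeric vector over samples, mean 0, variance 1.
#' @export
moduleEigengene <- function(x) {
  m <- .exprMatrix(x)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  z <- .standardizeRows(m)
  v <- svd(z, nu = 0L, nv = 1L)$v[, 1L]
  v <- (v - mean(v)) / stats::sd(v)
  ref <- colMeans(z)
  if (stats::cor(v, ref) < 0) v <- -v
  names(v) <- colnames(m)
  v
}

#' Eigengenes of every module in a partition
#'
#' @param x genes x samples matrix or `SummarizedExperiment` covering all
#'   genes of the partition.
#' @param partition A [ModulePartition-class]; unassigned genes are
#'   ignored.
#' @return samples x modules matrix; columns named by module label (or
#'   color once [assignColors()] has run), each zero mean, unit variance.
#' @export
moduleEigengenes <- function(x, partition) {
  m <- .exprMatrix(x)
  lab <- moduleLabels(partition)
  mods <- names(moduleSizes(partition))
  if (!length(mods)) stop("partition contains no modules")
  me <- vapply(mods, function(l) {
    moduleEigengene(m[names(lab)[lab == l], , drop = FALSE])
  }, numeric(ncol(m)))
  cm <- partition@colorMap
  if (length(cm)) colnames(me) <- unname(cm[mods])
  me
}

#' Merge modules with similar eigengenes
#'
#' Computes module eigengenes, then iteratively merges the pair with the
#' highest eigengene correlation while that correlation exceeds
#' `similarity` (the conventional reading of "eigengene similarity",
#' equivalently eigengene dissimilarity below `1 - similarity`),
#' recomputing eigengenes after every merge until no pair exceeds the
#' threshold. Unassigned genes never participate.
#'
#' @param x genes x samples matrix or `SummarizedExperiment`.
#' @param partition A [ModulePartition-class].
#' @param similarity merge threshold in `(0, 1)`, default 0.85.
#' @return list with `partition` (merged, relabelled by size) and
#'   `eigengenes` (samples x modules matrix of the final modules).
#' @export
mergeCloseModules <- function(x, partition, similarity = 0.85) {
  if (similarity <= 0 || similarity >= 1) {
    stop("similarity must lie in (0, 1)")
  }
  m <- .exprMatrix(x)
  labels <- moduleLabels(partition)
  repeat {
    part <- new("ModulePartition", labels = labels, colorMap = character())
    mods <- names(moduleSizes(part))
    if (length(mods) < 2L) break
    me <- moduleEigengenes(m, part)
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[top[1L], top[2L]] <= similarity) break
    pair <- sort(mods[top])
    labels <- .relabel(labels, from = pair[2L], to = pair[1L])
  }
  # relabel by decreasing size for a canonical partition
  sizes <- sort(table(labels[labels != .unassignedLabel]), decreasing = TRUE)
  map <- stats::setNames(as.character(seq_along(sizes)), names(sizes))
  map[.unassignedLabel] <- .unassignedLabel
  labels <- stats::setNames(unname(map[labels]), names(labels))
  part <- new("ModulePartition", labels = labels, colorMap = character())
  list(partition = part, eigengenes = moduleEigengenes(m, part))
}

# conventional size-ranked module color sequence
.moduleColorSequence <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
)

#' Name modules by size-ranked colors
#'
#' Sorts modules by decreasing size (ties broken by the lexicographically
#' smallest member gene id) and names them from the conventional color
#' sequence: turquoise, blue, brown, yellow, green, red, black, pink,
#' magenta, purple, ... Unassigned genes map to grey. Modules beyond the
#' palette get `"module<k>"`.
#'
#' @param partition A [ModulePartition-class] (after merging).
#' @return The partition with its `colorMap` filled.
#' @export
assignColors <- function(partition) {
  lab <- moduleLabels(partition)
  mods <- unique(lab[lab != .unassignedLabel])
  if (length(mods)) {
    size <- vapply(mods, function(l) sum(lab == l), 0L)
    firstGene <- vapply(mods, function(l) min(names(lab)[lab == l]), "")
    ord <- order(-size, firstGene)
    mods <- mods[ord]
    colors <- c(.moduleColorSequence,
                paste0("module", seq_len(max(0L, length(mods) -
                  length(.moduleColorSequence))) +
                  length(.moduleColorSequence)))[seq_along(mods)]
    cm <- stats::setNames(colors, mods)
  } else {
    cm <- character()
  }
  cm[.unassignedLabel] <- "grey"
  methods::initialize(partition, colorMap = cm)
}

#' @describeIn partition-accessors gene -> label vector
#' @export
setMethod("moduleLabels", "ModulePartition", function(object) object@labels)

#' @describeIn partition-accessors decreasing sizes, unassigned excluded
#' @export
setMethod("moduleSizes", "ModulePartition", function(object) {
  lab <- object@labels[object@labels != .unassignedLabel]
  if (!length(lab)) return(stats::setNames(integer(), character()))
  tab <- table(lab)
  sizes <- sort(tab, decreasing = TRUE)
  # stable numeric-label order among equal sizes
  stats::setNames(as.integer(sizes), names(sizes))
})

#' @describeIn partition-accessors gene -> color vector
#' @export
setMethod("moduleColors", "ModulePartition", function(object) {
  if (!length(object@colorMap)) {
    stop("no colors assigned yet; call assignColors() first")
  }
  stats::setNames(unname(object@colorMap[object@labels]),
                  names(object@labels))
})

#' @describeIn adjacency adjacency matrix of a network
#' @export
setMethod("adjacency", "CoexNetwork", function(object) object@adjacency)

#' @describeIn softPower power of a network
#' @export
setMethod("softPower", "CoexNetwork", function(object) object@power)
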