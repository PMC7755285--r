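#' Read a gene x sample expression matrix
#'
#' Reads a delimited text file of non-negative expression values (e.g. FPKM)
#' into a `SummarizedExperiment`. Sample metadata (gestational stage day and
#' replicate) come from a sidecar sample sheet, or are parsed from sample
#' ids of the form `d<stage>_r<rep>` (any two integers in the id work).
#'
#' @param path file path; first column (or row) holds gene ids, header holds
#'   sample ids.
#' @param delimiter field separator; default inferred from the extension
#'   (`","` for `.csv`, tab otherwise).
#' @param genesInRows logical; set `FALSE` for samples-in-rows files, which
#'   are transposed on read.
#' @param sampleSheet optional path or data.frame with columns `sample_id`,
#'   `stage_day`, `replicate`.
#' @return `SummarizedExperiment` with assay `"expr"` and colData columns
#'   `stage_day`, `replicate`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("d45_r1", "d45_r2"))), tf)
#' se <- readExpression(tf)
#' dim(se)
#' @seealso [writeExpression()], [readSampleSheet()]
#' @export
readExpression <- function(path, delimiter = NULL, genesInRows = TRUE,
                           sampleSheet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id in first column: ", dup[1L])
  body <- raw[, -1L, drop = FALSE]
  if (anyDuplicated(colnames(body))) {
    stop("duplicate id in header: ",
         colnames(body)[duplicated(colnames(body))][1L])
  }
  values <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)))
  )
  if (!is.matrix(values)) values <- matrix(values, nrow = nrow(body),
                                           dimnames = list(NULL, colnames(body)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at data row %d, column '%s'",
                 bad[["row"]], colnames(values)[bad[["col"]]]))
  }
  rownames(values) <- ids
  if (!genesInRows) values <- t(values)

  meta <- if (!is.null(sampleSheet)) {
    sheet <- if (is.character(sampleSheet)) readSampleSheet(sampleSheet)
             else sampleSheet
    idx <- match(colnames(values), sheet$sample_id)
    if (anyNA(idx)) {
      stop("sample sheet is missing sample: ",
           colnames(values)[which(is.na(idx))[1L]])
    }
    data.frame(stage_day = as.integer(sheet$stage_day[idx]),
               replicate = as.integer(sheet$replicate[idx]),
               row.names = colnames(values))
  } else {
    .parseSampleIds(colnames(values))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(meta)
  )
}

# stage/replicate from ids like "d45_r1", "45d.2", "S115-3"
.parseSampleIds <- function(ids) {
  nums <- regmatches(ids, gregexpr("[0-9]+", ids))
  stage <- vapply(nums, function(v)
    if (length(v) >= 1L) as.integer(v[1L]) else NA_integer_, 0L)
  repl <- vapply(nums, function(v)
    if (length(v) >= 2L) as.integer(v[length(v)]) else NA_integer_, 0L)
  if (anyNA(stage) || anyNA(repl)) {
    warning("could not parse stage/replicate from some sample ids; ",
            "supply a sample sheet for full metadata")
  }
  data.frame(stage_day = stage, replicate = repl, row.names = ids)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `stage_day`, `replicate`.
#' @return data.frame with those columns.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sheet <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "stage_day", "replicate")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1L])
  }
  sheet
}

#' Write an expression matrix as TSV
#'
#' Genes in rows, first column `gene_id`, full numeric precision so
#' read/write round-trips are value-identical.
#'
#' @param x `SummarizedExperiment` or genes x samples matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  m <- .exprMatrix(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn filterGenes genes x samples numeric matrix
#' @export
setMethod("filterGenes", "matrix", function(x, minValue, minFraction, minMad) {
  if (minValue < 0 || minFraction < 0 || minFraction > 1 || minMad < 0) {
    stop("thresholds must be non-negative (minFraction in [0, 1])")
  }
  okValue <- rowMeans(x >= minValue) >= minFraction
  okMad <- apply(x, 1L, stats::mad) > minMad
  keep <- okValue & okMad
  if (!any(keep)) {
    stop("all genes removed by the filter; relax minValue/minFraction/minMad")
  }
  out <- x[keep, , drop = FALSE]
  attr(out, "filterLog") <- list(kept = sum(keep), dropped = sum(!keep),
                                 minValue = minValue,
                                 minFraction = minFraction, minMad = minMad)
  out
})

#' @describeIn filterGenes `SummarizedExperiment` with genes in rows
#' @export
setMethod("filterGenes", "SummarizedExperiment",
  function(x, minValue, minFraction, minMad) {
    m <- filterGenes(.exprMatrix(x), minValue, minFraction, minMad)
    out <- x[rownames(m), ]
    S4Vectors::metadata(out)$filterLog <- attr(m, "filterLog")
    out
  })

#' @describeIn logTransform numeric matrix
#' @export
setMethod("logTransform", "matrix", function(x) {
  if (any(x < 0)) stop("logTransform requires non-negative values")
  log2(x + 1)
})

#' @describeIn logTransform `SummarizedExperiment` (assay 1 transformed)
#' @export
setMethod("logTransform", "SummarizedExperiment", function(x) {
  SummarizedExperiment::assay(x, 1L) <-
    logTransform(SummarizedExperiment::assay(x, 1L))
  x
})

#' Read gene sets from a GMT file
#'
#' Broad GMT dialect: one term per line, `term_id TAB description TAB gene
#' TAB gene ...`. Duplicate genes within a term are collapsed.
#'
#' @param path GMT file path.
#' @param namespace namespace assigned to every term in the file: `"BP"`,
#'   `"CC"`, `"MF"` or `"pathway"`.
#' @return An [AnnotationSet-class].
#' @export
readGmt <- function(path, namespace = c("pathway", "BP", "CC", "MF")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed GMT line %d: need term, description, >=1 gene",
                 which(nf < 3L)[1L]))
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(genes) == 0L
  if (any(empty)) {
    stop(sprintf("malformed GMT line %d: empty gene list", which(empty)[1L]))
  }
  AnnotationSet(termId = vapply(fields, `[`, "", 1L),
                termName = vapply(fields, `[`, "", 2L),
                namespace = namespace, genes = genes)
}

#' Write an AnnotationSet as GMT
#'
#' @param object An [AnnotationSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(object, path) {
  lines <- vapply(seq_along(object@termId), function(i) {
    paste(c(object@termId[i], object@termName[i], object@genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# combine several AnnotationSets (e.g. GO GMT + pathway GMT)
.bindAnnotations <- function(sets) {
  AnnotationSet(
    termId = unlist(lapply(sets, function(s) s@termId), use.names = FALSE),
    termName = unlist(lapply(sets, function(s) s@termName), use.names = FALSE),
    namespace = unlist(lapply(sets, function(s) s@namespace),
                       use.names = FALSE),
    genes = unlist(lapply(sets, function(s) s@genes), recursive = FALSE,
                   use.names = FALSE)
  )
}

#' Write pipeline result tables
#'
#' Writes the standard result set as TSV: module assignment (gene, module,
#' color; genes lexicographic; unassigned genes labelled `"unassigned"`),
#' eigengene matrix (sample x module, modules by size rank), per-gene
#' connectivity/kME/p table, hub list (header-only when empty) and the
#' enrichment table.
#'
#' @param outDir output directory (created if needed).
#' @param partition [ModulePartition-class].
#' @param eigengenes samples x modules numeric matrix.
#' @param stats [GeneModuleStats-class].
#' @param hubs optional [HubScreenResult-class].
#' @param enrichment optional enrichment data.frame from [hypergeomEnrich()].
#' @return Named character vector of written file paths, invisibly.
#' @export
writeResults <- function(outDir, partition, eigengenes, stats, hubs = NULL,
                         enrichment = NULL) {
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outDir)
  }
  if (file.access(outDir, 2L) != 0L) {
    stop("output directory is not writable: ", outDir)
  }
  paths <- c()
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)

  lab <- moduleLabels(partition)
  lab <- lab[order(names(lab))]
  colors <- if (length(partition@colorMap)) {
    unname(partition@colorMap[lab])
  } else rep(NA_character_, length(lab))
  shown <- ifelse(lab == .unassignedLabel, "unassigned", lab)
  p <- file.path(outDir, "module_assignment.tsv")
  utils::write.table(
    data.frame(gene = names(lab), module = shown, color = colors),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["assignment"] <- p

  sizes <- moduleSizes(partition)
  meCols <- intersect(names(sizes), colnames(eigengenes))
  me <- eigengenes[, c(meCols, setdiff(colnames(eigengenes), meCols)),
                   drop = FALSE]
  p <- file.path(outDir, "module_eigengenes.tsv")
  utils::write.table(
    data.frame(sample = rownames(me), num(as.data.frame(me)),
               check.names = FALSE),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["eigengenes"] <- p

  ord <- order(stats@gene)
  st <- data.frame(gene = stats@gene[ord], module = stats@module[ord],
                   connectivity = num(stats@connectivity[ord]),
                   check.names = FALSE)
  kme <- stats@kme[ord, , drop = FALSE]
  pv <- stats@p[ord, , drop = FALSE]
  colnames(kme) <- paste0("kME_", colnames(kme))
  colnames(pv) <- paste0("p_", colnames(pv))
  st <- cbind(st, num(as.data.frame(kme, check.names = FALSE)),
              num(as.data.frame(pv, check.names = FALSE)))
  p <- file.path(outDir, "gene_module_stats.tsv")
  utils::write.table(st, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["stats"] <- p

  if (!is.null(hubs)) {
    hdf <- data.frame(gene = sort(hubs@hubs), module = rep(hubs@module,
                                                           length(hubs@hubs)))
    p <- file.path(outDir, "hub_genes.tsv")
    utils::write.table(hdf, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["hubs"] <- p
    vdf <- data.frame(set = names(hubs@vennCounts),
                      count = as.integer(hubs@vennCounts))
    p <- file.path(outDir, "hub_venn_counts.tsv")
    utils::write.table(vdf, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["venn"] <- p
  }
  if (!is.null(enrichment)) {
    p <- file.path(outDir, "enrichment.tsv")
    utils::write.table(enrichment, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["enrichment"] <- p
  }
  invisible(paths)
}
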