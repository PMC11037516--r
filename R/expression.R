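## Expression module: probe-level ingest, gene-level aggregation.

#' Read a probe-level expression matrix with sample metadata
#'
#' The matrix TSV has a `probe_id` first column and one numeric column per
#' sample; the metadata TSV has columns `sample_id`, `subject_id`, `day`,
#' `replicate`, one row per sample column. Sample columns and metadata rows
#' are matched by sample id and any orphan on either side is an error naming
#' it. Intensities must be finite, and strictly positive on the linear
#' scale.
#'
#' @param matrixPath path to the intensity TSV.
#' @param metaPath path to the sample metadata TSV.
#' @param scale `"linear"` (default) or `"log2"`. No auto-detection is
#'   attempted; log2 data are linearized later, during aggregation.
#' @return A [SummarizedExperiment::SummarizedExperiment-class] with one
#'   assay `"exprs"` (probes x samples), `colData` columns `subject_id`,
#'   `day`, `replicate`, and the scale recorded in `metadata(se)$scale`.
#' @seealso [aggregateToGene()], [writeExpression()]
#' @export
readExpression <- function(matrixPath, metaPath, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  m <- .read_tsv(matrixPath, "expression matrix file")
  if (colnames(m)[1L] != "probe_id")
    stop("expression matrix must have 'probe_id' as its first column",
         call. = FALSE)
  probes <- as.character(m$probe_id)
  if (anyDuplicated(probes)) stop("duplicated probe ids", call. = FALSE)
  x <- as.matrix(m[, -1L, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric expression values", call. = FALSE)
  rownames(x) <- probes
  meta <- .read_tsv(metaPath, "sample metadata file")
  miss <- setdiff(c("sample_id", "subject_id", "day", "replicate"),
                  colnames(meta))
  if (length(miss))
    stop(sprintf("sample metadata is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  orphan_cols <- setdiff(colnames(x), meta$sample_id)
  orphan_meta <- setdiff(meta$sample_id, colnames(x))
  if (length(orphan_cols))
    stop(sprintf("sample column(s) without metadata: %s",
                 paste(orphan_cols, collapse = ", ")), call. = FALSE)
  if (length(orphan_meta))
    stop(sprintf("metadata row(s) without a sample column: %s",
                 paste(orphan_meta, collapse = ", ")), call. = FALSE)
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  makeExpressionSE(x, meta, scale = scale)
}

#' Assemble an expression SummarizedExperiment from in-memory pieces
#'
#' @param values numeric probe x sample matrix with probe row names and
#'   sample-id column names.
#' @param meta data.frame with columns `sample_id`, `subject_id`, `day`,
#'   `replicate` in the column order of `values`.
#' @param scale `"linear"` or `"log2"`.
#' @return A `SummarizedExperiment`; see [readExpression()].
#' @export
makeExpressionSE <- function(values, meta, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (any(!is.finite(values)))
    stop("expression intensities must be finite", call. = FALSE)
  if (scale == "linear" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive linear intensity at probe '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  if (!is.numeric(meta$day) || any(meta$day != round(meta$day)))
    stop("metadata 'day' must be integer-valued", call. = FALSE)
  if (any(meta$replicate < 1))
    stop("metadata 'replicate' must be a positive integer", call. = FALSE)
  if (anyDuplicated(meta[, c("subject_id", "day", "replicate")]))
    stop("duplicated (subject_id, day, replicate) in sample metadata",
         call. = FALSE)
  cd <- S4Vectors::DataFrame(subject_id = as.character(meta$subject_id),
                             day = as.integer(meta$day),
                             replicate = as.integer(meta$replicate),
                             row.names = as.character(meta$sample_id))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd,
    metadata = list(scale = scale))
}

#' Write an expression SummarizedExperiment to matrix + metadata TSVs
#'
#' Inverse of [readExpression()]: the written files read back value for
#' value.
#'
#' @param se a `SummarizedExperiment` as produced by [readExpression()] or
#'   [simulateExpression()].
#' @param matrixPath,metaPath output file paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
writeExpression <- function(se, matrixPath, metaPath) {
  x <- SummarizedExperiment::assay(se, "exprs")
  out <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- SummarizedExperiment::colData(se)
  meta <- data.frame(sample_id = rownames(cd), subject_id = cd$subject_id,
                     day = cd$day, replicate = cd$replicate,
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = matrixPath, meta = metaPath))
}

#' Read a probe-to-gene map
#'
#' TSV with columns `probe_id`, `gene_symbol`; many probes may map to one
#' gene, each probe to at most one gene. Probes absent from the map are
#' treated as unmapped and dropped during aggregation.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `probe_id`, `gene_symbol`.
#' @export
readProbeGeneMap <- function(path) {
  df <- .read_tsv(path, "probe-gene map file")
  miss <- setdiff(c("probe_id", "gene_symbol"), colnames(df))
  if (length(miss))
    stop(sprintf("probe-gene map is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$probe_id <- as.character(df$probe_id)
  df$gene_symbol <- toupper(as.character(df$gene_symbol))
  if (anyDuplicated(df$probe_id))
    stop("a probe maps to more than one gene", call. = FALSE)
  df[, c("probe_id", "gene_symbol")]
}

#' Aggregate probe-level intensities to gene-by-day means
#'
#' Aggregation proceeds in a fixed order: probes belonging to the same gene
#' are combined within each sample (`probeMethod`: mean or median), then the
#' per-sample gene values are averaged across all replicate samples of the
#' same day. Unmapped probes are dropped with a message stating the count.
#' log2-scale input is linearized (2^x) before any averaging. A gene with no
#' data at a day is `NA`, never zero-filled.
#'
#' @param se probe-level `SummarizedExperiment` from [readExpression()] or
#'   [simulateExpression()].
#' @param map probe-gene map data.frame (see [readProbeGeneMap()]).
#' @param probeMethod how to combine probes within a sample.
#' @return A [GeneExpressionTable-class] (genes x days matrix of mean
#'   intensities).
#' @examples
#' sim <- simulateExpression(defaultPahScenario(seed = 1))
#' tbl <- aggregateToGene(sim$se, sim$map)
#' @export
aggregateToGene <- function(se, map, probeMethod = c("mean", "median")) {
  probeMethod <- match.arg(probeMethod)
  x <- SummarizedExperiment::assay(se, "exprs")
  if (identical(S4Vectors::metadata(se)$scale, "log2")) x <- 2^x
  keep <- map$probe_id %in% rownames(x)
  map <- map[keep, , drop = FALSE]
  mapped <- rownames(x) %in% map$probe_id
  if (!any(mapped))
    stop("no probe of the expression matrix is present in the probe-gene map",
         call. = FALSE)
  if (any(!mapped))
    message(sprintf("dropping %d unmapped probe(s)", sum(!mapped)))
  x <- x[map$probe_id, , drop = FALSE]
  gene <- factor(map$gene_symbol)
  per_sample <- switch(probeMethod,
    mean = rowsum(x, gene) / as.vector(table(gene)),
    median = do.call(rbind, lapply(split(seq_len(nrow(x)), gene), function(ix)
      apply(x[ix, , drop = FALSE], 2L, stats::median))))
  per_sample <- per_sample[levels(gene), , drop = FALSE]
  day <- SummarizedExperiment::colData(se)$day
  days <- sort(unique(day))
  vals <- vapply(days, function(d)
    rowMeans(per_sample[, day == d, drop = FALSE], na.rm = TRUE),
    numeric(nrow(per_sample)))
  vals <- matrix(vals, nrow = nrow(per_sample),
                 dimnames = list(rownames(per_sample), as.character(days)))
  vals[is.nan(vals)] <- NA_real_
  new("GeneExpressionTable", values = vals, days = as.numeric(days),
      probeMethod = probeMethod)
}

#' @rdname accessors
setMethod("exprValues", "GeneExpressionTable", function(x) x@values)
#' @rdname accessors
setMethod("exprDays", "GeneExpressionTable", function(x) x@days)

setMethod("show", "GeneExpressionTable", function(object) {
  cat(sprintf("GeneExpressionTable: %d genes x %d days (%s), probe method '%s'\n",
              nrow(object@values), length(object@days),
              paste(object@days, collapse = ", "), object@probeMethod))
})
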