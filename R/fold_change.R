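## Fold-change module: per-gene fold change from baseline, with two
## reporting conventions.

.signed_from_ratio <- function(r) ifelse(is.na(r) | r >= 1, r, -1 / r)
.ratio_from_signed <- function(s) ifelse(is.na(s) | s >= 1, s, -1 / s)

#' Compute per-gene fold changes from baseline
#'
#' For each gene i and post-baseline day t, `f_{i,t} = x_{i,t} / x_{i,b}`
#' where x is the aggregated gene-level intensity and b the baseline day.
#' Under the `"signed"` convention a ratio r < 1 is reported as `-1/r` (the
#' negated reciprocal common in microarray reporting), so |f| >= 1 always.
#' Gene-days whose baseline is missing are omitted (`NA`), never imputed.
#' Baselines below `epsilon` are floored at `epsilon` with a warning naming
#' the genes.
#'
#' @param tbl a [GeneExpressionTable-class].
#' @param baselineDay day to use as baseline (default 0, the pre-disease
#'   measurement).
#' @param convention `"ratio"` (default; the plain ratio x_t/x_b) or
#'   `"signed"`.
#' @param epsilon positive floor for the baseline denominator; default
#'   `1e-9 * median(intensity)`.
#' @return A [FoldChangeTable-class] over the non-baseline days of `tbl`.
#' @examples
#' sim <- simulateExpression(defaultPahScenario(seed = 1))
#' fc <- computeFoldChange(aggregateToGene(sim$se, sim$map))
#' @export
computeFoldChange <- function(tbl, baselineDay = 0,
                              convention = c("ratio", "signed"),
                              epsilon = NULL) {
  stopifnot(is(tbl, "GeneExpressionTable"))
  convention <- match.arg(convention)
  if (!baselineDay %in% tbl@days)
    stop(sprintf("baseline day %s is not present (days: %s)", baselineDay,
                 paste(tbl@days, collapse = ", ")), call. = FALSE)
  if (is.null(epsilon))
    epsilon <- 1e-9 * stats::median(tbl@values, na.rm = TRUE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number", call. = FALSE)
  b <- as.character(baselineDay)
  xb <- tbl@values[, b]
  low <- !is.na(xb) & xb < epsilon
  if (any(low))
    warning(sprintf("baseline below epsilon floored for gene(s): %s",
                    paste(rownames(tbl@values)[low], collapse = ", ")),
            call. = FALSE)
  days <- setdiff(tbl@days, baselineDay)
  f <- tbl@values[, as.character(days), drop = FALSE] / pmax(xb, epsilon)
  if (convention == "signed") f <- .signed_from_ratio(f)
  new("FoldChangeTable", values = f, days = as.numeric(days),
      baselineDay = as.numeric(baselineDay), convention = convention,
      provenance = sprintf("computeFoldChange(probeMethod=%s, convention=%s, baselineDay=%s)",
                           tbl@probeMethod, convention, baselineDay))
}

#' Convert a fold-change table between conventions
#'
#' The ratio and signed conventions are mutual inverses on their valid
#' ranges, so converting back and forth is exact.
#'
#' @param fc a [FoldChangeTable-class].
#' @param convention target convention.
#' @return A [FoldChangeTable-class] in the requested convention.
#' @export
convertConvention <- function(fc, convention = c("ratio", "signed")) {
  stopifnot(is(fc, "FoldChangeTable"))
  convention <- match.arg(convention)
  if (convention == fc@convention) return(fc)
  v <- if (convention == "signed") .signed_from_ratio(fc@values)
       else .ratio_from_signed(fc@values)
  methods::initialize(fc, values = v, convention = convention,
                      provenance = paste0(fc@provenance, " + convertConvention(",
                                          convention, ")"))
}

#' Build a FoldChangeTable from a plain matrix
#'
#' Convenience constructor for tests, simulations and file input: wraps a
#' genes x days matrix (day column names) into a validated
#' [FoldChangeTable-class].
#'
#' @param values numeric matrix, gene row names, day column names.
#' @param convention fold-change convention of `values`.
#' @param baselineDay baseline day the values refer to.
#' @param provenance free-text provenance note.
#' @return A [FoldChangeTable-class].
#' @export
foldChangeTable <- function(values, convention = c("ratio", "signed"),
                            baselineDay = 0, provenance = "user-supplied") {
  convention <- match.arg(convention)
  days <- as.numeric(colnames(values))
  if (any(is.na(days)))
    stop("column names of 'values' must be the days", call. = FALSE)
  new("FoldChangeTable", values = values, days = days,
      baselineDay = as.numeric(baselineDay), convention = convention,
      provenance = provenance)
}

#' Write / read a fold-change table as TSV
#'
#' TSV with a `gene` first column and one column per day; the convention and
#' baseline day are recorded in `#` header comments and recovered on read.
#'
#' @param fc a [FoldChangeTable-class].
#' @param path file path.
#' @return `writeFoldChange`: `path` invisibly; `readFoldChange`: a
#'   [FoldChangeTable-class].
#' @export
writeFoldChange <- function(fc, path) {
  stopifnot(is(fc, "FoldChangeTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# convention: %s", fc@convention), con)
  writeLines(sprintf("# baseline_day: %s", fc@baselineDay), con)
  out <- data.frame(gene = rownames(fc@values), fc@values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFoldChange
#' @export
readFoldChange <- function(path) {
  if (!file.exists(path)) stop(sprintf("fold-change file not found: %s", path),
                               call. = FALSE)
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  pick <- function(key, default) {
    hit <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(hit)) trimws(sub(sprintf("^# %s:", key), "", hit[1L])) else default
  }
  df <- .read_tsv(path, "fold-change file")
  if (colnames(df)[1L] != "gene")
    stop("fold-change file must have 'gene' as its first column", call. = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df$gene
  foldChangeTable(v, convention = pick("convention", "ratio"),
                  baselineDay = as.numeric(pick("baseline_day", "0")),
                  provenance = sprintf("readFoldChange(%s)", path))
}

#' @rdname accessors
setMethod("fcValues", "FoldChangeTable", function(x) x@values)
#' @rdname accessors
setMethod("fcDays", "FoldChangeTable", function(x) x@days)
#' @rdname accessors
setMethod("fcConvention", "FoldChangeTable", function(x) x@convention)

setMethod("show", "FoldChangeTable", function(object) {
  cat(sprintf("FoldChangeTable: %d genes x %d days (%s), %s convention, baseline day %s\n",
              nrow(object@values), length(object@days),
              paste(object@days, collapse = ", "), object@convention,
              object@baselineDay))
})
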