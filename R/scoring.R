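## Scoring module: the alignment-weighted mean fold-change score S_t and
## per-day drug rankings.

#' Score one drug at one day
#'
#' Computes the modified mean `S_t = (1/n) * sum_i m_i * f_{i,t}`, where the
#' sum runs over exactly the drug's knowledge-base genes with fold-change
#' data available at day t, `m_i` is the +/-1 alignment factor of the
#' drug-gene interaction (see [deriveAlignment()]) and `f_{i,t}` the gene's
#' fold change from baseline. Higher scores indicate larger expression
#' changes that the drug's actions counteract. The unweighted mean avoids
#' biasing the score toward drugs with more extensively studied gene sets.
#'
#' @param kb a [DrugGeneKB-class].
#' @param fc a [FoldChangeTable-class].
#' @param drug drug name present in `kb`.
#' @param day day present in `fc`.
#' @return A [DrugScore-class] carrying the score, n, and per-gene
#'   contributions. If none of the drug's genes has data at that day this is
#'   an error, never a silent zero score.
#' @examples
#' kb <- defaultKnowledgeBase()
#' sim <- simulateExpression(defaultPahScenario(seed = 1))
#' fc <- computeFoldChange(aggregateToGene(sim$se, sim$map))
#' scoreDrug(kb, fc, "Sildenafil", 180)
#' @export
scoreDrug <- function(kb, fc, drug, day) {
  stopifnot(is(kb, "DrugGeneKB"), is(fc, "FoldChangeTable"))
  if (!day %in% fc@days)
    stop(sprintf("day %s is not present in the fold-change table (days: %s)",
                 day, paste(fc@days, collapse = ", ")), call. = FALSE)
  pairs <- interactionsForDrug(kb, drug)
  f <- rep(NA_real_, nrow(pairs))
  hit <- pairs$gene %in% rownames(fc@values)
  f[hit] <- fc@values[pairs$gene[hit], as.character(day)]
  keep <- !is.na(f)
  if (!any(keep))
    stop(sprintf("no fold-change data at day %s for any gene of drug '%s' (n = 0)",
                 day, drug), call. = FALSE)
  cb <- data.frame(gene = pairs$gene[keep], m = pairs$alignment[keep],
                   f = f[keep], stringsAsFactors = FALSE)
  cb$contribution <- cb$m * cb$f
  new("DrugScore", drug = drug, day = as.numeric(day),
      score = mean(cb$contribution), n = nrow(cb), contributions = cb)
}

#' Score a grid of drugs over days
#'
#' Runs [scoreDrug()] for every (drug, day) pair. Cells where a drug has no
#' gene with available data (n = 0) are `NA` with a single collective
#' warning, so one data-poor drug never aborts the rest of the grid.
#'
#' @param kb a [DrugGeneKB-class].
#' @param fc a [FoldChangeTable-class].
#' @param drugs drug names; default all drugs of `kb`.
#' @param days days; default all days of `fc`.
#' @return A [ScoreMatrix-class].
#' @export
scoreMatrix <- function(kb, fc, drugs = kbDrugNames(kb), days = fcDays(fc)) {
  stopifnot(is(kb, "DrugGeneKB"), is(fc, "FoldChangeTable"))
  if (length(drugs) == 0L) stop("empty drug list", call. = FALSE)
  if (length(days) == 0L) stop("empty day list", call. = FALSE)
  unknown <- setdiff(drugs, kbDrugNames(kb))
  if (length(unknown))
    stop(sprintf("unknown drug(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  s <- matrix(NA_real_, length(drugs), length(days),
              dimnames = list(drugs, as.character(days)))
  n <- matrix(0L, length(drugs), length(days), dimnames = dimnames(s))
  for (d in drugs) for (t in days) {
    ds <- tryCatch(scoreDrug(kb, fc, d, t), error = function(e) NULL)
    if (!is.null(ds)) { s[d, as.character(t)] <- ds@score
                        n[d, as.character(t)] <- ds@n }
  }
  if (any(n == 0L))
    warning(sprintf("no data (n = 0) for: %s",
                    paste(apply(which(n == 0L, arr.ind = TRUE), 1L, function(ix)
                      sprintf("%s@day%s", drugs[ix[1L]], days[ix[2L]])),
                      collapse = ", ")), call. = FALSE)
  new("ScoreMatrix", scores = s, n = n, days = as.numeric(days))
}

#' Rank drugs by score at one day
#'
#' @param sm a [ScoreMatrix-class].
#' @param day day present in `sm`.
#' @return data.frame with columns `rank`, `drug`, `score`, sorted by
#'   descending score with alphabetical tie-break. Drugs without a score at
#'   that day are excluded and listed in `attr(, "excluded")`.
#' @examples
#' ref <- referenceScoreMatrix()
#' rankDrugs(ref, 180)
#' @export
rankDrugs <- function(sm, day) {
  stopifnot(is(sm, "ScoreMatrix"))
  if (!day %in% sm@days)
    stop(sprintf("day %s is not present in the score matrix (days: %s)", day,
                 paste(sm@days, collapse = ", ")), call. = FALSE)
  sc <- sm@scores[, as.character(day)]
  scored <- !is.na(sc)
  ord <- order(-sc[scored], names(sc)[scored])
  out <- data.frame(rank = seq_len(sum(scored)),
                    drug = names(sc)[scored][ord],
                    score = unname(sc[scored][ord]),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- names(sc)[!scored]
  out
}

#' Read / write a score matrix as TSV
#'
#' TSV with columns `drug`, `drug_class` and one score column per day.
#' `readScoreMatrix` accepts the same layout (the class column is optional on
#' read and per-cell n is unknown, recorded as `NA`); empty cells are missing
#' scores. This is also the layout of the packaged reference score table,
#' see [referenceScoreMatrix()].
#'
#' @param sm a [ScoreMatrix-class].
#' @param path file path.
#' @param kb optional [DrugGeneKB-class] used to add the `drug_class` column
#'   on write.
#' @param round optional number of decimals for presentation rounding on
#'   write; scores are kept at full precision otherwise.
#' @return `writeScoreMatrix`: `path` invisibly; `readScoreMatrix`: a
#'   [ScoreMatrix-class].
#' @export
writeScoreMatrix <- function(sm, path, kb = NULL, round = NULL) {
  stopifnot(is(sm, "ScoreMatrix"))
  v <- sm@scores
  if (!is.null(round)) v <- base::round(v, round)
  out <- data.frame(drug = rownames(v), stringsAsFactors = FALSE)
  if (!is.null(kb))
    out$drug_class <- kbDrugs(kb)$drug_class[match(out$drug, kbDrugs(kb)$name)]
  out <- cbind(out, as.data.frame(v, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreMatrix
#' @export
readScoreMatrix <- function(path) {
  df <- .read_tsv(path, "score matrix file")
  if (!"drug" %in% colnames(df))
    stop("score matrix file must have a 'drug' column", call. = FALSE)
  daycols <- setdiff(colnames(df), c("drug", "drug_class"))
  days <- suppressWarnings(as.numeric(daycols))
  if (any(is.na(days)))
    stop("score matrix day columns must be numeric day labels", call. = FALSE)
  v <- as.matrix(df[, daycols, drop = FALSE])
  rownames(v) <- df$drug
  n <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  new("ScoreMatrix", scores = v, n = n, days = days)
}

#' The packaged reference score matrix
#'
#' Scores of the six packaged drugs at days 7, 21, 60 and 180 as published
#' for the porcine endoarterial-biopsy PAH time course. The underlying raw
#' expression data are not public, so these printed scores serve as the
#' fixture for ranking and regimen selection.
#'
#' @return A [ScoreMatrix-class] (per-cell n unknown, `NA`).
#' @export
referenceScoreMatrix <- function() {
  readScoreMatrix(system.file("extdata", "reference_scores.tsv",
                              package = "pahscore", mustWork = TRUE))
}

#' @rdname accessors
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("scoreN", "ScoreMatrix", function(x) x@n)
#' @rdname accessors
setMethod("scoreDays", "ScoreMatrix", function(x) x@days)
#' @rdname accessors
setMethod("scoreDrugs", "ScoreMatrix", function(x) rownames(x@scores))

setMethod("show", "DrugScore", function(object) {
  cat(sprintf("DrugScore: %s at day %s: S = %.4f over n = %d gene(s)\n",
              object@drug, object@day, object@score, object@n))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d drugs x %d days\n", nrow(object@scores),
              length(object@days)))
  print(round(object@scores, 2))
})
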