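#' @import methods
NULL

## enumerations shared by validity methods and parsers
.MECHANISMS <- c("inhibitor", "inducer")
.ROLES <- c("pathological", "compensatory")
.DRUG_CLASSES <- c("era", "pde5_inhibitor", "prostacyclin", "other")
.SCALES <- c("linear", "log2")
.CONVENTIONS <- c("ratio", "signed")
.DEFAULT_CLASSES <- c("prostacyclin", "pde5_inhibitor", "era")

.required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  else NULL
}

#' DrugGeneKB: a curated drug-gene interaction knowledge base
#'
#' Holds three relational tables: gene records (symbol, name, pathology role,
#' references), drug records (name, pharmacological class) and drug-gene
#' interactions (mechanism of action, references). The pathology role of a
#' gene states whether its dysregulation in pulmonary arterial hypertension is
#' itself pathological or a compensatory response that alleviates pathology;
#' together with the interaction mechanism it determines the +/-1 alignment
#' factor used in scoring (see [deriveAlignment()]).
#'
#' Validity enforces: unique non-empty gene symbols, unique drug names, the
#' mechanism / role / class enumerations, unique (drug, gene) pairs, and
#' referential integrity of every interaction.
#'
#' @slot genes data.frame with columns `symbol`, `name`, `pathology_role`,
#'   `refs` (semicolon-joined citation tags).
#' @slot drugs data.frame with columns `name`, `drug_class`.
#' @slot interactions data.frame with columns `drug`, `gene`, `mechanism`,
#'   `refs`.
#' @seealso [loadKnowledgeBase()], [defaultKnowledgeBase()],
#'   [interactionsForDrug()]
#' @export
setClass("DrugGeneKB",
  slots = c(genes = "data.frame", drugs = "data.frame",
            interactions = "data.frame"))

setValidity("DrugGeneKB", function(object) {
  g <- object@genes; d <- object@drugs; i <- object@interactions
  msgs <- c(
    .required_cols(g, c("symbol", "name", "pathology_role", "refs"), "genes"),
    .required_cols(d, c("name", "drug_class"), "drugs"),
    .required_cols(i, c("drug", "gene", "mechanism", "refs"), "interactions"))
  if (length(msgs)) return(msgs)
  if (any(!nzchar(g$symbol))) msgs <- c(msgs, "empty gene symbol")
  if (anyDuplicated(g$symbol)) msgs <- c(msgs, "duplicated gene symbols")
  if (anyDuplicated(d$name)) msgs <- c(msgs, "duplicated drug names")
  if (!all(g$pathology_role %in% .ROLES))
    msgs <- c(msgs, sprintf("pathology_role must be one of: %s",
                            paste(.ROLES, collapse = ", ")))
  if (!all(d$drug_class %in% .DRUG_CLASSES))
    msgs <- c(msgs, sprintf("drug_class must be one of: %s",
                            paste(.DRUG_CLASSES, collapse = ", ")))
  if (!all(i$mechanism %in% .MECHANISMS))
    msgs <- c(msgs, sprintf("mechanism must be one of: %s",
                            paste(.MECHANISMS, collapse = ", ")))
  if (anyDuplicated(i[, c("drug", "gene")]))
    msgs <- c(msgs, "duplicated (drug, gene) interaction rows")
  if (!all(i$drug %in% d$name))
    msgs <- c(msgs, sprintf("interactions reference unknown drug(s): %s",
                            paste(unique(setdiff(i$drug, d$name)), collapse = ", ")))
  if (!all(i$gene %in% g$symbol))
    msgs <- c(msgs, sprintf("interactions reference unknown gene(s): %s",
                            paste(unique(setdiff(i$gene, g$symbol)), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' GeneExpressionTable: gene-level mean intensities per study day
#'
#' Result of aggregating a probe-level expression matrix to one mean (or
#' median) intensity per gene and study day: probes belonging to a gene are
#' combined within each sample first, then replicate samples of the same day
#' are averaged. Entries are `NA` when a gene has no data at a day (missing
#' data are never imputed).
#'
#' @slot values numeric matrix, genes x days; column names are the days as
#'   character strings.
#' @slot days numeric vector of study days (column order of `values`).
#' @slot probeMethod how probes were combined within a sample ("mean" or
#'   "median").
#' @seealso [aggregateToGene()], [computeFoldChange()]
#' @export
setClass("GeneExpressionTable",
  slots = c(values = "matrix", days = "numeric", probeMethod = "character"))

setValidity("GeneExpressionTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (ncol(v) != length(object@days)) return("days/values dimension mismatch")
  if (!identical(colnames(v), as.character(object@days)))
    return("column names must equal the days")
  if (any(v <= 0, na.rm = TRUE)) return("aggregated intensities must be positive")
  TRUE
})

#' FoldChangeTable: per-gene fold changes from baseline
#'
#' Fold change of each gene at each post-baseline day relative to its
#' baseline (day 0) expression, `f = x_t / x_b`. Under the `"ratio"`
#' convention values are positive; under the `"signed"` convention a ratio
#' `r < 1` is reported as `-1/r`, so down-regulation appears as a negative
#' fold change of magnitude >= 1. Gene-days without a baseline value are `NA`.
#'
#' @slot values numeric matrix, genes x post-baseline days.
#' @slot days numeric vector of post-baseline days.
#' @slot baselineDay the day used as baseline.
#' @slot convention "ratio" or "signed".
#' @slot provenance free-text record of how the table was produced.
#' @seealso [computeFoldChange()], [convertConvention()]
#' @export
setClass("FoldChangeTable",
  slots = c(values = "matrix", days = "numeric", baselineDay = "numeric",
            convention = "character", provenance = "character"))

setValidity("FoldChangeTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (ncol(v) != length(object@days)) return("days/values dimension mismatch")
  if (!identical(colnames(v), as.character(object@days)))
    return("column names must equal the days")
  if (!object@convention %in% .CONVENTIONS)
    return(sprintf("convention must be one of: %s",
                   paste(.CONVENTIONS, collapse = ", ")))
  if (object@convention == "ratio" && any(v <= 0, na.rm = TRUE))
    return("ratio-convention fold changes must be positive")
  if (object@convention == "signed" &&
      any(abs(v) < 1 & v != 1, na.rm = TRUE))
    return("signed-convention fold changes must satisfy |f| >= 1")
  TRUE
})

#' DrugScore: one drug's alignment-weighted mean fold-change score
#'
#' The score of drug d at day t is `S_t = (1/n) * sum_i m_i * f_{i,t}` over
#' the `n` genes the drug is known to affect for which fold-change data are
#' available at day t; `m_i` is the +/-1 alignment factor of the drug-gene
#' interaction. The per-gene terms are kept in `contributions` for audit.
#'
#' @slot drug drug name.
#' @slot day study day.
#' @slot score the modified mean S_t.
#' @slot n number of genes with available data that entered the mean.
#' @slot contributions data.frame with columns `gene`, `m`, `f`,
#'   `contribution` (= m * f).
#' @seealso [scoreDrug()]
#' @export
setClass("DrugScore",
  slots = c(drug = "character", day = "numeric", score = "numeric",
            n = "integer", contributions = "data.frame"))

setValidity("DrugScore", function(object) {
  cb <- object@contributions
  msg <- .required_cols(cb, c("gene", "m", "f", "contribution"), "contributions")
  if (length(msg)) return(msg)
  if (object@n != nrow(cb)) return("n must equal the number of contributions")
  if (object@n < 1L) return("a DrugScore requires at least one gene (n >= 1)")
  if (!all(abs(cb$m) == 1)) return("alignment factors must be +1 or -1")
  if (max(abs(cb$contribution - cb$m * cb$f)) > 1e-12)
    return("contribution must equal m * f")
  if (abs(object@score - mean(cb$contribution)) > 1e-12)
    return("score must equal the mean contribution")
  TRUE
})

#' ScoreMatrix: drugs x days grid of drug scores
#'
#' Scores for a set of drugs over a set of study days. A cell is `NA` when
#' none of the drug's genes had fold-change data at that day (`n` records how
#' many genes entered each mean; 0 for missing cells).
#'
#' @slot scores numeric matrix, drugs x days (dimnames set).
#' @slot n integer matrix of the per-cell gene counts (same shape); `NA`
#'   when unknown, e.g. for score matrices read from a file.
#' @slot days numeric vector of days (column order).
#' @seealso [scoreMatrix()], [rankDrugs()], [selectRegimen()]
#' @export
setClass("ScoreMatrix",
  slots = c(scores = "matrix", n = "matrix", days = "numeric"))

setValidity("ScoreMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s)) return("scores must be numeric")
  if (!identical(dim(s), dim(object@n))) return("scores/n dimension mismatch")
  if (ncol(s) != length(object@days)) return("days/scores dimension mismatch")
  if (!identical(colnames(s), as.character(object@days)))
    return("column names must equal the days")
  if (is.null(rownames(s))) return("scores must have drug row names")
  if (anyDuplicated(rownames(s))) return("duplicated drug rows")
  TRUE
})

#' SimulationConfig: ground truth for a synthetic expression experiment
#'
#' Defines per-gene fold-change trajectories (day 0 fixed at 1), baseline
#' mean intensities, probe redundancy, replicate samples per day, the
#' standard deviation of multiplicative log-normal noise, the number of
#' decoy (unmapped) probes, and the RNG seed. [simulateExpression()] turns a
#' config into a probe-level dataset with known truth.
#'
#' @slot fold numeric matrix, genes x days, including a baseline column "0"
#'   that is identically 1; ratio convention (all values positive).
#' @slot baselineMean named positive numeric vector of baseline intensities,
#'   one per gene (names match the rows of `fold`).
#' @slot probesPerGene integer >= 1.
#' @slot replicatesPerDay integer >= 1 (two biopsy samples per procedure is
#'   the study default).
#' @slot noiseSigma standard deviation, on the natural-log scale, of the
#'   multiplicative noise; >= 0.
#' @slot decoyProbes number of unmapped probes carrying baseline-only signal.
#' @slot seed RNG seed.
#' @seealso [simulationConfig()], [defaultPahScenario()],
#'   [simulateExpression()]
#' @export
setClass("SimulationConfig",
  slots = c(fold = "matrix", baselineMean = "numeric",
            probesPerGene = "integer", replicatesPerDay = "integer",
            noiseSigma = "numeric", decoyProbes = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  f <- object@fold
  if (!is.numeric(f) || is.null(rownames(f)) || is.null(colnames(f)))
    return("fold must be a numeric matrix with gene row names and day column names")
  if (!"0" %in% colnames(f)) return("fold must contain a baseline column \"0\"")
  if (any(f[, "0"] != 1)) return("baseline fold changes must equal 1")
  if (any(!is.finite(f)) || any(f <= 0))
    return("fold changes must be finite and positive (ratio convention)")
  if (anyDuplicated(rownames(f))) return("duplicated gene names in fold")
  bm <- object@baselineMean
  if (!identical(sort(names(bm)), sort(rownames(f))))
    return("baselineMean names must match the genes of fold")
  if (any(!is.finite(bm)) || any(bm <= 0))
    return("baselineMean must be finite and positive")
  if (object@probesPerGene < 1L) return("probesPerGene must be >= 1")
  if (object@replicatesPerDay < 1L) return("replicatesPerDay must be >= 1")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@decoyProbes < 0L) return("decoyProbes must be >= 0")
  TRUE
})
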