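#' Accessors for pahscore S4 classes
#'
#' Small read-only accessors: `kbGenes()`, `kbDrugs()` and `kbInteractions()`
#' return the three tables of a [DrugGeneKB-class]; `kbDrugNames()` the drug
#' names; `fcValues()`, `fcDays()` and `fcConvention()` the fold-change
#' matrix, its days and its convention; `exprValues()` and `exprDays()` the
#' gene-level intensity matrix and days; `scoreValues()`, `scoreN()`,
#' `scoreDays()` and `scoreDrugs()` the pieces of a [ScoreMatrix-class].
#'
#' @param x the object.
#' @return The corresponding slot content (data.frame, matrix or vector).
#' @name accessors
#' @aliases kbGenes kbDrugs kbInteractions kbDrugNames fcValues fcDays
#'   fcConvention exprValues exprDays scoreValues scoreN scoreDays scoreDrugs
NULL

#' @rdname accessors
#' @export
setGeneric("kbGenes", function(x) standardGeneric("kbGenes"))
#' @rdname accessors
#' @export
setGeneric("kbDrugs", function(x) standardGeneric("kbDrugs"))
#' @rdname accessors
#' @export
setGeneric("kbInteractions", function(x) standardGeneric("kbInteractions"))
#' @rdname accessors
#' @export
setGeneric("kbDrugNames", function(x) standardGeneric("kbDrugNames"))
#' @rdname accessors
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))
#' @rdname accessors
#' @export
setGeneric("fcDays", function(x) standardGeneric("fcDays"))
#' @rdname accessors
#' @export
setGeneric("fcConvention", function(x) standardGeneric("fcConvention"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("exprDays", function(x) standardGeneric("exprDays"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("scoreN", function(x) standardGeneric("scoreN"))
#' @rdname accessors
#' @export
setGeneric("scoreDays", function(x) standardGeneric("scoreDays"))
#' @rdname accessors
#' @export
setGeneric("scoreDrugs", function(x) standardGeneric("scoreDrugs"))
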