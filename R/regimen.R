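## Regimen module: per-class argmax over drug scores -> combination therapy.
## (.DEFAULT_CLASSES lives in AllClasses.R so every file can see it at load.)

#' Select the optimal one-drug-per-class regimen at one day
#'
#' Combination therapy for PAH pairs one agent from each targeted pathway;
#' the optimal regimen at a day takes, independently for each requested
#' pharmacological class, the scored drug of that class with the highest
#' score (alphabetical tie-break). Class membership comes from the knowledge
#' base, never from drug-name matching. A class with no scored drug at that
#' day is an error naming the class.
#'
#' @param sm a [ScoreMatrix-class].
#' @param kb a [DrugGeneKB-class] supplying drug classes.
#' @param day day present in `sm`.
#' @param classes pharmacological classes to fill; defaults to the three
#'   pathway classes (prostacyclin, PDE5 inhibitor, endothelin receptor
#'   antagonist).
#' @return data.frame with one row per class: `day`, `drug_class`, `drug`,
#'   `score`.
#' @examples
#' selectRegimen(referenceScoreMatrix(), defaultKnowledgeBase(), day = 7)
#' @export
selectRegimen <- function(sm, kb, day, classes = .DEFAULT_CLASSES) {
  stopifnot(is(sm, "ScoreMatrix"), is(kb, "DrugGeneKB"))
  if (length(classes) == 0L) stop("empty class list", call. = FALSE)
  if (!day %in% sm@days)
    stop(sprintf("day %s is not present in the score matrix (days: %s)", day,
                 paste(sm@days, collapse = ", ")), call. = FALSE)
  sc <- sm@scores[, as.character(day)]
  drug_class <- kbDrugs(kb)$drug_class[match(names(sc), kbDrugs(kb)$name)]
  slots <- lapply(classes, function(cl) {
    cand <- !is.na(sc) & !is.na(drug_class) & drug_class == cl
    if (!any(cand))
      stop(sprintf("no scored drug of class '%s' at day %s", cl, day),
           call. = FALSE)
    nm <- names(sc)[cand]
    best <- nm[order(-sc[cand], nm)][1L]
    data.frame(day = day, drug_class = cl, drug = best,
               score = unname(sc[best]), stringsAsFactors = FALSE)
  })
  do.call(rbind, slots)
}

#' Optimal regimen at every day
#'
#' Applies [selectRegimen()] to each requested day; an error at any day is
#' re-signalled with the day named.
#'
#' @inheritParams selectRegimen
#' @param days days to cover; default all days of `sm`.
#' @return data.frame with `length(days) * length(classes)` rows (columns as
#'   [selectRegimen()]).
#' @examples
#' regimenTrajectory(referenceScoreMatrix(), defaultKnowledgeBase())
#' @export
regimenTrajectory <- function(sm, kb, days = scoreDays(sm),
                              classes = .DEFAULT_CLASSES) {
  out <- lapply(days, function(d)
    tryCatch(selectRegimen(sm, kb, d, classes), error = function(e)
      stop(sprintf("day %s: %s", d, conditionMessage(e)), call. = FALSE)))
  do.call(rbind, out)
}

#' Write a regimen table as TSV
#'
#' One row per day, one column per class, mirroring the usual triple-therapy
#' presentation.
#'
#' @param regimen data.frame from [regimenTrajectory()] or [selectRegimen()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRegimen <- function(regimen, path) {
  wide <- stats::reshape(regimen[, c("day", "drug_class", "drug")],
                         idvar = "day", timevar = "drug_class",
                         direction = "wide")
  colnames(wide) <- sub("^drug\\.", "", colnames(wide))
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
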