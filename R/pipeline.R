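## Pipeline module: file-in / file-out orchestration of the whole analysis
## (expression -> fold change -> scores -> rankings -> regimen).

.pipeline_defaults <- list(
  kb = NULL, matrix = NULL, meta = NULL, probe_map = NULL,
  scale = "linear", baseline_day = 0, days = NULL, convention = "ratio",
  probe_method = "mean", classes = .DEFAULT_CLASSES, round = NULL,
  out_dir = NULL)

#' Run the full ranking pipeline on files
#'
#' Chains the stages: read probe-level expression + metadata + probe map,
#' aggregate to gene level, compute fold changes from baseline, score every
#' knowledge-base drug at every requested day, rank drugs per day and select
#' the optimal per-class regimen. Writes `fc.tsv`, `scores.tsv`,
#' `rankings.tsv`, `regimen.tsv`, a JSON report (`report.json`: config echo,
#' per-cell gene counts, per-gene contributions, all warnings) and a
#' `run.log`. Outputs are deterministic for fixed inputs and config; only
#' the log carries a timestamp. On any stage error the partially written
#' outputs are removed and the error names the failing stage.
#'
#' @param config named list, or path to a YAML file with the same fields:
#'   `kb`, `matrix`, `meta`, `probe_map` (input paths), `out_dir` (required),
#'   and optionally `scale` ("linear"/"log2"), `baseline_day` (0),
#'   `days` (default: all post-baseline days), `convention`
#'   ("ratio"/"signed"), `probe_method` ("mean"/"median"), `classes`
#'   (regimen classes), `round` (presentation rounding for scores.tsv).
#' @param ... individual fields overriding those in `config`.
#' @return Invisibly, a list with the written `paths`, the [ScoreMatrix-class]
#'   `scores`, the `rankings` and `regimen` data.frames, and the collected
#'   `warnings`.
#' @examples
#' dir <- file.path(tempdir(), "pah-demo")
#' writeSimulation(sim <- simulateExpression(cfg <- defaultPahScenario(1)),
#'                 dir, cfg)
#' res <- runPipeline(list(
#'   kb = system.file("extdata", "pah_kb.tsv", package = "pahscore"),
#'   matrix = file.path(dir, "matrix.tsv"), meta = file.path(dir, "meta.tsv"),
#'   probe_map = file.path(dir, "probe_map.tsv"),
#'   out_dir = file.path(dir, "out")))
#' res$regimen
#' @export
runPipeline <- function(config, ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config <- utils::modifyList(config, list(...))
  unknown <- setdiff(names(config), names(.pipeline_defaults))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- utils::modifyList(.pipeline_defaults, config)
  if (is.null(cfg$out_dir)) stop("config must set 'out_dir'", call. = FALSE)
  for (p in c("kb", "matrix", "meta", "probe_map")) {
    if (is.null(cfg[[p]]))
      stop(sprintf("config must set input path '%s'", p), call. = FALSE)
    if (!file.exists(cfg[[p]]))
      stop(sprintf("input '%s' not found: %s", p, cfg[[p]]), call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(c("fc", "scores", "rankings", "regimen"), function(x)
    file.path(cfg$out_dir, paste0(x, ".tsv")), "")
  paths <- c(paths, report = file.path(cfg$out_dir, "report.json"),
             log = file.path(cfg$out_dir, "run.log"))

  notes <- character()
  stage <- "setup"
  res <- tryCatch(
    withCallingHandlers({
      stage <- "knowledge_base"
      kb <- loadKnowledgeBase(cfg$kb)
      stage <- "expression"
      se <- readExpression(cfg$matrix, cfg$meta, scale = cfg$scale)
      map <- readProbeGeneMap(cfg$probe_map)
      stage <- "aggregation"
      tbl <- aggregateToGene(se, map, probeMethod = cfg$probe_method)
      stage <- "fold_change"
      fc <- computeFoldChange(tbl, baselineDay = cfg$baseline_day,
                              convention = cfg$convention)
      if (!is.null(cfg$days)) {
        days <- as.numeric(cfg$days)
        missing_days <- setdiff(days, fc@days)
        if (length(missing_days))
          stop(sprintf("requested day(s) absent from the data: %s",
                       paste(missing_days, collapse = ", ")), call. = FALSE)
        fc <- methods::initialize(fc, values = fc@values[, as.character(days),
                                                         drop = FALSE],
                                  days = days)
      }
      stage <- "scoring"
      sm <- scoreMatrix(kb, fc)
      rankings <- do.call(rbind, lapply(fc@days, function(d)
        cbind(day = d, rankDrugs(sm, d))))
      stage <- "regimen"
      regimen <- regimenTrajectory(sm, kb, classes = cfg$classes)
      stage <- "report"
      writeFoldChange(fc, paths[["fc"]])
      writeScoreMatrix(sm, paths[["scores"]], kb = kb, round = cfg$round)
      utils::write.table(rankings, paths[["rankings"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeRegimen(regimen, paths[["regimen"]])
      detail <- lapply(scoreDrugs(sm), function(d) lapply(fc@days, function(t) {
        if (is.na(sm@scores[d, as.character(t)])) return(NULL)
        ds <- scoreDrug(kb, fc, d, t)
        list(drug = d, day = t, score = ds@score, n = ds@n,
             contributions = ds@contributions)
      }))
      report <- list(package_version = as.character(utils::packageVersion("pahscore")),
                     config = cfg[!vapply(cfg, is.null, TRUE)],
                     warnings = notes, scores = detail)
      jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      writeLines(c(sprintf("pahscore %s", utils::packageVersion("pahscore")),
                   sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                   "config:",
                   paste0("  ", names(cfg), " = ",
                          vapply(cfg, function(v) paste(format(v), collapse = ","), "")),
                   if (length(notes)) c("warnings:", paste0("  ", notes))
                   else "warnings: none"),
                 paths[["log"]])
      list(paths = paths, scores = sm, rankings = rankings, regimen = regimen,
           warnings = notes)
    },
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    }),
    error = function(e) {
      unlink(paths[file.exists(paths)])
      stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
    })
  invisible(res)
}

#' Plot score trajectories over the time course
#'
#' One line per drug, score versus study day — the usual presentation of how
#' drug preference evolves with disease progression.
#'
#' @param sm a [ScoreMatrix-class].
#' @param main plot title.
#' @return `sm`, invisibly.
#' @export
plotScoreTrajectories <- function(sm, main = "Drug scores over the time course") {
  stopifnot(is(sm, "ScoreMatrix"))
  v <- t(sm@scores)
  graphics::matplot(sm@days, v, type = "b", pch = 19, lty = 1,
                    xlab = "day after disease induction", ylab = "score S_t",
                    main = main, col = seq_len(ncol(v)))
  graphics::legend("topleft", legend = colnames(v), col = seq_len(ncol(v)),
                   lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(sm)
}
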