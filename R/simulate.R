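## Synthetic-data module: probe-level longitudinal expression with known
## ground-truth fold-change trajectories.

#' Build a simulation configuration
#'
#' @param fold numeric genes x days matrix of true fold changes in ratio
#'   convention (gene row names, day column names). A baseline column `"0"`
#'   of ones is prepended if absent.
#' @param baselineMean named positive numeric vector of baseline mean
#'   intensities, one per gene.
#' @param probesPerGene probes measuring each gene (default 3).
#' @param replicatesPerDay samples per day (default 2, the two biopsy
#'   samples taken at each procedure).
#' @param noiseSigma sd of multiplicative log-normal noise on the
#'   natural-log scale (default 0.1, a typical within-array coefficient of
#'   variation of ~10%).
#' @param decoyProbes unmapped probes carrying baseline-only signal
#'   (default 0).
#' @param seed RNG seed.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(fold, baselineMean, probesPerGene = 3L,
                             replicatesPerDay = 2L, noiseSigma = 0.1,
                             decoyProbes = 0L, seed = 1L) {
  if (!"0" %in% colnames(fold))
    fold <- cbind(`0` = rep(1, nrow(fold)), fold)
  days <- as.numeric(colnames(fold))
  if (any(is.na(days)))
    stop("column names of 'fold' must be numeric days", call. = FALSE)
  fold <- fold[, order(days), drop = FALSE]
  new("SimulationConfig", fold = fold,
      baselineMean = baselineMean[rownames(fold)],
      probesPerGene = as.integer(probesPerGene),
      replicatesPerDay = as.integer(replicatesPerDay),
      noiseSigma = as.numeric(noiseSigma),
      decoyProbes = as.integer(decoyProbes), seed = as.integer(seed))
}

#' Simulate a probe-level longitudinal expression experiment
#'
#' Each probe of gene i in a sample taken at day t gets intensity
#' `baselineMean_i * fold_i(t) * exp(e)` with `e ~ N(0, noiseSigma^2)`
#' independent per cell — the standard multiplicative log-normal noise model
#' for microarray intensities. Decoy probes carry baseline-only signal (the
#' median baseline mean, fold 1 at every day) and no probe-map entry, so the
#' aggregation drop-path is exercised. Output is fully reproducible from the
#' seed stored in the config.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `se` (probe-level `SummarizedExperiment`, see
#'   [readExpression()]), `map` (probe-gene map data.frame) and `truth` (the
#'   configured trajectories as a ratio-convention
#'   [FoldChangeTable-class]).
#' @examples
#' sim <- simulateExpression(defaultPahScenario(seed = 42))
#' dim(SummarizedExperiment::assay(sim$se))
#' @export
simulateExpression <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  genes <- rownames(config@fold)
  days <- as.numeric(colnames(config@fold))
  P <- config@probesPerGene; R <- config@replicatesPerDay
  probe_gene <- rep(genes, each = P)
  probes <- paste0(probe_gene, "_p", rep(seq_len(P), length(genes)))
  D <- config@decoyProbes
  if (D > 0L) probes <- c(probes, sprintf("decoy_%03d", seq_len(D)))
  meta <- expand.grid(replicate = seq_len(R), day = days,
                      KEEP.OUT.ATTRS = FALSE)
  meta <- data.frame(sample_id = sprintf("d%03d_r%d", meta$day, meta$replicate),
                     subject_id = "S1", day = meta$day,
                     replicate = meta$replicate, stringsAsFactors = FALSE)
  base <- c(config@baselineMean[probe_gene],
            rep(stats::median(config@baselineMean), D))
  foldrow <- rbind(config@fold[probe_gene, , drop = FALSE],
                   matrix(1, D, length(days)))
  signal <- base * foldrow[, as.character(meta$day), drop = FALSE]
  dimnames(signal) <- list(probes, meta$sample_id)
  set.seed(config@seed)
  if (config@noiseSigma > 0)
    signal <- signal * exp(matrix(
      stats::rnorm(length(signal), 0, config@noiseSigma),
      nrow(signal), ncol(signal)))
  se <- makeExpressionSE(signal, meta, scale = "linear")
  map <- data.frame(probe_id = probes[seq_len(P * length(genes))],
                    gene_symbol = probe_gene, stringsAsFactors = FALSE)
  truth <- foldChangeTable(
    config@fold[, colnames(config@fold) != "0", drop = FALSE],
    convention = "ratio", baselineDay = 0, provenance = "simulation truth")
  list(se = se, map = map, truth = truth)
}

#' Default simulation scenario: progressive PAH over 180 days
#'
#' A documented scenario covering every gene of the packaged knowledge base
#' over days 0, 7, 21, 60 and 180. Genes annotated pathological follow
#' monotone-increasing trajectories `fmax^((t/180)^0.7)` with maximal fold
#' changes cycling through 1.5, 2, 3, 4 and 6 — emulating progressive
#' vascular remodeling. Compensatory genes get mixed fixed trajectories
#' (rise-then-fall for PGIS/NOS3/ID1/PPARD, mild down-regulation for
#' PPARA/PPARG). Baseline means are log-spaced between 50 and 500 intensity
#' units. Probe redundancy 3, two replicate samples per day, log-normal
#' noise sigma 0.1 and 5 decoy probes round out the study-like defaults.
#'
#' @param seed RNG seed stored in the config (only the noise is random; the
#'   trajectories are fixed).
#' @return A [SimulationConfig-class].
#' @export
defaultPahScenario <- function(seed = 1L) {
  kb <- defaultKnowledgeBase()
  genes <- sort(kbGenes(kb)$symbol)
  days <- c(7, 21, 60, 180)
  fold <- matrix(NA_real_, length(genes), length(days),
                 dimnames = list(genes, as.character(days)))
  compensatory <- list(
    PGIS  = c(1.6, 2.2, 2.8, 2.0),
    NOS3  = c(1.4, 1.8, 1.5, 1.1),
    ID1   = c(1.3, 1.7, 2.1, 1.6),
    PPARA = c(0.9, 0.8, 0.7, 0.8),
    PPARD = c(1.2, 1.5, 1.3, 1.0),
    PPARG = c(0.8, 0.7, 0.9, 1.1))
  path_genes <- setdiff(genes, names(compensatory))
  fmax <- rep(c(1.5, 2, 3, 4, 6), length.out = length(path_genes))
  for (k in seq_along(path_genes))
    fold[path_genes[k], ] <- fmax[k]^((days / 180)^0.7)
  for (g in names(compensatory)) fold[g, ] <- compensatory[[g]]
  baselineMean <- stats::setNames(
    exp(seq(log(50), log(500), length.out = length(genes))), genes)
  simulationConfig(fold = fold, baselineMean = baselineMean,
                   probesPerGene = 3L, replicatesPerDay = 2L,
                   noiseSigma = 0.1, decoyProbes = 5L, seed = seed)
}

#' Analytic drug scores implied by a simulation configuration
#'
#' Computes each drug's score directly from the configured true fold-change
#' trajectories and the knowledge-base alignment factors — the closed form
#' that a noise-free simulation must reproduce through the full pipeline.
#'
#' @param config a [SimulationConfig-class].
#' @param kb a [DrugGeneKB-class].
#' @param convention fold-change convention to score in.
#' @return A [ScoreMatrix-class] over the config's non-baseline days.
#' @export
analyticScoreMatrix <- function(config, kb, convention = c("ratio", "signed")) {
  stopifnot(is(config, "SimulationConfig"), is(kb, "DrugGeneKB"))
  convention <- match.arg(convention)
  f <- config@fold[, colnames(config@fold) != "0", drop = FALSE]
  if (convention == "signed") f <- .signed_from_ratio(f)
  days <- as.numeric(colnames(f))
  drugs <- kbDrugNames(kb)
  s <- matrix(NA_real_, length(drugs), length(days),
              dimnames = list(drugs, colnames(f)))
  n <- matrix(0L, length(drugs), length(days), dimnames = dimnames(s))
  for (d in drugs) {
    pairs <- interactionsForDrug(kb, d)
    pairs <- pairs[pairs$gene %in% rownames(f), , drop = FALSE]
    if (nrow(pairs) == 0L) next
    s[d, ] <- colMeans(pairs$alignment * f[pairs$gene, , drop = FALSE])
    n[d, ] <- nrow(pairs)
  }
  new("ScoreMatrix", scores = s, n = n, days = days)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `matrix.tsv`, `meta.tsv`, `probe_map.tsv`, `truth.tsv` and
#' `config.yaml` into a directory, the on-disk form consumed by the
#' file-based pipeline entry points.
#'
#' @param sim list from [simulateExpression()].
#' @param dir output directory (created if needed).
#' @param config the [SimulationConfig-class] used, echoed to `config.yaml`.
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             meta = file.path(dir, "meta.tsv"),
             map = file.path(dir, "probe_map.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  writeExpression(sim$se, paths["matrix"], paths["meta"])
  utils::write.table(sim$map, paths["map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeFoldChange(sim$truth, paths["truth"])
  if (!is.null(config)) {
    cfg <- list(genes = rownames(config@fold),
                days = as.numeric(colnames(config@fold)),
                fold = apply(config@fold, 1L, as.list, simplify = FALSE),
                baseline_mean = as.list(config@baselineMean),
                probes_per_gene = config@probesPerGene,
                replicates_per_day = config@replicatesPerDay,
                noise_sigma = config@noiseSigma,
                decoy_probes = config@decoyProbes,
                seed = config@seed)
    yaml::write_yaml(cfg, paths["config"])
  }
  invisible(paths)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d genes x days {%s}; %d probes/gene, %d replicates/day, sigma = %g, %d decoys, seed = %d\n",
              nrow(object@fold), paste(colnames(object@fold), collapse = ", "),
              object@probesPerGene, object@replicatesPerDay,
              object@noiseSigma, object@decoyProbes, object@seed))
})
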