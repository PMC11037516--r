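Package: pahscore
Title: Expression-Based Ranking of Pulmonary Arterial Hypertension
    Therapies from Endoarterial Biopsy Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks approved pulmonary arterial hypertension (PAH) drugs
    from longitudinal pulmonary vascular gene-expression data. Probe-level
    intensities are aggregated to gene level, fold changes from a
    pre-disease baseline are computed at each follow-up day, and each drug
    receives an alignment-weighted mean fold-change score over the genes it
    is known to affect, using a curated drug-gene interaction knowledge
    base. Per-day rankings and an optimal one-drug-per-class combination
    regimen (prostacyclin, PDE5 inhibitor, endothelin receptor antagonist)
    are derived from the scores. A synthetic-data module simulates
    probe-level longitudinal microarray experiments with known ground-truth
    fold-change trajectories and multiplicative log-normal noise so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
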