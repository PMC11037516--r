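---
title: "Ranking PAH therapies from longitudinal expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking PAH therapies from longitudinal expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahscore)
```

# The model

Pulmonary arterial hypertension (PAH) progresses through vascular
remodeling that dysregulates many genes in the arterial wall. Each approved
PAH drug is known, from the pharmacogenomic literature, to inhibit or induce
a specific set of those genes. `pahscore` quantifies how well a drug's
actions oppose the dysregulation actually observed in a tissue sample at a
given time:

$$S_t = \frac{1}{n}\sum_{i=1}^{n} m_i\,\frac{x_{i,t}}{x_{i,b}}$$

* $x_{i,t}$ — aggregated expression of gene $i$ at day $t$;
* $x_{i,b}$ — its baseline (day 0, pre-disease) expression;
* $m_i \in \{-1, +1\}$ — the *alignment factor* of the drug–gene
  interaction;
* $n$ — the number of the drug's genes for which data are available at day
  $t$ (never the full knowledge-base count; genes without data are omitted,
  not imputed as zero).

The alignment factor is a pure function of two annotations: the drug's
mechanism on the gene (inhibitor/inducer) and the gene's *pathology role*
(pathological/compensatory). Inhibiting a pathological gene or inducing a
compensatory one counteracts disease ($m = +1$); inducing a pathological
gene or inhibiting a compensatory one follows or worsens it ($m = -1$).
Both single-annotation flips negate $m$, which the test suite asserts as a
property.

The score is an unweighted mean by design: a drug whose pharmacology has
been studied against many genes should not outrank a less-studied drug
merely by having more terms in the sum. Consequently $S_t$ is linear in the
fold changes, invariant to gene order, and bounded by the extreme aligned
contributions $m_i f_{i,t}$ — all asserted as properties against a
brute-force loop oracle on randomly generated knowledge bases and
fold-change tables.

Drugs are ranked per day by descending $S_t$ (alphabetical tie-break, so
output is deterministic), and the optimal combination regimen takes the
top-scoring drug *independently within each pharmacological class* —
prostacyclin, PDE5 inhibitor, endothelin receptor antagonist by default.
No drug–drug interaction terms enter the selection; a joint optimization is
deliberately out of scope because no data inform it. Class membership comes
from the knowledge base's `drug_class` column, never from name matching,
and the class list is a parameter so further pathway classes can be added
as drugs targeting them appear.

# The knowledge base and its curation defaults

The packaged knowledge base (`defaultKnowledgeBase()`) contains 65
interactions between six drugs and 34 genes, with mechanisms taken from the
pharmacogenomic literature on each agent. The *pathology roles* deserve
care: the literature rarely states explicitly whether a gene's upregulation
in PAH is itself pathological or a compensatory relief mechanism. The
packaged annotations are therefore curation defaults, not experimental
facts:

* every gene defaults to `pathological`;
* prostaglandin I2 synthase (PGIS) is `compensatory` — its upregulation
  alleviates pathology, so a drug that *inhibits* it is penalized
  ($m = -1$);
* the genes that packaged drugs act on as inducers in a beneficial sense
  (NOS3, ID1, PPARA, PPARD, PPARG) are `compensatory`, so their induction
  scores $+1$.

Two consequences are worth flagging. Sildenafil is annotated as an
*inhibitor* of NOS3; with NOS3 compensatory, that edge scores $-1$. And
MMP9 — inhibited by macitentan but induced by iloprost — is annotated
pathological, so iloprost's MMP9 edge scores $-1$. Users who read the
biology differently can edit the role column of the TSV; roles are ordinary
input, and flipping a role flips the sign of every alignment factor
involving that gene. Whether drugs within a class have identical gene
effects is unknown; the knowledge base treats every drug independently.

Gene identity is a bare symbol string (uppercased), with no orthology
mapping: porcine array data are commonly reported under human-style
symbols, and the knowledge base follows that convention.

# From probes to fold changes

The expression container is a `SummarizedExperiment` (assay `exprs`,
probe × sample; `colData` columns `subject_id`, `day`, `replicate`).
Aggregation to gene level has a fixed, documented order:

1. probes of the same gene are combined **within each sample** (`mean` by
   default; `median` offered for outlier robustness);
2. the per-sample gene values are averaged **across replicate samples of
   the same day**.

The order matters when probe counts are unbalanced across samples, so it is
fixed rather than configurable. Unmapped probes are dropped with a logged
count. Inputs on the log2 scale are linearized ($2^x$) before any
averaging; the scale is an explicit flag, never auto-detected.

Fold change from baseline is $f_{i,t} = x_{i,t} / \max(x_{i,b}, \epsilon)$,
with $\epsilon$ defaulting to $10^{-9}$ times the median intensity — a pure
guard against degenerate near-zero baselines, which are additionally
warned about. Two reporting conventions are supported:

* **ratio** (default): the literal quotient, always positive;
* **signed**: a ratio $r < 1$ is reported as $-1/r$, the negated-reciprocal
  form common in microarray practice, so $|f| \ge 1$ always.

The conventions are exact mutual inverses and both are available throughout
because published score tables in this field do not always state which was
used; the reference score table packaged here contains one small negative
entry whose provenance cannot be settled without the raw data, so the
package commits to neither convention on the user's behalf. Fold change is
scale-invariant (multiplying every intensity by a constant changes
nothing), and missing gene-days are omitted rather than imputed.

# The synthetic study generator

The raw array data behind the reference score table are not public, so the
package ships a first-class simulator instead of a downloaded fixture. A
`SimulationConfig` specifies per-gene true fold-change trajectories (ratio
convention, day 0 ≡ 1), baseline mean intensities, probe redundancy,
replicates per day, noise, decoy probes and a seed. Intensities are
generated as

$$\text{intensity} = \text{baseline}_i \times \text{fold}_i(t) \times e^{\varepsilon},
\qquad \varepsilon \sim N(0, \sigma^2),$$

independently per matrix cell — multiplicative log-normal noise, the
standard intensity-noise model for microarrays. Decoy probes carry
baseline-only signal and no map entry, so the aggregation drop-path is
always exercised.

`defaultPahScenario()` encodes a progressive-disease study over days
0/7/21/60/180: every knowledge-base gene is covered; pathological genes
rise monotonically as $f_{\max}^{(t/180)^{0.7}}$ with $f_{\max}$ cycling
through 1.5–6 (a concave-in-log time course: most change early, continuing
to day 180); compensatory genes get fixed mixed trajectories (rise-then-
fall for PGIS/NOS3/ID1/PPARD, mild down-regulation for PPARA/PPARG).
Baselines are log-spaced over 50–500 intensity units; 3 probes per gene,
2 replicate samples per day (the biopsy protocol's two samples per
procedure), $\sigma = 0.1$ (≈10 % coefficient of variation), 5 decoys.
These values were chosen once as a realistic microarray study of this
design and are not tuned.

What the simulator does *not* emulate: probe-sequence effects, spatial
artifacts, inter-subject variability (one subject), correlated noise
between probes of a gene, and missingness mechanisms other than absent
mapping. Passing tests therefore demonstrate algorithmic correctness on
clean generative data, not robustness to real-array pathology.

## Calibration of the stochastic recovery check

With noise, the aggregated value at each gene-day is a mean of
$k = \text{probes} \times \text{replicates}$ log-normal terms, in both the
numerator and the baseline denominator of the fold change. Writing $M$ for
such a mean, $E[M] = e^{\sigma^2/2}$ and
$\mathrm{CV}^2(M) = (e^{\sigma^2} - 1)/k$; the $e^{\sigma^2/2}$ factors
cancel between numerator and baseline, and a second-order delta expansion
of $E[1/M_b]$ leaves

$$E[\hat f] \approx f \times \Bigl(1 + \frac{e^{\sigma^2} - 1}{k}\Bigr).$$

Because the score is linear in the fold changes, the same factor applies to
$E[\hat S_t]$. The test suite and the acceptance script assert, over 200
independently seeded simulated studies, that every drug–day mean score sits
within three standard errors of the analytic score times this centering
(about 1.0017 at the default $\sigma = 0.1$, $k = 6$). Using the naive
single-measurement correction $e^{\sigma^2/2}$ would systematically
overshoot, since it ignores that the baseline is estimated from noisy data
too.

# Numerical and interface choices

* **Determinism.** All randomness flows from explicit seeds; identical
  configs reproduce bit-identical simulated data and byte-identical
  pipeline reports (a timestamp appears only in the run log). Ranking and
  regimen ties break alphabetically.
* **Missing data.** $n = 0$ for a drug–day is an explicit error in
  `scoreDrug()` and a warned `NA` cell in `scoreMatrix()` — never a silent
  zero, which would masquerade as a genuinely neutral score.
* **Precision.** Scores are kept at full double precision; rounding (e.g.
  to the 2 decimals of published tables) is a presentation-layer option of
  `writeScoreMatrix()` only.
* **Validation problem sizes.** The property suites run the scorer against
  a brute-force oracle on 1000+ random instances (≤10 drugs, ≤20 genes),
  noise-free recovery on the full 6 × 4 grid at tolerance $10^{-12}$, and
  the stochastic recovery above on 200 replicates — sizes chosen to give
  the statistical assertions comfortable power while the whole suite runs
  in well under a minute.

# Worked pipeline

```{r example, eval = FALSE}
kb  <- defaultKnowledgeBase()
cfg <- defaultPahScenario(seed = 7)
sim <- simulateExpression(cfg)
fc  <- computeFoldChange(aggregateToGene(sim$se, sim$map))
sm  <- scoreMatrix(kb, fc)
rankDrugs(sm, 180)
regimenTrajectory(sm, kb)
```

File-based use goes through `runPipeline()` (or the `pahscore` script in
`inst/scripts/`), which writes `fc.tsv`, `scores.tsv`, `rankings.tsv`,
`regimen.tsv`, a JSON report carrying per-gene contributions and every
warning that affected $n$, and a run log.

# Limitations

The method ranks drugs by a mean of aligned fold changes; it attaches no
uncertainty to a score (no replicate-based variance model is defined), no
dosing, no drug–drug interactions, and no claim of clinical efficacy — the
selected regimen is the argmax of a score, validated here against the
published score-to-regimen logic and against synthetic ground truth, not
against outcomes. The knowledge base inherits the biases of the
pharmacogenomic literature it curates, and prostacyclin-receptor genes are
absent from it entirely (no array data existed for them), which likely
depresses prostacyclin-class scores. Cross-species calibration of scores is
out of scope.
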