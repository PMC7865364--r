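---
title: "Immunoscore scoring and outcome analysis: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunoscore scoring and outcome analysis: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(imscore)
```

## The problem

In localized muscle-invasive bladder cancer (MIBC) treated with neoadjuvant
platinum-based chemotherapy before cystectomy, five-year overall survival is
roughly 50% and there is no validated tissue biomarker for predicting either
the pathologic complete response (pCR) or long-term outcome. The Immunoscore
quantifies the adaptive immune contexture of the tumor: CD3+ and CD8+
T-lymphocyte densities (cells/mm²) are measured in two regions of the
pre-treatment specimen — the tumor center (CT) and the invasive margin (IM) —
and summarized into an ordinal score. This package implements that scoring
system and the outcome analyses it feeds, together with a synthetic cohort
generator, so that the whole pipeline is reproducible and testable without
patient data.

## The scoring model

Each of the four densities (CD3-CT, CD8-CT, CD3-IM, CD8-IM) is converted to a
percentile of the analysis cohort's own distribution using the midrank
convention

$$p(x) = 100\,\frac{\#\{r < x\} + \tfrac12\,\#\{r = x\}}{n},$$

which is symmetric, stable under ties, and rank-invariant. The mean of the
available percentiles (four when the IM is present, the two CT percentiles
otherwise) is retained as a continuous covariate.

Categories are defined by counts of per-density "high" calls at fitted
thresholds, with *high* meaning density ≥ threshold (the closed convention
makes tie handling deterministic):

* **IS-0 … IS-4** — number of high calls among all four densities; defined
  only when the invasive margin is present (IS-0 = both populations low in
  both regions, IS-4 = both elevated in both).
* **ISb-0 / ISb-1 / ISb-2** — the biopsy-adapted score using only the CT
  pair: both low, one high, both high. Always defined, which matters because
  a substantial fraction of trans-urethral resections have no identifiable
  invasive margin.
* Collapsed groups used by the outcome analyses: {IS-0, IS-1–2, IS-3–4},
  {IS-0–2, IS-3–4}, {ISb-0, ISb-1–2}.

Two descriptions of the score circulate — a mean-percentile translation and
the per-density low/high counting rule. Only the counting rule is fully
specified (the low/high wording defines IS-0 and IS-4 verbatim), so
categories are implemented as counts of high calls and the mean percentile is
kept as a separate continuous summary. One consequence worth stating: under
shared CT thresholds, ISb ≥ 1 whenever IS ≥ 3, because at most two of the
four high calls can come from the margin.

### Cut-off determination

The "optimal cut-off" is implemented as a maximally selected log-rank search
on time to recurrence: for each marker × region, every observed unique
density between the 10th and 90th percentile is tried as a threshold, and the
one maximizing the absolute standardized two-group log-rank statistic
$z = (O_1 - E_1)/\sqrt{V_1}$ is selected; ties are broken toward the
threshold nearest the median. The `[q10, q90]` restriction avoids unstable
extreme splits. The maximal statistic is *not* reported as a test — its null
distribution is inflated by the selection — and the fitted model (thresholds,
grid, statistic trace) serializes to JSON so that scoring is reproducible
without refitting. Whether the original assay dichotomized raw densities or
percentiles, per marker × region or on the mean percentile, is not stated
anywhere we could rely on; both scales are supported (`fixed_cutoffs(...,
scale = "percentile")`) and the default is raw densities per marker × region.

## Association with pathologic response

Score groupings are related to pCR with exact conditional tests: the 2×2
Fisher test by hypergeometric enumeration, and the Freeman–Halton R×C
generalization by depth-first enumeration of all margin-fixed tables scored
with the multivariate hypergeometric probability. The two-sided p-value is
the sum of probabilities not exceeding the observed one, with a relative
tolerance of 1e-7 — the convention of mainstream statistical software, which
is what makes published 4-decimal p-values bit-reproducible from printed
counts. Enumeration is guarded (`max_tables`); past the guard the seeded
Monte-Carlo fallback uses Patefield's algorithm (`r2dtable`) and reports its
standard error. Patients missing either variable are dropped per test
(complete case), which is why an IS×pCR table can have a smaller total than
an ISb×pCR table on the same cohort. No multiple-testing correction is
applied anywhere; raw p-values are reported. Density contrasts between
clinical categories use the two-sample t-test, pooled-variance by default
(the classical reading of "Student's t-test"), with Welch available.

## Survival machinery

* **Kaplan–Meier** (via the `survival` package): Greenwood variance, log-log
  transformed CIs, Brookmeyer–Crowley median CI with "not reached" emitted as
  `NA` when the curve never crosses the bound, and rates at 36/60-month
  horizons by step lookup.
* **Cox models** are stratified by recruiting center (each center keeps its
  own baseline hazard) with Efron tie handling — the ecosystem default and
  more accurate than Breslow; the source analyses were run in the same
  ecosystem. "Unknown" is an explicit factor level, never an exclusion. A
  separated level is reported with its 0/Inf hazard-ratio sentinel rather
  than an error; a covariate constant across patients is flagged degenerate
  (HR 1, p 1). Harrell's C is taken from the fit's concordance.
* **Relative importance** of each covariate is its joint Wald χ² (all levels
  at once, using the corresponding block of the variance matrix) divided by
  the sum over covariates; shares are in [0, 1] and sum to 1.
* **RMST**: the restricted mean survival time is the exact step integral of
  the KM curve to a horizon τ, with the standard large-sample variance
  $\sum_j A_j^2 d_j / (n_j (n_j - d_j))$; the two-sample comparison uses a
  normal approximation for the difference. τ defaults to the smaller of the
  two arms' largest observed times so both curves are defined on the whole
  window. The reference implementations of both the RMST comparison and the
  χ²-share decomposition are not available in this build environment, so both
  are implemented from their standard formulas and cross-checked in the test
  suite against closed forms and independent numerical integration of the
  fitted survival curve.
* **Time to recurrence** censors at death without recurrence; the competing
  risk is deliberately ignored to mirror the dual TTR/OS reporting of the
  source design. This is a documented limitation, not an oversight: cumulative
  incidence under competing risks is out of scope.
* **Schoenfeld sizing**: required events
  $d = (z_{\alpha} + z_{\beta})^2 / (p(1-p)(\ln \mathrm{HR})^2)$, inflated to
  a total by the expected event fraction. The published design range
  "103–152 patients" (HR 1.85–2.1, power 90%, 60% events, balanced groups)
  reproduces only under a **one-sided** alpha of 5% (giving 104–151), despite
  the design text calling its alpha two-tailed (which gives 128–186). The
  function exposes `sided` and the discrepancy is surfaced, not silently
  resolved — `analysis/05_multivariable.R` prints both.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` states a world chosen once from the published cohort
description and held fixed:

* n = 117 patients over five centers with the published center mix; gender
  77.8% male; age ~ N(66.4, 8.2²); tobacco, professional exposure, prior
  BCG, histologic variant, T and N stages and regimen drawn at the published
  Table-1 frequencies, with "Unknown" generated by completely-at-random
  masking at those same frequencies (no missingness mechanism is published).
* A latent per-patient immune level A ~ N(0,1) loads on all four log-normal
  densities (pairwise log-scale correlation 0.6), giving the right-skewed,
  cross-correlated density distributions such assays show.
* pCR is logistic in (mean percentile)/100 with slope 2.0 and an intercept
  set so the marginal pCR rate is ≈ 30–35% (the published rate among
  evaluable patients); pCR is masked with probability 16/117.
* Recurrence is exponential with hazard
  `0.035 · exp(−0.35 · IS + log 2.5 · [N+])` per month, where IS is the
  generator's own count of densities above their configured medians — the
  analysis never sees this latent truth and must re-derive scores from the
  data. Overall survival is recurrence time plus an exponential
  post-recurrence survival (hazard 0.04/month) competing with a small
  background death hazard (0.006/month); this guarantees TTR ≤ OS and
  correlated endpoints. The joint law of recurrence and death is otherwise
  unspecified in the source; this construction is the package's choice.
* Follow-up is uniform on [6, 96] months, emulating staggered accrual with an
  administrative horizon; this reproduces a median follow-up in the 2–3 year
  range without extra machinery.
* Invasive margins are missing with probability 14/117. The source is
  internally inconsistent here (21 specimens without margins in the methods
  text vs 14 unclassified patients in the response table footnote); the
  generator exposes the fraction rather than resolving the conflict. A
  second printed inconsistency — N+ 65.8% in the cohort-description table vs
  8/39 in the bivariable table — is resolved in favor of the cohort table,
  and a third (pCR yes 35 in the cohort table vs a margin of 34 in the
  response table) in favor of the response table for the packaged fixture.

What the generator does **not** emulate: spatial clustering of cells beyond
homogeneous Poisson (the slide generator is a plain Poisson point process on
rectangular masks), informative missingness, center × effect interactions,
inter-observer variability, and any image-level realism. A green test on
synthetic data therefore establishes that the statistical machinery is
correct under the stated world, not that the biological effect sizes are
right.

### The published-counts fixture

`table2_fixture_cohort()` encodes the published response-by-score table
patient-by-patient: densities are 50/150 against a uniform threshold of 100,
so re-scoring the fixture regenerates exactly the printed ISb×pCR (n = 100)
and IS×pCR (n = 90) cross-tabs, 14 margin-missing patients, and 17 with
unknown response. Its follow-up columns are schema-valid placeholders; no
survival quantity of the source is patient-level reproducible, so none is
encoded.

## Numerical choices and degenerate inputs

* Percentiles: midrank; a value below every reference value maps to 0 and a
  value equal to the minimum maps to 50/n.
* High calls: `>=` at the threshold.
* Cut-off search: grid = observed unique densities in [q10, q90]; identical
  densities error ("degenerate density distribution"); an all-censored
  outcome errors; at least 20 events are required by default.
* Exact tests: zero margins error for the 2×2 test; the R×C test tolerates
  them (the cells are forced in every attainable table — a single nonzero
  column yields p = 1, the only attainable table). Probabilities are
  accumulated in log space.
* t-test: two constant groups give p = 1 (equal means) or a flagged p = 0.
* Reports round p-values to 4 decimals and rates to 1 (print precision of
  the source tables); the JSON report keeps full precision.

## Simulation scaling in the test suite

Simulation-based checks state their design up front and were not tuned to
outcomes. The cut-point recovery check draws densities on a 25 cells/mm²
lattice (density readouts are effectively binned; on a continuous support
"within one grid step" of the candidate grid would be vacuously strict) with
a hazard ratio of 3 across the changepoint, matching the strong-effect regime
of the log-rank power checks. The null-coverage check uses 100 replicates of
n = 400 (Wald-CI coverage is asymptotically free of n; larger cohorts only
cost time), while point recovery uses a single n = 1500 cohort. The
permutation-null and power checks in the routine suite run scaled-down seed
counts of the same designs to stay inside the test-time budget.

## Known limitations

* Competing risks are ignored for TTR (death without recurrence censors).
* The maximally selected threshold is reused for inference downstream without
  selection correction, as in the source design; downstream p-values are
  therefore optimistic for the score variables.
* The percentile reference is the analysis cohort itself; an external
  reference must be supplied through `fixed_cutoffs()` / a serialized
  `cutoff_model`.
* Proportional hazards are assumed for all Cox fits; the RMST comparison is
  the provided PH-free alternative, and no further diagnostics are run.
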