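---
title: "Subtyping Parkinson's disease: model, generator and design notes"
author: "pdsubtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtyping Parkinson's disease: model, generator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pdsubtype` packages a standardized k-means subtyping analysis for de
novo Parkinson's disease baseline data and everything around it:
normalization with persisted parameters, cluster-number selection,
semantic subtype labelling, nearest-centroid classification of new
patients, effect-size-based group characterization, and longitudinal
progression comparison. This vignette records the model, its
assumptions, and the design decisions taken where the procedure was
genuinely open.

## The clustering model

The analytic unit is a patient row of 22 baseline variables: age of
symptom onset, five motor scores (MDS-UPDRS Part III total and its
tremor, rigidity, bradykinesia and axial subscores) and sixteen
non-motor scores (UPSIT, MoCA, GDS, STAI, hallucination, apathy,
fatigue, pain, RBD, SCOPA-AUT total and six SCOPA domains). Two of these
scales are *reversed*: higher MoCA and UPSIT mean better function.

Rows with any missing clustering value are dropped — never imputed —
because downstream centroids and rescaling parameters must be estimable
without distributional assumptions about missingness. Each variable is
min-max normalized with extremes fitted on the analytic cohort. Min-max
(rather than z-scoring) keeps every feature in a comparable unit
interval while preserving the shape of bounded ordinal scales; its cost
is sensitivity to extreme observations, which is accepted as part of the
standardized procedure. The fitted extremes persist inside the model
object because classification of future patients must reuse the
*training* ranges; new values are deliberately not clipped to [0, 1], as
clipping would distort centroid distances.

Lloyd k-means is run in the normalized space with squared Euclidean
distance. Tunable parameters, with defaults:

| parameter    | default | meaning                                        |
|--------------|---------|------------------------------------------------|
| `k_range`    | 2–10    | candidate subtype counts scored by pseudo-F    |
| `n_restarts` | 100     | random initializations per k (local-optimum guard) |
| `max_iter`   | 100     | Lloyd iteration cap per restart                |
| `tol`        | 1e-6    | centroid-movement stop, normalized units       |
| `init_method`| forgy   | k distinct data rows; `"kmeans++"` available   |

The number of subtypes maximizes the Calinski–Harabasz pseudo-F
`[B/(k-1)] / [W/(n-k)]`; ties go to the smaller k (parsimony). The
default initialization is Forgy sampling of k distinct data rows because
the procedure being standardized specifies only "random initialization";
k-means++ is provided as an option but neither is asserted to be the
original environment's default.

Numerical policies, all deterministic: point-to-centroid ties resolve to
the lowest centroid index; a cluster emptied during assignment is
re-seeded at the data point farthest from its centroid (points that are
sole members of their cluster are exempt, so k is preserved); the WSS is
non-increasing across iterations and the final state satisfies both
Lloyd fixed-point conditions. Restart sub-seeds are spawned
deterministically from one master seed, so a fit is a pure function of
`(data, parameters, seed)`.

## Composite severity scores and subtype labels

Two composites place each patient in a severity plane: the motor
composite is the mean of the five normalized motor scores, and the
non-motor composite the mean of the sixteen normalized non-motor scores
after replacing MoCA and UPSIT by `1 - z`. Higher always means more
severe, and fit-cohort values live in [0, 1]. Age belongs to neither
composite: it is a risk marker, not a symptom. The UPDRS-III total is
kept in the motor set alongside its four subscores — the composite is
defined over "all" motor features and the total carries items the four
subscores miss; an analyst who dislikes the implied double-weighting can
pass a schema whose motor category lists only the subscores.

Fitted clusters are ordered by the sum of their centroid composites,
mildest first; for k = 2 the labels are MMNS and SMNS (mild/severe
motor–non-motor subtype). An exact severity tie falls back to cluster
size (descending), then lexicographic centroid order, and is logged.

A note on the variable list: the SCOPA orofacial domain appears in some
instrument descriptions but not in the 22-variable accounting used here;
the packaged schema follows the 22-variable set, and an orofacial column
can be added through a custom schema if a cohort carries it.

## The synthetic cohort generator

The real cohort sits behind a gated registry, so the package ships a
generator whose defaults encode the published summary structure: two
subtypes of 270 (MMNS) and 138 (SMNS) patients; per-variable Gaussian
profiles with the published means/SDs for the 22 clinical, 28 SPECT
imaging and 10 CSF variables; a sex column with per-subtype male
fractions (177/270, 92/138) that is never clustered; per-category MCAR
missingness (0 clinical, 0.003 imaging, 0.05 CSF — reproducing the
imaging N = 269/270 and CSF N = 246–266 patterns in expectation); and a
longitudinal model with 17 follow-up dropouts.

Assumptions worth stating plainly:

* **Independence within subtype.** Only means and SDs are published, so
  variables are drawn independently within subtype. Real clinical scores
  are correlated (UPDRS-III with its own subscores above all); the
  generator therefore *understates* the within-subtype structure and the
  mixture is somewhat easier to separate on some axes, harder on others,
  than real data. No correlation hook is exposed — there is nothing
  published to calibrate one against.
* **Clamp-and-round.** Draws are clamped to the clinical scale and
  rounded when the scale is integer-valued. Clamping after sampling
  slightly biases realized moments of variables whose mean sits within
  about one SD of a bound (hallucination, apathy, GDS floor effects;
  MoCA ceiling), so moment-recovery checks are scoped to variables away
  from their bounds.
* **Longitudinal model.** Per patient and measure a latent trajectory is
  built: baseline draw, plus an early (Y1−Y0) and a secondary (Y3−Y1)
  increment draw with the published interval moments; Y2, which is
  plotted but never used in rates, interpolates the latent Y1→Y3 segment
  plus noise with SD scaled by √(1/2). Observed scores are the latent
  values clamped to the scale — a measurement floor/ceiling — so latent
  increments keep their configured moments while recorded H&Y stays in
  [0, 5] and MoCA in [0, 30]. Near the MoCA ceiling observed changes are
  attenuated relative to the configured increments; this is inherent to
  imposing a bounded scale on Gaussian increments. Long-term change is
  by construction the sum of the two interval increments; the published
  long-term cells differ slightly from that sum because each printed
  cell summarizes a different completing subsample.
* **Baseline H&Y.** No per-subtype baseline H&Y summary is published;
  the generator uses MMNS 1.5 (SD 0.5) and SMNS 1.7 (SD 0.5) — typical
  early-stage staging, with the severe subtype worse so the time-plot
  ordering is stable across visits, as reported.
* **Dropout.** Exactly 17 patients, chosen uniformly at random, keep
  only their baseline visit — an exact-count design matching the
  published accounting (408 baseline → 391 longitudinal), not a
  per-patient hazard.

What passing tests on this generator shows: that the pipeline recovers a
two-cluster structure of the published effect-size geometry, and that
every statistic is computed correctly. What it does not show: robustness
to correlated features, non-Gaussian score distributions, informative
missingness, or medication-start effects — none of which the generator
emulates.

## Comparison statistics

Hedges' g uses the pooled SD; the small-sample correction
`J = 1 - 3/(4(n1+n2) - 9)` is applied by default (the named estimator
includes it) with a flag to disable, and both paths are tested.
Confidence intervals are percentile bootstrap with 3,000 within-group
resamples (groups resampled independently); BCa is out of scope.
Wilcoxon rank-sum p-values are exact by enumeration for pooled sizes up
to 16 without ties, otherwise a tie-corrected normal approximation with
continuity correction. Family-wise control is Bonferroni at level 0.05
over the actual family size — 0.05/22 ≈ 0.00227 clinical, 0.05/28 ≈
0.00179 imaging, 0.05/10 = 0.005 CSF — held at full precision
internally; printed thresholds elsewhere are rounded displays, and a
printed imaging threshold of 0.0017 would imply ~29 comparisons, so the
package always derives the threshold from the member count rather than
hard-coding it. Imaging and CSF families use pairwise-complete
observations per variable, never imputation, which is why per-variable n
varies.

## Longitudinal analysis

Patients with a baseline record but no follow-up score on either measure
are removed (any single follow-up value keeps a patient). Progression
rates are plain differences — early Y1−Y0, secondary Y3−Y1, long-term
Y3−Y0 — and the long-term rate is computed as the sum of the two
interval rates whenever both exist, so additivity is exact in floating
point. Y2 contributes to visit-wise summaries and the ANCOVA but never
to the rates.

The ANCOVA pools all (patient, visit) observations per measure and fits
`score ~ subtype + visit + age_at_onset` — main effects only, visit
categorical, age at onset as the continuous covariate. Factors are
tested with partial (Type II) F statistics from nested residual sums of
squares, which are order-invariant in the absence of interactions. This
pooled main-effects form is the minimal reading of "the effect of
subtypes and visits adjusted for age"; a per-patient random-intercept
model would respect the repeated measures but is a different estimand
and is deliberately out of scope. Degenerate inputs are handled
explicitly: a numerically zero full-model RSS with zero incremental RSS
yields F = 0, and a rank-deficient design errors naming the collinear
term.

## Problem sizes used in the test suite

The suite regenerates everything from seeds: exhaustive-partition
k-means oracles at n ≤ 10, pseudo-F oracles on random fixtures,
full-enumeration rank-sum checks for pooled sizes ≤ 12, a 500-replicate
bootstrap coverage study at n = 200 per group, 500 null ANCOVA
simulations at 30 patients × 4 visits, and a 100-seed cluster-recovery
study on the full 408-patient default cohort. These sizes were chosen so
each study pins its statistic's behaviour (coverage, type-I rate,
selection frequency) with binomial error a few percent wide.

## Known limitations

* The generator's independence assumption means reported pseudo-F values
  on synthetic cohorts are not comparable in magnitude to values from
  real correlated data; only the *selected k* and the qualitative
  subtype geometry are.
* Min-max scaling ties the model to the training cohort's observed
  extremes; a future cohort with wider ranges changes normalized
  geometry. This is intrinsic to the standardized procedure, which is
  why the scaling parameters ship inside the model file.
* The pooled ANCOVA treats repeated visits as independent observations;
  its F statistics are descriptive of the pooled contrast, not of a
  subject-level longitudinal model.
* Deep-brain-stimulation timing, medication start after baseline, and
  genetics are outside the data model entirely.
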