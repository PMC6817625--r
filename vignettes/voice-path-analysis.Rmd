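---
title: "Methods: vocal parameters, rating reliability, and path-model inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocal parameters, rating reliability, and path-model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxpath)
```

voxpath implements a complete analysis chain for paired speech/singing
voice studies: deterministic acoustic transforms, rating-panel
aggregation, and a small-sample-robust path-analysis workflow. This
vignette documents the models, the tunable parameters, the synthetic-data
generator that the tests rely on, and the numerical and design choices
made where the methodology left room.

## 1. Acoustic transforms

**Semitone scale.** F0 values in Hz are expressed as perceptual pitch
relative to concert A4: `st = 12·log2(F0/440)`. The scale is logarithmic
(12 semitones per frequency doubling) and the reference is configurable
(`reference_hz`). Note labels round to the nearest integer semitone;
exact halves round *away from zero*, and only naturals and sharps are
used (A4, A#4, B4, C5, ...), with the octave incrementing at C.

**Pitch range.** Per recording, `12·log2(F0_max/F0_min)`; invariant under
transposition (multiplying both bounds by a common factor), which is the
point of a log-ratio measure.

**Formant spacing and apparent VTL.** For a uniform tube closed at one
end the resonances sit at odd quarter-wavelengths, `F_i = (2i−1)/2·ΔF`.
ΔF is estimated as the through-origin least-squares slope of the four
measured formant medians on `x_i = (2i−1)/2`, i.e. in closed form
`ΔF = Σ x_i F_i / Σ x_i²`. Apparent vocal tract length is
`VTL = c/(2ΔF)`. The speed of sound defaults to `c = 33,500 cm/s`
(335 m/s, warm humid air in the vocal tract); the printed source value
uses a European thousands separator ("33.500 cm/s") and is interpreted
accordingly. Both `c` and the averaging order are configurable.

**Averaging order.** Per-recording mean F0 is converted to semitones
*first* and the semitone values are then averaged across recordings (the
stated processing order); ranges are averaged likewise. For VTL the
source is silent on the order, so the package averages per-recording ΔF
and converts once (`vtl_from = "mean_delta_f"`). Because `c/(2ΔF)` is
convex in ΔF, averaging per-recording VTLs instead
(`vtl_from = "mean_vtl"`) gives a slightly larger value (Jensen's
inequality); both orders are exposed, and the difference is a fraction of
a millimetre at realistic within-person ΔF jitter.

## 2. Ratings

Rater-by-target matrices of 1–7 integer scores are summarized per target
by the arithmetic mean across raters, pooled over rater countries (the
default, after verifying cross-country agreement); per-country
aggregation is retained as an option. Interrater agreement is Cronbach's
α with raters as items and targets as observations,
`α = k/(k−1)·(1 − Σ var_i / var_total)`, computed per block (display ×
rater set); sub-blocks of raters who judged different target sets are
detected automatically. Cross-sample agreement between two panels' target
means is a Pearson correlation with a Fisher-z interval,
`tanh(atanh(r) ± z·(n−3)^{−1/2})`; the CI method is not named in the
source, but Fisher-z reproduces the asymmetry of the printed intervals.

## 3. The path model

### Specification

The default model has 11 observed variables in four layers:

| layer | variables | equations |
|---|---|---|
| exogenous | age, height, weight, body-shape ratio (WSR men / WHR women) | 6 free covariances |
| mediators | speech/singing mean F0 *or* VTL, speech/singing F0 range | each on all 4 exogenous (16 edges) |
| outcomes | speech and singing attractiveness | each on 4 mediators + 4 exogenous (16 edges) |
| final | sociosexuality total | on 4 mediators + 2 attractiveness (6 edges) |

That is 38 regressions + 6 covariances. Residual covariances among
mediators and among outcomes are fixed at zero; this is the unique
reconstruction consistent with the published parameter count and with the
invariance test's 44 degrees of freedom. Whether the sociosexuality total
was also regressed on the exogenous block is not decidable from the
published material; the 38-edge reconstruction excludes it (including it
would give 42 edges, contradicting the printed count). The edge
allocation is overridable via `path_spec()` or a YAML model file.

### Estimation

All variables are z-scored within the analysis sample, each equation is
estimated by OLS, and exogenous covariances are the sample correlations.
For a recursive system with uncorrelated residuals, equation-wise OLS *is*
the maximum-likelihood estimator, so the model-level fit statistic is the
standard normal-theory discrepancy
`F_ML = log|Σ(θ)| + tr(S·Σ(θ)^{−1}) − log|S| − p` with
`χ² = (n−1)·F_ML`, where `Σ(θ) = (I−A)^{−1} S_0 (I−A)^{−T}` is the
RAM-form implied covariance. Complete-case analysis is used per fit and
the analysis n is logged (sample sizes legitimately differ across
analyses). The default single-group model has df = 11.

### Permutation p-values

With as few as ~1.7 observations per parameter, normal-theory p-values
are not trusted; instead the full model is refitted on B randomized
datasets (default B = 10,000) and the two-sided p-value for each
parameter is `(1 + #{|θ*_b| ≥ |θ̂|})/(B+1)`, so the smallest attainable
value is 1/(B+1). "Randomized" is operationalized as *independent
permutation of every variable's column*: this destroys all dependencies
while preserving every marginal exactly, the weakest assumption
consistent with a randomization null. A `"joint"` scheme (one shared
permutation of the endogenous block against the exogenous block) is
exposed as an alternative; column-wise is the default. Replicate refit
failures are counted and more than 1% aborts the run.

### Jackknife stability

A parameter is *stable* iff its p-value is below α (default 0.05) in the
full sample **and** in every leave-one-out refit. Inside the loop the
analytic OLS/correlation p-values are used by default: running B
permutations inside each of n subsamples is supported
(`p_method = "permutation"`) but costs n·B refits and changes little, and
which p-value fed the original criterion is not stated. Any refit
failure marks the parameter unstable rather than silently passing.

### Invariance

The two-group test compares the configural model (identical structure,
all 44 parameters free per group) with the path-invariant model (all 44
constrained equal; exogenous and residual variances stay free per group).
The configural fit is closed-form (per-group OLS, exact ML), so the
constrained optimum can never undercut it and `χ²_diff ≥ 0` holds by
construction. The constrained fit minimizes `Σ_g (n_g−1)·F_ML,g` by BFGS
over the 44 shared parameters plus per-group log-variances, started at
the across-group average of the per-group estimates (with the shared
covariances shrunk toward zero if that start is infeasible), converging
at relative change `1e-10`. Following the standardized-reporting
convention, groups are z-scored separately for the configural fit and on
the pooled sample for the constrained fit; `F_ML` is scale-invariant for
this model family, so the choice does not affect the statistic. The
difference is referred to χ² with df = 44.

## 4. Generic statistics

Pearson correlations carry t-based p-values and Fisher-z intervals.
Kendall correlations use **tau-b** — ties are pervasive on 7- and
10-point scales, and the variant is not named in the source — computed
from the cross-tabulation concordance counts with the standard tie
corrections, and a normal-approximation p with the tie-corrected variance
of S. Paired comparisons are one-sample t-tests on the differences. The
sex × country GLM uses Type-III sums of squares on a sum-to-zero
encoding with the interaction included by default (the published term set
is unstated; error df are consistent with the factorial model), partial
η² = SS_effect/(SS_effect+SS_error), and estimated marginal means that
average cells equally. No multiple-comparison correction is applied,
matching the original analysis policy.

## 5. The synthetic cohort generator

No raw data were deposited with the study the calibration emulates, so
the generator *is* the test bed. Its defaults are the stated world:

* **Group means/SDs** of mean F0, F0 range (semitones) and VTL (cm) per
  sex × country are the published summary-table values; ages are the
  published group means/SDs; group sizes are the published recruitment
  counts (40/33 men and 44/35 women for BR/CZ).
* **Cross-display correlations** (speech–singing F0 0.800/0.607, range
  0.408/0.160, VTL 0.808/0.764, attractiveness 0.720/0.674 for men/women)
  are embedded in a per-sex correlation matrix.
* **Unpublished quantities** are fixed once at realistic values: body
  height/weight and ratios for university students of the two countries
  (Czechs taller and heavier), sociosexuality totals on the 9–81 scale
  (Brazilians higher, consistent with the study's own framing), and
  correlations the source reports only qualitatively — height–weight 0.5,
  weight/height–VTL 0.3, within-person F0–VTL −0.5 (a free calibration
  choice, flagged as such), F0–VTL across displays −0.4. If a
  configuration makes the matrix indefinite it is repaired by eigenvalue
  clipping at 1e−6 and rescaling to unit diagonal, and the repair is
  reported; the default matrix is positive definite without repair
  (minimum eigenvalue ≈ 0.096).
* **Attractiveness and sociosexuality** are generated from standardized
  structural equations (low-pitched speech, heavier and younger men more
  attractive; high-pitched women more attractive; sociosexuality linked
  to lower speech F0 / higher singing F0 in men and to speech/singing VTL
  with opposite signs in women — the directions of the reported stable
  paths, magnitudes 0.15–0.30), plus correlated normal residuals solved
  in closed form so the *total* attractiveness correlation hits its
  target.
* **Ratings** are `clip(round(true + rater_effect + noise))`; the noise
  SD is solved numerically (common random numbers, so the objective is
  deterministic and monotone) to hit the per-block α target of 0.79 —
  rounding and clipping are inside the solved system. Because the
  printed attractiveness correlation is a correlation of *mean ratings*,
  the generator plants a latent correlation inflated by the pooled-panel
  reliability (Spearman–Brown step-up of the per-rater reliability
  implied by the block α; ≈ 0.88 for the default panels), so aggregated
  panel means reproduce the printed value in expectation. Panel sizes
  are the published rater counts (59+47 women rating men, 51+46 men
  rating women).
* **Recordings** are back-synthesized from each person's profile: two per
  display, with per-recording pitch jitter (SD 0.5 st), range jitter
  (SD 1 st), VTL jitter (SD 0.15 cm) and 1% formant measurement noise
  around the exact uniform-tube positions.

All randomness flows from one master seed through named substreams; the
same seed reproduces the same study byte-for-byte.

**What a green test does and does not establish.** The generator draws
from multivariate normals with the published moments; real cohorts have
skewed weights and SOI totals, country mixtures inside rating panels,
rater in/out-group effects, and measurement error with structure (Praat
octave jumps, formant mistracking) that the jitter model does not
emulate. Green calibration tests therefore certify that the *pipeline*
recovers what was planted at the published sample sizes — not that the
published effect sizes are correct. Pooling the two countries also
re-introduces small mixture correlations through the group-mean
differences (visible as ≈ +0.01–0.08 on otherwise-zero cross-display
correlations); this is a property of the stated two-country world, not a
bug, and it is why the calibration tests compare against the targets at
tolerance ±0.03.

## 6. Numerical choices and degenerate inputs

* Non-positive or non-finite frequencies, non-increasing formants, and
  out-of-scale scores are rejected with row-level messages; zero total
  variance makes α (and correlations on constant input) *undefined*, and
  the package signals that explicitly rather than returning NaN.
* Note rounding: half-semitones away from zero (documented above).
* Permutation p-values use the add-one correction; they can never be 0.
* The invariance optimizer treats non-PD implied or structural matrices
  as an infinite-discrepancy region (value 1e10) rather than crashing;
  convergence failure is reported with optimizer diagnostics, and the CLI
  maps it to exit code 3 (validation errors exit 2).
* CSVs are UTF-8 (BOM tolerated), comma-separated, dot-decimal, with
  numbers written at 12 significant digits; write-then-read round-trips
  are lossless at that precision.

## 7. Known limitations

* Latent-variable measurement models, fit indices beyond χ² (CFI/RMSEA),
  and mediation decompositions are out of scope.
* The jackknife defaults to analytic p-values inside the loop (see above).
* The multivariate GLM reports univariate between-subjects effects only.
* The generator's α-noise solver assumes the expected α depends on the
  true scores only through their location and spread (it bins both for
  caching); this is exact for normal scores and a good approximation
  otherwise.
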