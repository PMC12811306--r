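---
title: "Measuring the unhealthy = tasty intuition from cursor trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the unhealthy = tasty intuition from cursor trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Many people hold the lay belief that healthiness and tastiness of food are
opposed — the "unhealthy = tasty" intuition (UTI). Self-report scales
measure the explicit, reasoned form of this belief well, but they cannot
capture how the belief intrudes on a decision as it unfolds, and they are
poorly suited to detecting momentary, contextually induced activation of
the association.

`utitrack` analyzes a two-choice mouse-tracking classification task built
for exactly that purpose. On each trial a food image appears once the
participant starts moving the cursor from a start button at the bottom
center of the screen; the participant classifies the food as *tasty*
(upper-left response box) or *not tasty* (upper-right box) while the
cursor is sampled every 10 ms. If a participant's UTI is engaged when a
healthy food must be affirmed as tasty, the competing "not tasty"
response attracts the cursor: movements become slower and more curved.
Aggregated into healthy-minus-unhealthy difference scores, these motor
signatures form a process-based behavioral index of the belief.

## From raw samples to trial metrics

The pipeline consumes three delimited-text tables (cursor samples, trial
design, participant questionnaire) and proceeds in fixed stages:

1. **Coordinate remap** (`remap_coordinates()`). Each trial is anchored by
   its *observed* geometry: the point where the cursor left the start
   button maps to (0, 0), the clicked pixel maps to (−1, 1) for a left
   response and (1, 1) for a right response, each axis scaled
   independently. Because screen y grows downward and the boxes sit above
   the start, the map also flips y so "up" is positive. The map is
   invariant to rigid translation of the raw samples, so trials recorded
   on different screens are directly comparable.
2. **Mirroring** (`mirror_to_right()`). Left responses are reflected so
   every trajectory ends at (1, 1); mirrored unit-frame paths can be
   averaged across response sides (`average_trajectory()`).
3. **Spatial normalization** (`resample_spatial()`). The path is
   re-parameterized by cumulative arc length and linearly interpolated at
   101 equidistant points (0–100% of the movement distance). This removes
   duration from the shape description.
4. **Temporal normalization** (`resample_temporal()`). x and y are
   interpolated on a uniform 101-point time grid; this is the input
   convention for sample entropy, which requires uniform sampling.

Three trial-level metrics are computed (`compute_trial_metrics()`):

* **Reaction time**: last timestamp minus first (tracking starts at
  movement onset, so the first retained sample is at 0 ms).
* **Signed maximum absolute deviation (MAD)** (`mad_signed()`): the
  largest perpendicular point-to-*line* distance of the 101 spatially
  normalized points from the straight line connecting the first and last
  points. The sign is positive when the extreme point lies on the side of
  that line toward the non-chosen response box — the direction of
  attraction by the competing response. MAD is reported in screen pixels
  (computed on the pixel-frame path before remapping) because that is the
  scale on which task geometry is interpretable; a unit-frame value is
  returned alongside. Point-to-line rather than point-to-segment distance
  is used deliberately: the reference is the ideal straight trajectory,
  not a clipped segment.
* **Sample entropy** (`sample_entropy()`): SampEn(m, r) = −ln(A/B), where
  B counts pairs of length-m templates within Chebyshev tolerance r and A
  the same at length m+1, self-matches excluded and both template sets
  sharing the same n−m starting indices. We compute it on the x
  coordinate of the time-normalized path (lateral motion carries the
  conflict signal) with m = 2 and r = 0.2 SD of the series, the standard
  parameterization; both are configurable. Setting r proportional to the
  series SD makes the statistic invariant to affine transformation of the
  series. Degenerate cases (zero variance, or no matches at either
  template length) return 0 with a `degenerate` attribute rather than an
  infinity, so perfectly regular series sort below irregular ones.

Trials whose geometry cannot be anchored (zero horizontal or vertical
extent) or whose path has zero length are flagged `degenerate`, receive
`NA` metrics, and are excluded from aggregation — flagged, never silently
dropped, so counts remain auditable.

## Participant-level indices

`exclude_outliers()` implements the preregistration-style rule: the mean
and SD of each metric are computed **once** over all non-degenerate trials
of the whole sample (grand pooling, no per-participant recentering and no
iteration), and trials outside mean ± 3 SD are flagged. Reaction times
are excluded two-sided (both unusually slow and unusually fast responses
are suspect); the signed MAD is excluded upper-tail only (only
implausibly extreme excursions toward the competitor). Both tails and the
multiplier are configurable. Grand pooling is the documented default
because sample-wide exclusion percentages are the quantity usually
reported; flagged rows stay in the table.

`difference_scores()` averages each retained metric within healthy and
unhealthy trials per participant and takes healthy − unhealthy: positive
ΔRT means slower responses to healthy foods, positive ΔMAD more curved
ones. A participant with an empty cell after exclusion keeps an `NA`
delta and a warning rather than a fabricated value.

The explicit UTI score is the mean of the three 7-point items
(`score_uti_scale()`), with `cronbach_alpha()` for internal consistency.
The diet quality score (`score_dqs()`) summarizes a 20-item food
frequency questionnaire into five components (vegetables, fruit, sugary
foods, processed meat, whole grains/fish), each scored 1–3 from the mean
item frequency against two cutpoints, summing to 5–15 (higher =
healthier). The component-to-item map and cutpoints ship as a
serializable configuration (`dqs_default_config()`), because FFQ
instruments and scoring guidelines vary; the default cutpoints (3 and 5
on the 1–8 frequency scale) divide the response range into thirds.
`median_split()` (ties to "low", documented and deterministic) exists for
descriptive breakdowns only; all confirmatory statistics use the
continuous score.

## Inferential conventions

* `pearson_r()`, `welch_t()`, `cohens_d_ci()` wrap the standard
  product-moment correlation, the unequal-variance t test with
  Satterthwaite degrees of freedom (the default two-group contrast), and
  the pooled-SD standardized mean difference with the large-sample normal
  CI (`SE = sqrt((n_a+n_b)/(n_a n_b) + d²/(2(n_a+n_b)))`); a
  noncentral-t interval is out of scope.
* `fit_lmm()` fits, by REML via `lme4`, the trial-level model
  `metric ~ food_type * classification * uti_z + age + gender + education
  + (1 | participant) + (1 | stimulus)`, with crossed random intercepts
  for participants and stimuli and no random slopes. `uti_z` is the
  explicit score standardized over the analysis sample, so slopes read
  "per 1 SD of explicit UTI". Reference levels are `healthy` and `tasty`;
  gender and education are indicator-coded with the most frequent level
  as reference. Coefficient p-values use the normal approximation
  z = estimate/SE — documented, configurable by post-processing, and the
  reason the key `food_typeunhealthy:uti_z` term is read as a z test.
  Convergence is reported honestly; a boundary (singular) fit — a
  variance component estimated at zero — counts as converged.
* `simple_slopes()` evaluates the UTI slope inside each food-type ×
  classification cell as a linear combination L′β of the fixed effects,
  with SE from the coefficient covariance, and contrasts the
  healthy-vs-unhealthy slope within each classification — the check that
  distinguishes genuine healthy-specific conflict from a mere surplus of
  generally-slower "not tasty" responses.
* `fit_glmm_choice()` is the logistic counterpart for the classification
  itself (tasty = 1), with condition × food type as the term of interest.
  A single-level outcome returns a flagged degenerate fit; separation
  symptoms (non-finite SEs, runaway logits) clear the convergence flag.
* `incremental_validity()` compares nested OLS models for DQS (covariates
  + explicit score, with and without a behavioral index) by the F-change
  on 1 numerator df; a collinear added predictor yields a `singular` flag
  and no invented statistics.
* `power_n_for_r()` is the Fisher-z closed form
  `n = ceil(((z_{1−α/tails} + z_{power}) / atanh(|r|))² + 3)`.

## The synthetic cohort generator

No deposited raw data ship with the package, so every stage is validated
against `simulate_cohort()`, which emits the exact three-table format
with known ground truth. The default configuration reproduces the
reference task: 10 healthy + 10 unhealthy stimuli shown twice (40
trials), 1920×1080 screen, start button at (960, 980), response boxes at
(160, 80) and (1760, 80), 100-Hz sampling.

Each agent draws a latent behavioral trait u ~ N(0,1). A hedonic goal
condition shifts the *active* trait, u\* = u + Δcond — state activation
on top of a stable disposition, which is why the manipulation moves
behavior without moving the stored trait. Choices follow
P(tasty) = logistic(α₀ + α₁·[unhealthy] − α₂·max(u\*,0)·[healthy]):
stronger UTI suppresses tasty judgments of healthy foods specifically.
Trial conflict is softplus(κ₀ + κ₁·u\*·[healthy ∧ tasty] + κ₂·[not
tasty]): the trait's cost concentrates where a healthy item is affirmed
as tasty, and "not tasty" responses carry a general conflict bump.

Trajectories integrate a closed-loop controller in 10-ms steps: the
cursor heads toward the clicked pixel at the speed needed to arrive on
schedule (total duration = base + γ·conflict, times lognormal noise),
while a lateral pull toward the competing box — proportional to conflict
and decaying linearly over the first half of the movement — and isotropic
Gaussian positional noise perturb it. The controller admits a closed-form
solution for the whole step sequence, so generation is fast and exactly
reproducible under a seed; a capture radius around the click point
terminates the movement and the final sample is the click pixel itself.

**Why the explicit scale has its own factor.** Scale items load on an
explicit belief factor e = ρ·u + √(1−ρ²)·ν rather than on u directly.
A three-item scale with good reliability (α > .8) necessarily tracks its
own latent factor almost perfectly; if that factor *were* u, the
explicit score would correlate near-unity with any low-noise behavioral
index of u, which is not how explicit and implicit measures relate
empirically — validated implicit tasks typically correlate ~.3 with their
explicit counterparts while remaining sensitive to experimental
manipulations of the underlying association. The divergence parameter
(default ρ = 0.55) reproduces exactly that regime: a reliable scale,
moderate explicit–behavioral validity correlations, and a goal
manipulation that is detectable at two-digit arm sizes.

Diet quality targets 10 − 0.8·u plus noise, clipped to 5–15; FFQ item
responses are then constructed by inverting the default DQS scoring
configuration (component levels chosen to sum to the target, item
frequencies placed centrally within each level's band), so
`score_dqs()` recovers the target exactly — a documented generator
convenience that makes diet quality a downstream consequence of the
behavioral trait, not of the explicit belief.

Default effect and noise magnitudes (κ = 0.5/0.55/1.5, α = 1.1/0.5/1.0,
motor base 800 ms, γ = 110 ms per conflict unit, pull 2.6 px/step,
positional noise 7 px, duration noise 0.13 log-SD) were chosen once so
that the synthetic study conditions resemble the published regime this
task operates in: mean reaction times near 900 ms, MAD values of tens of
pixels, ~1% outlier exclusions, tasty rates around 66%/83% for
healthy/unhealthy items, explicit-scale α ≈ .85, validity correlations
near .3, and a hedonic-goal contrast of d ≈ .3 at 100 participants per
arm. They are conventions of this artifact, not estimates from any
dataset.

**What the generator does not emulate:** real cursor dynamics
(sub-movement structure, pauses, velocity asymmetries, device and
browser jitter), item-level stimulus effects beyond a random intercept,
response errors and lapses, questionnaire styles (acquiescence,
social desirability), or dropout. Passing recovery tests therefore shows
that the pipeline measures what the generative model encodes — not that
the generative model is a faithful model of human movement.

## Numerical choices and edge cases

* Resampling interpolates linearly; zero-length segments are collapsed
  before interpolation and endpoints are set exactly.
* The MAD sign reference is the non-chosen box: in the unit frame the
  mirrored competitor sits at (−1, 1); in the pixel frame the click is
  reflected about the start column. A collinear reference (degenerate
  chord) falls back to positive orientation.
* Exclusion bounds collapse to the mean when the SD is 0, excluding
  nothing.
* `fit_lmm()` special-cases a constant outcome (the exact solution:
  intercept at the constant, all slopes and variance components 0)
  instead of pushing a zero-variance problem into the optimizer.
* All simulator randomness flows from one seeded stream, sequentially per
  agent; the same seed reproduces all tables bit-identically.

## Validation suite and problem sizes

The test suite validates each metric against an independent oracle
(projection-based perpendicular distances, arc-position recovery on the
source polyline, O(n²) template counting for SampEn, textbook formula
evaluations for r/t/d/α/ΔF to 1e-10), and the whole pipeline against the
generator's ground truth: validity-correlation recovery over 20 cohorts
of n = 200; type-I error of the trait × food-type interaction over 200
null cohorts of n = 40 with 20 trials each (a scale at which the z-test
calibration of the mixed model can be checked in minutes); and the goal
manipulation over 20 experiments with 100 participants per arm. These
sizes were chosen as the smallest at which the binomial bands asserted by
the tests are stable. `scripts/acceptance.R` re-runs the same quantities
from scratch at a caller-supplied seed.

## Limitations

The package analyzes one task family (two response boxes at the top
corners, dynamic start at the bottom); it does not parse proprietary
experiment-builder exports, does not smooth or filter cursor jitter, and
deliberately computes only the three metrics above — no area under the
curve, x-flips, velocity decomposition, or entropy variants. Mixed-model
p-values use the normal approximation, which is mildly anticonservative
for small participant counts; for confirmatory use at small n, prefer the
participant-level difference-score tests.
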