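# utitrack

Analysis toolkit for a mouse-tracking food classification task that
yields a process-based behavioral index of the **unhealthy = tasty
intuition (UTI)** — the lay belief that healthiness and tastiness of food
are opposed.

In the task, a participant starts each trial by moving the cursor from a
button at the bottom center of the screen; a food image appears, and the
participant classifies it as *tasty* (upper-left box) or *not tasty*
(upper-right box) while the cursor is sampled at 100 Hz. When someone
who holds the UTI must affirm a healthy food as tasty, the competing
response attracts the cursor: responses get slower and the path bends
toward the non-chosen box. `utitrack` turns raw cursor logs into those
conflict measures and the statistics used to validate them.

## What it computes

**Trial level.** For each trial with samples $(t_i, x_i, y_i)$:

- **RT** — time from movement onset to the click (ms);
- **signed MAD** — after spatial normalization of the path to 101
  equidistant points along its arc length, the maximum perpendicular
  deviation from the straight line between the first and last points,

  $$\mathrm{MAD} = \pm \max_i \; d_\perp(p_i,\; \overline{p_1 p_{101}}),$$

  signed positive when the extreme point lies toward the non-chosen
  response box (the conflict direction), reported in px;
- **sample entropy** — $\mathrm{SampEn}(m, r) = -\ln(A/B)$ with template
  length $m = 2$ and tolerance $r = 0.2\,\mathrm{SD}$, computed on the x
  coordinate of the time-normalized path; a regularity measure of the
  movement.

**Participant level.** After the preregistration-style 3-SD outlier rule
(grand-pooled; two-sided for RT, upper-tail for MAD), healthy-minus-
unhealthy difference scores ΔRT and ΔMAD (positive = costlier processing
of healthy foods), the 3-item explicit UTI scale mean, Cronbach's α, and
a 5–15 diet quality score (DQS) from a 20-item food frequency
questionnaire.

**Inference.** Pearson validity correlations; Welch t and Cohen's d with
CI for condition contrasts; trial-level linear mixed models
`metric ~ food_type * classification * uti_z + covariates` with crossed
random intercepts for participant and stimulus (lme4); simple-slope
contrasts of UTI within food-type × classification cells; nested-model
F-change for incremental validity of the behavioral indices over the
explicit scale; and the Fisher-z power analysis
`n = ⌈((z_{1-α/tails}+z_{power})/\mathrm{atanh}|r|)^2 + 3⌉`.

**Simulation.** `simulate_cohort()` generates synthetic cohorts — latent
UTI traits, choices, full cursor trajectories, scale and FFQ responses —
in the exact three-table input format with ground truth attached, so the
entire pipeline is testable without collected data.

## Worked example

```r
library(utitrack)

cohort <- simulate_cohort(sim_config(n_participants = 200, seed = 42))
result <- analyze_dataset(cohort$samples, cohort$trials, cohort$participants)
print(result)
#> UTI classification-task analysis
#>   trials: 8000 (200 participants)
#>   exclusions:
#>     rt_ms: 40/8000 trials (0.5%) outside [537.3, 1357.8]
#>     mad_px: 2/8000 trials (0.0%) outside [-Inf, 229.6]
#>   validity correlations:
#>     uti_delta_rt: r = 0.320 (p = 3.829e-06, n = 200)
#>     uti_delta_mad: r = 0.394 (p = 7.837e-09, n = 200)
#>     uti_dqs: r = -0.179 (p = 0.01115, n = 200)
#>     delta_rt_dqs: r = -0.234 (p = 0.0008335, n = 200)
#>     delta_mad_dqs: r = -0.261 (p = 0.0001852, n = 200)
```

Reading the output: 0.5% of trials fell outside the 3-SD reaction-time
band and were flagged; participants with stronger explicit UTI beliefs
were slower (r = .32) and more curved (r = .39) when classifying healthy
relative to unhealthy foods; and both behavioral indices, like the
explicit score, correlate negatively with reported diet quality. The
analytic sample size for a preregistered correlation study is one call
away:

```r
power_n_for_r(0.21, alpha = 0.05, power = 0.90, tails = 2)
#> [1] 235
```

A command-line front end (`inst/cli/utitrack.R`) chains the stages as
`simulate | process | indices | analyze | power` subcommands for shell
use.

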