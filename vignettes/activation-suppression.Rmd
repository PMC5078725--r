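---
title: "Modelling and analysing cognitive action control in an oculomotor Simon task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing cognitive action control in an oculomotor Simon task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(simonact)
library(dplyr)
```

## The scientific problem

In a Simon task the stimulus carries a relevant feature (here, colour,
which dictates a left or right saccade) and an irrelevant one (its
location). When location and required direction disagree — an
*incongruent* trial — responses slow down and errors rise: the congruence
effect. The activation–suppression account explains this with two routes:
an automatic route primed by stimulus location that can capture the
response early, and a deliberate, controlled route that applies the
colour rule; the automatic tendency is selectively inhibited, but
inhibition needs time to build. Two distributional fingerprints follow:

* **Conditional accuracy functions (CAFs).** Sorting each participant's
  trials into seven equal-count RT bins (septiles) and plotting per-bin
  accuracy shows a characteristic dip in the fastest incongruent bin —
  fast responses are the ones the automatic route wins.
* **Delta plots.** The congruence effect on *correct* RTs, computed per
  septile, shrinks for slower responses as inhibition catches up; the
  slope of its final segment is the conventional index of
  selective-inhibition strength.

`simonact` implements this analysis end to end — trial exclusion,
CAF/delta/slope summaries, and random-intercept mixed models — together
with a generative simulator of the task, so that every stage can be
validated against known ground truth.

## The generative race model

No trial-level recordings are available for the study design this package
emulates, so the simulator is a first-class component, not a fixture. A
trial is a race between three clocks:

1. **Controlled route.** Finishing time
   $T_c = \exp(\mu + b_i + \varepsilon)$, with $b_i \sim N(0,
   \sigma_b^2)$ a participant intercept and $\varepsilon \sim N(0,
   \sigma^2)$ trial noise. On incongruent trials the emission is delayed
   by an interference cost $\max\{0,\; \delta_0 - \lambda\,(T_c -
   t_{\mathrm{ref}})^+\}$: slower controlled processing leaves more time
   for inhibition to strip the cost away, which is exactly what makes the
   population delta function decrease (for $\lambda > 0$ it is
   non-increasing beyond $t_{\mathrm{ref}}$).
2. **Automatic route.** With probability $\pi$ a location-driven response
   is launched at $T_a \sim \mathrm{logN}(\mu_a, \sigma_a^2)$.
3. **Suppression deadline.** $D \sim \mathrm{logN}(\mu_s, \sigma_s^2)$;
   a launched automatic response only takes effect if $T_a < D$ and
   $T_a$ beats the controlled emission.

An effective capture responds toward the stimulus — correct on congruent
trials, an error on incongruent ones. Otherwise the controlled response
executes, wrong with a small lapse probability. Contaminant trials
(micromovements under 2°, anticipations under 100 ms, absent responses,
responses beyond 1000 ms) are injected at configurable rates, and genuine
saccade amplitudes are drawn from Normal(12°, 1°) truncated at 2°,
matching targets at 12° eccentricity. With $\pi = 0$ and $\delta_0 = 0$
the two conditions are generated by an identical process — the
simulator's null.

Each participant's trials come from an RNG stream keyed by (seed,
participant id), so any participant reproduces independently of cohort
size.

### Parameters that matter, and their defaults

| parameter | meaning | young | middle-aged |
|---|---|---|---|
| `mu_log_rt` | log mean controlled time (log-ms) | log 300 | log 340 |
| `sigma_log_rt` | trial SD of log controlled time | 0.20 | 0.22 |
| `subj_sd` | participant-intercept SD (log-ms) | 0.15 | 0.15 |
| `capture_prob` | automatic-route launch probability | 0.344 | 0.813 |
| `mu_log_auto` | log mean automatic time (ms) | 5.910 (369 ms) | 6.139 (464 ms) |
| `sigma_log_auto` | log SD of automatic time | 0.35 | 0.35 |
| `mu_log_suppress` | log mean suppression deadline | log 500 | log 500 |
| `delta0` | initial interference cost (ms) | 39.1 | 72.3 |
| `lambda_inhib` | relief rate (ms/ms beyond `t_ref`) | 0.15 | 0.25 |
| `t_ref` | relief origin (ms) | 150 | 150 |
| `lapse_rate` | controlled-route lapse probability | 0.015 | 0.015 |

`t_ref` sits just above the 100 ms anticipation cutoff so relief operates
over the observed RT range. The route parameters were fixed once by the
package's own calibration oracle (below) against the group-level
observables the emulated design reports: mean raw congruence effects of
23 / 35 ms, incongruent accuracies of 88% / 79%, and first-septile
incongruent accuracies of 62% / 46%, for young and middle-aged groups
respectively; contaminant rates were set so the exclusion filters remove
about 1.07% of a pooled study. The two groups differ by general slowing
(`mu_log_rt`), stronger automatic capture (`capture_prob`, `delta0`) and
stronger late inhibition (`lambda_inhib`) — the middle-aged group is not
just a slowed copy of the young one.

A note on where calibration landed: hitting a 46% first-septile accuracy
*and* a 79% overall incongruent accuracy simultaneously requires the
automatic route's error times to overlap the controlled RT distribution
substantially. A fast, tightly suppressed automatic route (means near
220/250 ms) piles essentially all errors into bin 1 and cannot satisfy
both numbers; the admissible regime has a broad, relatively slow
automatic route with a late suppression deadline, with most cancellation
done by the race against the controlled response itself.

### The calibration oracle

`simulate_observables()` estimates the five calibratable observables by
brute force: simulate a large cohort (default $10^5$ trials), run the
*actual* pipeline (exclusions, congruence effect, CAF) and read the
numbers off. Two numerical choices matter:

* The oracle keeps the emulated 300-trial session length and grows the
  cohort instead of lengthening sessions. First-septile accuracy depends
  on trials-per-bin (about 21 here); an oracle with very long sessions
  estimates a slightly different quantity than the study-sized pipeline.
* `calibrate_group()` solves one parameter per observable by bisection
  (`delta0` for the congruence effect, `capture_prob` for incongruent
  accuracy, `mu_log_auto` for first-septile accuracy, `lapse_rate` for
  congruent accuracy, a common contaminant scale for the exclusion rate),
  sweeping over the observables until all sit within tolerance (default
  0.01 absolute on proportions, 1 ms on the effect). Every oracle call
  reuses the same seed — common random numbers make the
  parameter-to-observable map deterministic and near-monotone, so plain
  bisection converges despite the Monte-Carlo setting. Non-convergence
  returns the best point found, flagged.

## Trial exclusion

`apply_exclusions()` applies, in order: absent responses; saccades under
2° (fixation micromovements); latencies strictly below 100 ms
(anticipations) or strictly above 1000 ms (the target's lifetime), both
bounds themselves retained; then a one-pass, two-sided 3-SD latency trim
computed on the survivors. Three conventions were genuinely open and are
configuration switches with these defaults:

* **Trim scope** — per participant, conditions pooled, after the other
  filters: the least aggressive reading consistent with per-participant
  binning downstream (`outlier_scope = "global"` available).
* **Trim scale** — raw milliseconds (`outlier_on = "log"` available).
* **Recursion** — the trim runs once; re-trimming after removal is a
  different (and not described) procedure.

## Distributional summaries

Binning is deterministic: trials are stably sorted by RT (ties broken by
trial order), counts are as equal as possible, and a remainder of $r$
puts one extra trial in each of the $r$ fastest bins (a 140-trial
condition gives exactly 20 per bin; 16 trials over 7 bins give
3,3,2,2,2,2,2). CAFs bin *all* trials per participant × condition; delta
plots bin correct trials only, per condition, and use the mean of the two
condition bin means as the abscissa — the standard convention where the
source analyses leave the abscissa undefined. Group curves are
unweighted participant means (vincentization) with standard errors.
Slopes are per-participant segment slopes of the delta plot; 7 bins give
6 segments, and `drop_first_segment = TRUE` reproduces a 5-level slope
factor for designs analysed that way (which of the six segments the
original 5-level analysis dropped is not derivable; we expose the switch
rather than guess).

```{r pipeline, fig.width = 7, fig.height = 4}
cfg <- study_config(n_participants = c(young = 10, middle_aged = 10),
                    seed = 42)
rep <- run_pipeline(cfg, models = FALSE)
rep$congruence$by_group
autoplot(rep$caf)
autoplot(rep$delta)
```

## Mixed models

The inferential layer mirrors standard practice for this design:

* `fit_lmm()` — log RT on congruence × group with a participant random
  intercept, REML via `lme4`/`lmerTest`. Natural logs counter general
  slowing; raw RTs stay in the table for the plots and deltas.
* `fit_glmm_logit()` — trial-level (Bernoulli) accuracy with the same
  effects, adaptive Gauss–Hermite quadrature (15 nodes by default; the
  fixed effects move by less than $10^{-3}$ between 7 and 31 nodes).
  Working at the trial level avoids the power loss of aggregating.
* `caf_model()` — accuracy on congruence × group × bin (2 × 2 × 7), with
  the first-bin group contrast (the automatic-activation index) extracted
  as a nested fit.
* `slope_model()` — slopes on segment + group with a participant
  intercept, plus the final-segment-only group contrast (one value per
  participant, so an ordinary between-participant F test).

Wald chi-square statistics (`car::Anova`, type II) are the primary
per-term tests — always well defined for both families; Satterthwaite F
tests are reported alongside for the linear models. Denominator degrees
of freedom are a software convention with no single exact answer for
mixed models, so no attempt is made to replicate any particular
historical df; both labelled conventions are exposed. The overall
$R^2$ is the squared Pearson correlation between fitted and observed
responses. Complete separation in the logistic models (a design cell
with all-identical outcomes) is detected and handled by a light
data-augmentation ridge — one success and one failure per affected cell
at weight 0.05 — and flagged in the fit's notes.

The test suite checks this layer against independent implementations:
a direct dense-matrix optimizer of the exact REML criterion and a direct
Gauss–Hermite marginal-likelihood optimizer, both written from scratch in
the tests, must agree with the fitted models on small instances; with the
random variance generated as zero, both models must collapse to their
ordinary fixed-effects counterparts.

## Saccade detection

For gaze-trace input (300 Hz, horizontal-only — the task is left/right),
`estimate_velocity()` smooths with a short moving average (3 samples) and
differentiates centrally; `detect_saccades()` applies an iterative
adaptive threshold (start 100 deg/s; re-estimate as mean + 6 SD of
sub-threshold samples until the change is under 1 deg/s; fixed 30 deg/s
fallback, flagged, if 50 iterations fail to converge). Supra-threshold
runs of ≥ 3 samples become events, extended to the nearest local
velocity minima; the first post-stimulus event of at least 2° is the
trial's response, smaller earlier events being fixation micromovements.
Glissade/fixation classification and blink handling are out of scope —
downstream needs only the first movement's latency, direction and
amplitude. The synthetic traces use a minimum-jerk displacement with
main-sequence durations (≈ 2.2 ms/deg + 21 ms) and Gaussian sample noise
(default SD 0.05°, typical of 300 Hz video trackers); on these, detected
onsets match the programmed onset within one sample for ≥ 95% of trials,
and end-to-end direction/latency agree with generator truth on ≥ 99% of
uncontaminated trials.

## What the simulator does and does not establish

The generator reproduces the qualitative signatures that motivate the
analysis — general slowing plus a larger congruence effect in the older
group, fast location-driven errors concentrated in the first incongruent
septile, delta functions that decline across the distribution and
decline faster in the older group — with interpretable parameters. It
does not emulate sequential effects (post-error slowing, congruence
sequence effects), speed–accuracy trade-off strategies, fatigue or
learning across blocks, or non-stationary eye-tracker noise. Passing
tests therefore certify the pipeline's correctness and the estimators'
calibration on a faithful-but-idealised data-generating process, not the
empirical adequacy of the race model itself; the package deliberately
offers no routine for fitting the race model to real data.

## Problem sizes and numerical choices

Replicate-based checks in the test suite run at reduced sizes chosen so
each check retains its diagnostic value: parameter-recovery at 12–20
participants × 40–60 trials over 25–50 replicates (3-SE coverage is
insensitive to size), type-I calibration at 100–200 replicates, and the
group-difference and recovery acceptance checks at the full emulated
sample sizes (43 + 39 participants × 300 trials), which simulate in
seconds. Bisection tolerances are 1 ms on the congruence effect and 0.01
on proportions; tie-breaks in binning follow input order; degenerate
inputs (single bin, coincident midpoints, a condition with no correct
trials, empty tables) raise warnings or errors as documented on each
function.
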