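---
title: "Models and methods for infant audiotactile orienting analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for infant audiotactile orienting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiotactile)
```

## The scientific problem

When an auditory or vibrotactile stimulus is delivered to one of an
infant's hands, the infant's first lateralized movement — an eye/head turn
or a unilateral hand/arm movement — can be coded for direction, modality
and latency. Comparing such orienting responses between sighted (S) and
severely visually impaired (SVI) infants, across unimodal (auditory-only,
tactile-only) and bimodal (audiotactile congruent or spatially
incongruent) stimulation, and across uncrossed- versus crossed-hands
postures, probes three things at once: the accuracy of unisensory
localization, the influence of an external (visual) frame of reference on
tactile space (the crossed-hands deficit), and multisensory integration
(redundancy gains and crossmodal conflict).

This package implements the full analysis chain for such studies: session
scheduling, dual-rater reconciliation and reliability, trial filtering,
random-intercept mixed models with Type III Wald tests and corrected
marginal-mean contrasts, and the race-model redundancy-gain analysis — and
a synthetic-data generator so every stage can be exercised and validated
without access to infant data.

## Design and trial model

A session has 6 blocks: blocks 1–3 with hands uncrossed, 4–6 crossed.
Auditory-only, congruent and incongruent trials are interleaved in blocks
1, 2, 4 and 5; tactile-only trials sit separately in blocks 3 and 6. Each
of the four conditions occurs 12 times (6 per posture), 48 trials in all,
and no hand receives the same sensory cue on more than 2 consecutive
trials. `make_schedule()` regenerates such an order by constrained
pseudorandomization (block-wise permutations under rejection sampling).
The exact historical trial order is not public; because no implemented
statistic depends on the particular order — only on the constraints — a
documented default seed stands in for it, and `validate_schedule()`
checks every constraint explicitly.

Responses are coded per trial as modality (`arm_hand`, `eye_head`, `both`,
`null`), side (`left`, `right`, `null`) and latency in seconds within the
8 s response window. The binary analysis outcome codes 1 for a response
with or toward the stimulated limb; on incongruent trials, where both
hands are stimulated, the outcome instead codes 1 for a response toward
the *auditory* location (`add_response_outcome()`).

Trials coded `both` (simultaneous eye/head and hand/arm movement) carry a
single side and latency and are included in all analyses; the
`hand_arm_only` switch restricts the tactile-localization models to
`arm_hand` responses for the sensitivity analysis in which eye/head
responses (which necessarily engage an external reference frame) are
excluded. The reaction-time cutoff in `filter_trials()` is strict — a
response at exactly 4 s survives a 4 s cutoff, matching the convention of
excluding responses *longer than* the cutoff.

## Rater reconciliation and reliability

Two raters code every trial from video recorded at 25 frames per second,
so latencies are quantized to 1/25 s. `reconcile_ratings()` keeps trials
on which the raters agree on side and modality; residual disagreements
become null trials and drop out of analysis (reconciliation can exclude
but never invent a response). The agreed latency is the mean of the two
ratings re-quantized to the frame grid — the historical procedure let
raters "come to an agreement" without stating a rule, and the symmetric
mean is the natural convention.

Agreement is summarized by Cohen's kappa `(p_o - p_e) / (1 - p_e)` and by
weighted kappa with linear or quadratic distance weights, with the `null`
category included as a rating level. Confidence intervals use the
large-sample (Fleiss–Cohen) asymptotic variance with normal quantiles;
this is the common default where the interval method is otherwise
unspecified, and values can differ in the third decimal from bootstrap or
exact methods. Latency agreement is summarized by the Pearson correlation
(Fisher-z interval) and the mean signed difference (normal-approximation
interval).

## Mixed models

Orienting direction is modelled by a logistic generalized linear mixed
model and latency by a linear mixed model, each with the fully crossed
fixed effects of group, posture, (condition,) and age in months, and a
participant random intercept — infant studies rarely support
participant-specific slopes. Four analysis presets mirror the standard
design: auditory localization (auditory-only trials), tactile
localization (tactile-only), multisensory gain (tactile-only,
auditory-only, congruent) and crossmodal conflict (tactile-only,
auditory-only, incongruent). For the latency models only responses to the
stimulated limb enter, except in the incongruent condition where the
first response counts whichever stimulus it targeted.

Fitting goes through `lme4`: `glmer()` with the participant intercept
integrated out by adaptive Gauss–Hermite quadrature (`n_quad` nodes;
`n_quad = 1` is the Laplace approximation and the default, matching the
toolchain default for binomial mixed models), and `lmer()` by REML
(default) or ML. Two numerical conventions matter and are enforced by
`prepare_model_data()`:

* **Sum-to-zero contrasts** on all factors. Type III tests are
  coding-sensitive; they are only meaningful under sum-to-zero coding, so
  the package mandates it rather than leaving it to the session options.
* **Grand-mean centering of age.** With interactions present, Type III
  tests of lower-order terms are evaluated at age 0 of the covariate;
  centering makes that the sample mean age rather than birth.

`wald_type3()` computes, for each model term, the Wald statistic
`b'V^{-1}b` over the term's coefficient block (`V` from the observed
information), with as many degrees of freedom as the block has columns —
the chi-square analogue of the classical Type III table. Degenerate
(aliased) blocks raise an error naming the term. `fit_lmm()` refuses
data with one observation per participant, where the intercept and
residual variances are not separately identified.

`emm_contrasts()` produces estimated marginal means on the
linear-predictor scale and pairwise contrasts within conditioning cells,
with an *explicit* Bonferroni family size: the study's convention counts
the full set of meaningful contrasts for an interaction (n = 2 for a
two-way interaction, n = 6 or 12 for the three-way families), which is
larger than the per-cell family a default adjustment would use, so the
multiplier is a parameter rather than an inference. Effect sizes are
standardized differences using the model sigma and error degrees of
freedom.

## Race-model redundancy gains

The race-model inequality bounds the bimodal reaction-time CDF by the sum
of the unisensory CDFs: `P(RT_AT <= t) <= F_A(t) + F_T(t)`. Responses
faster than this bound cannot be explained by independent parallel
channels and indicate multisensory integration. The analysis:

1. Per participant and posture, empirical CDFs of the reaction times of
   responses to the stimulated hand in the A, T and AT conditions, read
   off at the nine deciles 0.1–0.9 with the **type-1 (inverse step-CDF)
   estimator**: the quantile at `q` is the smallest observed value whose
   step-CDF reaches `q`. The bound `G(t) = min(1, F_A(t) + F_T(t))` is a
   step function, and inverting bound and data CDFs with the same
   estimator keeps the comparison exact; interpolating estimators would
   mix conventions. Capping at 1 cannot move any decile at or below 0.9.
2. The multisensory gain at decile `q` is the *horizontal* difference
   `RT_bound(q) - RT_AT(q)` in seconds (positive = faster than the
   bound). The gain is defined in the reaction-time domain — the
   operational definition of the published Methods — rather than as a
   vertical CDF difference; the package computes quantile profiles from
   which either reading can be derived.
3. Gains are computed within participant first and then aggregated:
   per group, posture and decile, a one-sample one-tailed t test of the
   mean gain against zero (H1: gain > 0), and a two-tailed Welch t test
   between groups (no variance homogeneity assumed, hence fractional
   degrees of freedom). Both families are Bonferroni-corrected for the
   nine deciles. Participants missing any of the A, T or AT cells in a
   posture are dropped listwise from that posture and logged.

## The synthetic-data generator

`simulate_dataset()` emulates the data-generating structure the analysis
assumes, not any particular dataset:

* **Design**: two groups of 10 infants (ages uniform over 5–35 months),
  one shared 48-trial schedule, ~5% null responses. Session truncation
  (infants quitting early) is not modelled; every simulated participant
  completes the schedule.
* **Direction**: a logistic model on the log-odds scale with participant
  random intercepts (`sigma_u`, default 0.8) and effects for group,
  posture, their interaction, age and condition. Defaults (intercept 1.2,
  posture 0.4, group x posture 0.6, congruent boost 0.6) give ~70–85%
  correct orienting with a crossed-hands cost concentrated in the sighted
  group — the qualitative pattern such studies report.
* **Latency**: a two-channel race. Each unisensory channel is
  shifted-lognormal, `t0 + exp(Normal(meanlog, sdlog))` (default
  `t0 = 0.4` s, `meanlog = 0.2/0.35`, `sdlog = 0.5`), chosen because
  infant orienting latencies are strictly positive, right-skewed and on a
  1–4 s scale; no distributional form is prescribed by the design, so
  this is a package decision. Congruent bimodal latencies are the channel
  minimum minus `violation_v` seconds (default 0.2), floored at 0.05 s: a
  subtractive violation is the simplest mechanism that parametrically
  controls the quantity the race-model test measures, without committing
  to a process-level coactivation model. With `violation_v = 0` the
  architecture satisfies the race bound (independent channels:
  `P(min <= t) = F_A + F_T - F_A F_T <= F_A + F_T`). On incongruent
  trials the tactile side wins with probability `tactile_pref`
  (defaults S 0.35, SVI 0.65, mirroring the reported preference
  asymmetry) and the latency is the winning channel's draw, with no
  interference term. Latencies beyond the 8 s window become null
  responses.
* **Raters**: rater 1 reproduces the truth; rater 2 flips sides with
  probability `rater_disagree` (default 0.03, putting kappa near the
  reported ~0.93) and jitters latencies with SD `rater_rt_sd` (default
  0.04 s, about one video frame). Both raters are frame-quantized.

What passing tests on simulated data do *not* show: real infant data have
session truncation, drifting attention, age-dependent latency scales and
coder idiosyncrasies that the generator does not emulate. The simulations
validate the statistical machinery — estimator identities, operating
characteristics under known truth — not the substantive findings.

## Numerical choices and degenerate inputs

* Schedules: rejection sampling over block-wise permutations, bounded at
  10,000 attempts per block (the constraints are loose; failures are not
  expected but raise a diagnostic).
* Quantile inversion uses a `1e-9` slack when comparing step-CDF values
  to decile targets so that grid probabilities like 0.3 do not tip over a
  step edge through floating-point representation.
* GLMM: fixed `lme4` defaults (Laplace unless `n_quad` raised); a
  constant outcome triggers a separation warning; convergence is recorded
  in the fit object rather than silently ignored.
* Kappa: degenerate marginals (chance agreement 1) raise an error;
  confidence intervals are truncated to [-1, 1].
* Race model: participants with empty cells are excluded listwise per
  posture and logged; group tests with fewer than 2 participants per
  group return `NA` rather than a fabricated statistic.

## Problem sizes used in the validation suite

The test suite validates schedule constraints over 1,000 seeds; parameter
recovery with 50 participants per group over 100 replicates; race-model
test level under the bound-satisfying null over 500 simulated studies;
and detection power under a 0.5 s violation over 200 replicates at the
study's own scale (10 per group). One caveat the power simulations make
explicit: with 6 trials per condition-posture cell, per-decile
Bonferroni-corrected tests are underpowered in individual group x posture
cells even for a 0.5 s violation, both because decile estimates from ~4–6
latencies are noisy and because a subtractive violation of the channel
minimum translates into a smaller gap against the summed-CDF bound at
central deciles. Detection of the violation per group (across postures)
is essentially certain; per-cell power is ~0.8–0.93.

## Limitations

* The generator's distributional choices (shifted-lognormal channels,
  subtractive violation) are conventions, not estimates; parametric
  conclusions about real infant latencies should not be read off them.
* The kappa confidence-interval method is asymptotic; small rating sets
  deserve a bootstrap.
* Mixed-model statistics recomputed on any archived dataset can differ in
  late decimals from published tables depending on contrast coding and
  age centering, which published methods sections rarely pin down; the
  package's conventions (sum-to-zero, grand-mean centering) are stated
  above precisely so such differences are attributable.
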