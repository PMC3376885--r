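---
title: "Predictive wagers in short sequence learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive wagers in short sequence learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqwager)
```

## The task and the measures

seqwager analyses a "Whac-A-Mole"-style serial reaction time (SRT) task:
a target circle appears at one of four positions in a 2×2 grid inside a
500×500-px canvas, the participant clicks it, and after a 750-ms
inter-stimulus interval (ISI) the next circle appears. Stimulus order
follows a 48-item training sequence whose statistical regularity is
controlled; the cursor is tracked at roughly 40 Hz throughout. The
scientific question is whether learning expresses itself *reactively*
(faster responses once the stimulus appears) or *predictively* — as
overt "wagers" in which the cursor travels to the expected position
during the ISI, before anything is on screen.

Two trial-level measures carry the analysis, both taken from the cursor
position at the end of the ISI (the "750-ms mark", immediately before
onset):

* **initial distance to next** — Euclidean distance to the upcoming
  target's centre; 0 for a perfect prediction;
* **initial distance from previous** — the maximum of the horizontal and
  vertical displacement from the previous target's centre (axis-max /
  Chebyshev). A movement committed to *any* other target registers the
  full grid spacing on at least one axis, whether or not the guess was
  right.

A trial is classified **predictive** when the distance from previous is
at least 275 px and **correct** when it is predictive and ends within
100 px of the upcoming target. Both thresholds are inclusive. Trial 1
has no previous target and is excluded from classification (it counts
toward block denominators but can never be predictive). Trials are
aggregated in eight six-trial blocks; each block yields a predictive
proportion on the lattice 0, 1/6, …, 1 and an **excess score**
(predictive minus correct-predictive counts, 0–6), which is positive
when participants wager before their wagers are accurate.

### Why the targets sit 300 px apart

The task geometry is not fully determined by the published constants
(canvas 500 px, 35-px circles, 2×2 grid), so the layout is a package
design choice. We centre the targets 100 px from each edge, giving
300-px spacing, because that is the only symmetric arrangement under
which the two published thresholds partition behavior cleanly: a
movement onto any other target covers 300 px on at least one axis
(≥ 275 ⇒ predictive), while waiting at the canvas centre — the
"centering" strategy — sits at 150 px on both axes (< 275 ⇒ reactive).
With the tighter 250-px spacing of a grid centred at quarter points, a
perfect wager onto an adjacent target would measure only 250 px and
could never be classified predictive, which contradicts the behavioral
definitions the thresholds encode. `initial_distance_from_previous()`
also exposes a Euclidean alternative (`metric = "euclidean"`) for
sensitivity analysis; Chebyshev is the default reading of "maximum
horizontal/vertical distance".

## Sequence regularity G

Regularity is redundancy under a first-order (bigram) model. For a
sequence over the four positions, let `N[s, t]` count how often `t`
immediately follows `s`, let `H(s)` be the base-2 Shannon entropy of
row `s`'s maximum-likelihood successor distribution, and let `H̄` be the
unweighted mean of the four row entropies (rows with no observed
successor contribute zero). Then

$$G = 1 - \bar H / \log_2 4 .$$

`G = 1` means every observed transition is deterministic; `G = 0` would
require uniform successors including immediate repeats. Because training
sequences forbid repeats, each row has at most three successors and G is
floor-bounded at `1 − log2(3)/2 ≈ 0.2075`.

Choices worth recording:

* *Weighting.* Each symbol contributes 1/4 regardless of how many
  transitions it emits, and the normaliser is `log2(4) = 2` bits. This
  is the only combination that reproduces the reference G values shipped
  with the eleven bundled training sequences (`bundled_sequences()`);
  transition-count weighting and a `log2(3)` normaliser do not.
* *The 0.68 row.* One bundled sequence is published with G = .68 but
  recomputes to 0.6872, which rounds to .69. The loader flags the row
  (`g_mismatch`, plus an optional warning) rather than silently adopting
  either value.
* *Rounding.* Full precision is carried everywhere; `round_half_up()`
  (half away from zero, 2 decimals) is applied only for display and for
  comparison against the 2-decimal reference values.
* *Recall scoring.* The same statistic is applied unchanged to 24-click
  recall output, which is neither balanced nor repeat-free; empty rows
  contribute zero entropy there too.

`generate_sequence()` synthesises new constrained sequences for a target
G by seeded local search: start from a random balanced no-repeat
sequence, propose position swaps (count-preserving by construction;
swaps that would create a repeat are rejected), accept moves that reduce
`|G − target|`, and escape local minima with a simulated-annealing
probability `exp(−Δ/T)` under a slowly decaying temperature
(`T0 = 0.05`, factor 0.9995 per proposal, 20 000 proposals). A target of
exactly 1 short-circuits to a repeated 4-cycle. Targets below the
no-repeat floor fail fast with a `search-failure` error.

## The synthetic cohort

No trajectory corpus ships with the package, so a generative agent
stands in for participants; every downstream stage runs identically on
real exports with the same CSV schema. The agent is deliberately minimal
— enough structure to express the behavioral modes the analyses are
designed to detect, and nothing else.

**Learning.** The agent keeps additively smoothed transition counts
(pseudocount `smoothing_pseudocount = 0.1`). Each observed transition is
stored correctly with probability `1 − encoding_noise` and mis-stored as
a random other successor otherwise (`encoding_noise = 0.15`). Encoding
noise is what makes *early* wagers error-prone — a wager formed from one
or two possibly-corrupted observations can head to the wrong target —
while accumulating counts wash errors out, so late wagers are almost
always correct. This single mechanism produces the early excess-score
positivity and the late dominance of correct prediction.

**Wagering.** Before each trial the agent looks up the smoothed
successor distribution of the previous symbol. If the maximum
probability reaches `wager_threshold = 0.75` it commits a wager toward
the argmax (ties broken uniformly at random); once wagering, the mode
persists with `wager_stickiness = 0.95` per trial. The threshold is set
so that one confidently encoded observation (smoothed probability
1.1/1.4 ≈ 0.79) suffices: wagers can then emerge during the second
six-trial block on fully regular sequences, rather than only after every
transition has been seen twice. Setting `wager_threshold` above 1 (e.g.
1.01) disables wagering entirely.

**Reactive trials.** The agent either stays on the previous target or
repositions to the canvas centre with `centering_propensity = 0.5` — the
"optimal equidistant waiting" strategy.

**Movement and timing.** The ISI cursor stream is sampled at a nominal
40 Hz (25-ms steps with ±3-ms jitter), moving in a straight line toward
the goal at `motor_speed = 600` px/s, capped at the goal, with 3-px
isotropic noise on the recorded coordinates. Click time is

```
onset + base_latency · (1 − implicit_gain · p̂) + distance/speed + noise
```

where `p̂` is the agent's internal probability of the stimulus that
actually appeared and `distance` is from the ISI-end cursor position to
its centre (`base_latency = 400` ms, `implicit_gain = 0.5`, latency
noise SD 50 ms, floored at zero). Two facts follow by construction
rather than by injection: RT facilitation with G is *emergent* (wagers
shorten the travel term; expectation priming shortens the latency term),
and the priming term operates whether or not the agent overtly wagers —
which is what lets low-awareness, non-wagering agents still show a
G-dependent RT improvement, the implicit-learning signature.

**Recall and awareness.** The 24-item recall is a walk sampled from the
agent's own smoothed transition table (start symbol uniform) — an
"inclusion"-style generation from learned knowledge, not verbatim
replay. The awareness rating is
`100 + 300·logistic(6·p − 3) + noise` clipped to [100, 400], where `p`
is the final-two-block predictive proportion and the noise SD is 120
scale units, chosen so the awareness–predictiveness coupling is moderate
(~0.5) rather than deterministic. Note the generative structure:
awareness depends on sequence regularity *only through* predictive
behavior, so the residual-mediation asymmetry the analysis tests for
(prediction survives partialling out G; G does not survive partialling
out prediction) is a property of the mechanism, not of a tuned constant.

**What the generator does not emulate.** Curved or minimum-jerk
trajectories, speed–accuracy trade-offs (Fitts' law), fatigue and
attention lapses, within-participant parameter heterogeneity, explicit
strategy switching away from wagering, and oculomotor behavior. Passing
tests therefore demonstrate that the pipeline detects these effects when
they are present with the stated generative structure — not that human
data will show them, nor that the agent is a cognitive model of record.

## The statistical stage

* **Learning curves** — `response ~ G + Trial + G:Trial` with a
  subject random intercept, via lme4/lmerTest; per-term F tests use
  Satterthwaite denominator degrees of freedom. Only a random intercept
  is fitted (random slopes are not identified at 48 trials per subject
  with G constant within subject). Singular or failed fits fall back to
  OLS with subject-clustered sandwich standard errors, flagged in the
  result.
* **Bimodality** — per-block histograms of predictive proportions over
  the 7-point lattice, Pearson chi-square against uniformity (df 6).
* **Excess scores** — one-sample t against zero per block; zero-variance
  inputs are reported with flags (t = 0 or ±Inf) rather than erroring.
* **Recall** — Pearson correlations of training G with recall G and
  with the cross-recurrence match, plus multiple regressions of each
  recall measure on predictive proportion with training G as covariate.
* **Mediation** — residual-based: regress awareness on G and correlate
  residuals with predictiveness, and vice versa.
* **Low-awareness subset** — participants strictly below the 250
  midpoint of the 100–400 scale ("somewhat patterned" maps to the scale
  midpoint; the cutoff is config-exposed), refit of the RT model.
* No multiple-testing correction is applied anywhere, matching the
  analysis style the pipeline reproduces.

**Cross-recurrence match.** The match between a 48-item training
sequence and a 24-item recall is the best diagonal alignment of the
cross-recurrence matrix: the maximum over non-negative lags 0–24 of the
number of positions where the lagged training window equals the recall,
as a percentage of 24. This is the simplest operationalisation of
"percentage of positions that are the same" for sequences of unequal
length; negative lags are excluded by default (config-exposed), and a
normalised longest-common-subsequence variant (`variant = "lcs"`,
order-preserving but gap-tolerant, hence an upper bound on the diagonal
score) is provided for sensitivity analysis. Note that even for
unrelated sequences the max-over-lags statistic exceeds the 25%
single-lag chance level; comparisons should always be against matched
baselines, as in the test suite's Monte-Carlo check.

## Numerical and degenerate-input conventions

* ISI-end position: last sample at or before onset; when jitter leaves
  the onset strictly between two samples, linear interpolation between
  the straddling pair; a trial with no usable ISI sample is dropped and
  logged, never imputed.
* Ties among equally probable wager targets: uniform seeded choice.
* All randomness flows from explicit integer seeds; cohorts draw one
  sub-seed per participant from the master seed, so any participant is
  reproducible in isolation and `simulate_cohort()` is byte-stable.
* `transition_counts()` rejects sequences shorter than 2
  (degenerate-input); `redundancy_g()` tolerates absent symbols via the
  zero-entropy convention for empty rows.

## Problem sizes

The shipped test suite simulates full 143-agent cohorts (11 sequences ×
13 agents) for the end-to-end checks, 20 seeded replicate cohorts for
the stochastic signatures (coefficient signs, bimodality chi-squares,
early excess positivity, mediation asymmetry), smaller 2–3-sequence
cohorts for mechanism-level properties, and 1 000–10 000 random
instances for the oracle-equivalence and structural-bound checks. These
sizes were chosen to match the design being emulated while keeping the
suite comfortably re-runnable on a laptop.

## Known limitations

* The agent's straight-line, constant-speed kinematics make the two
  distance measures sharper than human trajectories would be; threshold
  sensitivity should be explored with `metric` and the threshold
  arguments before applying the pipeline to real exports.
* G is first-order by design; sequences with higher-order structure but
  flat bigram statistics will score near the floor (non-goal:
  trigram-and-beyond redundancy).
* Mixed-model degrees of freedom follow the Satterthwaite convention of
  the fitting backend; they are not expected to reproduce any particular
  published df exactly.
* The awareness link and its constants are a modelling convenience;
  only sign and ordering claims about awareness should be read off the
  synthetic cohort.
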