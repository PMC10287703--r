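---
title: "Methods: activity levels, forecasts, weekly statistics and the rule base"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity levels, forecasts, weekly statistics and the rule base}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcoach)
```

stepcoach implements a hybrid activity-coaching engine: deterministic
WHO-derived rules and a learned classifier assign each day an activity level,
a convolutional network forecasts daily steps, naive residual statistics turn
point forecasts into 80% prediction intervals, weekly pattern statistics
score each week against a goal profile, and a propositional rule base maps
all of these signals to personalized recommendation messages annotated into a
small RDF knowledge schema. This vignette documents the models, their
assumptions, the tunable parameters, and the design choices taken where the
design was genuinely open.

## Daily activity levels

A day is classified into five levels (0 = sedentary to 4 = highly active)
from two signals: the daily step count and the weekly moderate-equivalent
(ME) minutes, `(2 * VPA + MPA minutes) * 7`, where one vigorous minute counts
as two moderate minutes. The step bands are <5000, 5000--7499, 7500--9999,
10000--12499 and >=12500; the ME bands are <90, 90--209, 210--299, 300--359
and >=360 weekly minutes, with the ME route applying only above 4999 steps.
Two open points were resolved as follows:

* **Precedence.** The step and ME bands can disagree (11000 steps with ME
  140 satisfies the level-3 step band and the level-1 ME band). We evaluate
  levels from 4 down to 0 and return the first match — the maximum attained
  level. This keeps the classifier total, deterministic, and monotone
  non-decreasing in steps (and in ME above 4999 steps), which the property
  tests verify on a 3-D grid.
* **Units.** Storage is seconds (sensor native); seconds are divided by 60
  only at this rule boundary, fractional minutes are kept, and thresholds are
  compared with the strict/non-strict operators exactly as stated. The
  "LPA >= 0" conjunct of the sedentary rule is vacuous and has no effect.

Per-minute intensity (IMA) counts partition into LPA [0, 400],
MPA [401, 800] and VPA [801, inf); `classify_ima()` is a partition of the
non-negative integers with no gap at the 400/401 and 800/801 boundaries.

## The synthetic cohort generator

No sensor data ships with the package; `synthesize_cohort()` emulates
minute-epoch output of a wrist/thigh accelerometer of the MOX2-5 class. Its
defaults are the study conditions we target: 16 participants, 30 days,
and an activity-level mix of (0.35, 0.25, 0.15, 0.15, 0.10) over levels 0--4
— a sedentary-leaning cohort typical of adult convenience samples. Per day
the generator draws a target level, a step count inside that level's step
band, and integer moderate/vigorous minutes whose weekly ME stays inside a
band no higher than the target, so every synthetic day classifies exactly to
its target level — the generator's labels are rule-consistent by
construction. Minutes are then laid out with active minutes carrying 60 s of
their own type, sedentary minutes splitting their 60 s between sitting and
standing (so mixed second budgets occur while the six fields always sum to
60 s), IMA drawn from the dominant type's band with a 0.005 probability of a
just-across-the-boundary draw (documented sensor boundary noise), and daily
steps distributed over minutes by a multinomial with intensity-scaled rates,
which conserves the daily total exactly. Everything is deterministic under
the spec's seed.

What the generator does **not** emulate: wear-time gaps and non-wear days,
autocorrelated within-day activity bouts, inter-day habit persistence, and
device-specific step-detection error. Tests passing on this cohort therefore
show that the pipeline's logic and learning behave correctly under clean,
rule-consistent data; they do not establish accuracy figures on real sensor
data.

## Learned models

**Classifier.** A feed-forward network with six dense layers
(32-32-16-16-16-5), ReLU hidden activations and a softmax head over the five
levels, trained on the five daily features (steps and sedentary/LPA/MPA/VPA
seconds) with categorical cross-entropy under ADAM (alpha 0.001, beta1 0.9,
beta2 0.999, eps 1e-8, no decay), a 0.05 validation split and a
reduce-on-plateau schedule (halve after 10 stale epochs, floor 1e-5).
Features are min-max scaled to [0, 1]. The epoch count is not pinned down by
the reference architecture, so the classifier defaults to 200 epochs with the
plateau schedule; the train/test split used in benchmarks is a stratified-ish
random 80/20 at a fixed seed. Both networks are implemented in plain R
matrix code (no deep-learning framework is required at run time), which
keeps training single-threaded and bit-reproducible under a seed; on the
2000-row synthetic benchmark training takes a few seconds and reaches
held-out accuracy above 0.95 against the rule labels.

**Forecaster.** A univariate convolutional network: two 1-D convolutions
(kernel 3, ReLU; filter counts are not specified by the reference design and
default to 64 and 32, exposed in `forecaster_config()`), one max-pooling
layer (pool size 2), a flatten and a dense output of size 1. The series is
min-max scaled to [0, 1] (a constant series maps to 0.5 so the inverse
recovers the constant), supervised windows of `n_steps` values predict the
next value, and training uses MSE under ADAM for 200 epochs with batch size
50. The window length defaults to `n_steps = 7` — one week, the natural
period of the data. Multi-step forecasts are recursive (each prediction is
appended to the window), clamped at zero because step counts cannot be
negative.

## Prediction intervals

The 80% interval around a point forecast is `point +/- c * sigma_h` with
`c = 1.28` (1.645 and 1.96 are available for 90%/95%); `sigma_h` is the
sample standard deviation of the one-step naive-forecast residuals, i.e. of
the first differences of the observed series, computed over the full history
by default (a trailing window is available). `sigma_h` is held constant
across the 7-day horizon, matching the reference usage of a single residual
SD for all seven days; `sqrt(h)` widening exists behind a flag, off by
default. Bounds are rounded half-up to integers. Note the reference interval
table is internally inconsistent at the final integer digit for four of its
seven days (its gap alternates between the rounded and truncated value of
`1.28 * 1271.0 = 1626.88`); the implementation applies one convention —
half-up on the exact bounds — uniformly.

## Weekly statistics

For each week: the feature means; the activity pattern vector (APV) of the
seven daily levels; the similarity score `SC = sum(APV) - sum(goal scores)`
(`SC >= 0` means the weekly goal was met); the performance score
`S = sum(level * weight)` with weights {0, 2, 4, 6, 8} (equivalently
`2 * sum(level^2)`, used as an independent oracle in the tests); the weekly
mean `S/7`, displayed to one decimal half-up; and the cumulative deviation —
the population SD of the weekly means accumulated from week 1 — with error
`sd/sqrt(n)`. Two conventions are documented rather than guessed:

* the deviation list uses the one-decimal *displayed* weekly means, matching
  how the weekly report is read and reproducing the reference four-week
  report's SD/error pairs from its printed means exactly;
* `158/7 = 22.571` displays as 22.6 under half-up; the reference report
  prints 22.5 for that single value, an inconsistency we surface in the test
  suite rather than absorb with a bespoke rounding rule.

## The rule base

Nineteen propositional variables (A-1..A-19) in eight categories — level,
sedentary, steps, activity minutes, daily goal, forecast trend, weekly
deviation, weekly goal — each carry a message template. Daily evaluation
fires exactly one variable per daily category; weekly evaluation fires one
per applicable weekly category, with two documented resolutions:

* **Deviation trend.** The literal printed operands (`SC > 0` for the
  negative trend, `SC == 0` for the positive) contradict the worked example,
  in which a week with `SC = -20` and a rising deviation receives the
  negative-trend message. The default reading is minimal: negative when the
  cumulative deviation rose *and* the weekly goal was missed (`SC < 0`),
  positive otherwise. The literal forms remain available via
  `strict = TRUE`, under which the category may fire nothing.
* **Exclusivity.** The satisfiability rule is enforced per category
  (exactly one true variable in every applicable category), not as a global
  sum-to-one, since a day legitimately receives one message of each kind.
  `check_exclusivity()` mirrors the reasoner-style check; the acceptance
  suite runs it over 10000 randomized contexts.

Sleep terms are treated as satisfied when sleep data is absent (the minute
sensor records none); `hasSedentaryBouts` is read as the daily sedentary
total, since bout segmentation is never defined; the weekly step prediction
compared against the weekly goal is the sum of the 7 forecast points; the
two weather variables are declared in the schema but never fired (no weather
input exists). The exact goal profile behind the worked recommendation sets
is not published; the package fixes a documented WHO-style default
(10000 steps/day, 21.45 moderate minutes/day = 150/7 with the vigorous
target at half, 8 h sedentary budget, goal score 3) that reproduces those
sets.

## Orchestration and the knowledge base

`run_pipeline()` classifies and fires the daily rules for every participant
and day, and at each week boundary after a two-week cold start computes the
weekly statistics, retrains the forecaster on the participant's full history,
builds the interval table and fires the weekly rules. Because each weekly
pass rescans the whole accumulated history, total work grows quadratically
with the number of days (verified empirically by the `pairwise_ops`
counter). All outcomes are annotated into a knowledge base whose schema
declares the object properties (participant to health record, activity
level, interval day, statistic, recommendation, each timestamped) with
domains and ranges; `export_rdf()` serialises it as Turtle, one triple per
line, and `parse_turtle()` reads that profile back so round-trip triple
conservation is testable. The export parses identically under a standard
RDF parser.

## Problem sizes used in the test and acceptance runs

The bundled benchmarks are sized for a desk run: 2000 synthetic rule-labeled
days (100 participants x 20 days) for the classifier benchmark, a 120-day
trend + weekly-seasonal + noise series (innovation SD 300 steps) for the
forecaster-vs-naive comparison, cohorts of 1--4 participants x 14--30 days
for pipeline and generator properties, and 10000 randomized rule contexts
for the exclusivity sweep. These sizes were chosen so each suite exercises
the full code path at statistical scales where the expected behaviour is
unambiguous.

## Known limitations

The classifier learns labels that are a deterministic function of its own
inputs, so its synthetic benchmark measures capacity to recover the rule
surface, not real-world generalisation. The forecaster's advantage over the
naive baseline depends on structure (trend/seasonality) being present; on a
pure random walk the naive forecast is optimal and the network can only
match it. Interval coverage is nominal (normal-residual assumption), not
backtested. The rule base fires every applicable message; selecting an
optimal subset is out of scope.
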