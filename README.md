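# stepcoach

Personalized physical-activity eCoaching from wearable step data, for
digital-health researchers and engineers building activity-coaching
pipelines. The package combines a deterministic WHO-derived activity-level
classifier, a learned daily-level classifier, a univariate convolutional
step forecaster with naive prediction intervals, bespoke weekly performance
statistics, and a propositional rule base that turns all of these signals
into personalized recommendation messages, annotated into an RDF knowledge
schema. A seeded synthetic cohort generator emulates minute-epoch
accelerometer records (MOX2-5-style: per-minute IMA intensity plus a
60-second budget over sitting, standing, weight-bearing and LPA/MPA/VPA
seconds), so the entire pipeline runs and is tested without any real
dataset.

## The model in brief

**Daily level.** A day is level 0–4 by the maximum of its step band
(<5000, 5000–7499, 7500–9999, 10000–12499, ≥12500) and, above 4999 steps,
its weekly moderate-equivalent band, ME = (2·VPA + MPA minutes)·7 against
thresholds 90/210/300/360.

**Weekly statistics.** For each week with activity pattern vector
APV = (ℓ₁…ℓ₇) and goal scores G: similarity score `SC = ΣAPV − ΣG` (goal met
iff SC ≥ 0); performance score `S = Σ ℓᵢ·wᵢ` with weights w = 2ℓ ∈
{0,2,4,6,8}; weekly mean S/7; and the cumulative deviation, the population
SD of the weekly means so far, with error SD/√n.

**Forecasting.** A CNN (two 1-D convolutions, kernel 3, ReLU → max-pool →
dense 1) fits min–max-scaled sliding windows of daily steps; 7-day forecasts
are recursive. Around each point forecast Ŷ the 80% interval is
`Ŷ ± 1.28·σ`, where σ is the sample SD of the naive one-step residuals
(first differences) of the observed series.

**Rules.** Nineteen propositional variables (A-1…A-19) in eight mutually
exclusive categories map the daily level, sedentary/step/minute goal
comparisons, the weekly forecast trend, the deviation trend and the weekly
goal to message templates; exactly one variable fires per applicable
category, enforced by a satisfiability check.

## Worked example

```r
library(stepcoach)

# weekly statistics for a week with pattern [3,3,3,4,4,2,4] against goal 3/day
apv <- c(3, 3, 3, 4, 4, 2, 4)
similarity_score(apv, rep(3, 7))              # 2   (weekly goal met)
performance_score(apv)                        # 158
mean_performance(performance_score(apv))      # 22.6

# 80% prediction intervals around a week of point forecasts, sigma = 1271
tab <- weekly_interval_table(c(3520, 5171, 4855, 4979, 5071, 4508, 3928),
                             c = 1.28, sigma_h = 1271)
tab
#>  day point lower upper
#>    1  3520  1893  5147
#>    2  5171  3544  6798
#>    3  4855  3228  6482
#>    4  4979  3352  6606
#>    5  5071  3444  6698
#>    6  4508  2881  6135
#>    7  3928  2301  5555
attr(tab, "mean_point")                       # 4576

# recommendations for a sedentary day under the default WHO-style goals
goals <- goal_profile()
day <- list(steps = 4649, sedentary_s = 1305, mpa_s = 316, vpa_s = 0)
evaluate_daily(day, goals, level = 0L)
#> "A-1" "A-7" "A-8" "A-10" "A-15"
render_message("A-8", list(x = goals$daily_step_goal - day$steps,
                           x1 = goals$weekly_step_goal))
#> "Please continue 5351 steps more tomorrow to achieve your weekly goal of 70000 steps"
```

The five fired variables read: keep up light activity (A-1), you were under
your sedentary budget (A-7), you missed the daily step goal (A-8) and the
daily activity-minute goal (A-10), and the daily goal overall was not met
(A-15).

For an end-to-end run (synthetic cohort → classification → weekly stats →
forecasts → recommendations → Turtle export):

```r
r <- run(run_config(output_dir = "demo-run", forecaster_method = "naive"))
list.files("demo-run")
```

or from a shell, `Rscript inst/cli/stepcoach.R recommend --out demo-run`.

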