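# actiward

Accelerometer-based physical-activity monitoring and functional-recovery
analysis for hospitalized orthopedic patients.

Patients recovering from total knee or hip arthroplasty (TKA/THA) spend
most of their hospital stay lying or sitting, and low in-hospital activity
predicts slower recovery. A thigh-worn tri-axial accelerometer (25 Hz,
±8 g) makes activity measurable: the thigh is horizontal when lying or
sitting and vertical when upright, so the gravity component on the sensor's
longitudinal axis separates sedentary time from standing, and short-term
signal variability separates standing from walking. `actiward` is for
researchers analyzing such ward-monitoring studies: it implements the
device-style posture classifier, the daily activity summaries, a clinical
recovery score, and the group-comparison statistics, plus a seeded
synthetic-data generator so the whole chain is testable without patient
data.

## What it computes

* **Posture classification** — raw signal → 5 Hz zero-phase low-pass →
  fixed non-overlapping 1-second windows → *dynamic* if the activity
  dispersion (mean deviation of the acceleration vector from its window
  mean) exceeds 0.1 g, otherwise *standing* when the mean absolute
  longitudinal acceleration ≥ **0.8 g** and *sedentary* below it →
  per-minute second counts.
* **Daily summaries** — wear hours from covered time; a **valid
  measurement day** needs ≥ 20 h wear; the primary outcome is minutes
  standing + walking per day (`active_min`), indexed by postoperative day
  (surgery day = POD 0).
* **mILAS scoring** — five activities of daily living scored 0–6 (total
  0–30, 0 = independent; the stair item counts 0 when the patient has no
  stairs at home), app-style percentage transforms, and the dichotomized
  endpoint *functional recovery on POD 1* (first total-0 day ≤ POD 1).
* **Group comparison** — descriptives (median/IQR, n (%)); OLS for POD 1
  active minutes with t-based CIs (B ± t₀.₉₇₅,df·SE); maximum-likelihood
  logistic regression for recovery with Wald CIs and odds ratios; and the
  iterative **≥ 10 % change-in-estimate** confounder selection: candidates
  (age, sex, BMI, surgery type, ASA class) are added one at a time, the
  one shifting the group coefficient most (and by at least 10 %) enters,
  and the process repeats on the enlarged model until no candidate reaches
  10 %, returning the final model plus a full selection trace.
* **Synthetic cohorts and signals** — `simulate_cohort()` reproduces a
  97-patient two-arm ward study (exclusions for delayed sensor fixation,
  early discharge and device malfunction leaving 88 analyzed, 84 with
  POD 1 data) with configurable confounding structure; `simulate_signal()`
  generates seeded accelerometer traces from posture-bout schedules.

## Worked example

Simulate a 6-hour monitored period with 25 scheduled active minutes,
classify it, and summarize the day:

```r
library(actiward)
sch  <- simulate_schedule(as.POSIXct("2019-03-12", tz = "UTC"),
                          wear_s = 6 * 3600, active_min = 25, seed = 1)
sig  <- simulate_signal(sch, sensor_config(), seed = 2)
days <- summarize_days(classify_signal(sig), as.Date("2019-03-11"))
days
#>   patient_id       date pod wear_h valid active_min sedentary_min
#> 1       <NA> 2019-03-12   1      6 FALSE   24.98333      335.0167
```

The classifier recovers the scheduled 25 active minutes to within a few
seconds (bout-boundary windows mix postures); with only 6 h of coverage
the day is correctly flagged invalid for analysis.

Fit the crude group comparison on a two-group dataset (61 control /
23 intervention):

```r
# outcomes with group means fixed at 70.89 and 102.99 min
dat <- data.frame(
  group = rep(c(0L, 1L), c(61, 23)),
  active_min_pod1 = c(70.89 + 15 * scale(rnorm(61))[, 1],
                      102.99 + 15 * scale(rnorm(23))[, 1]))
fit <- fit_linear(dat, predictors = "group")
fit
#> Linear regression of active_min_pod1 (n = 84 complete cases)
#>         term estimate    se p_value ci_lower ci_upper
#>  (Intercept)    70.89 1.921       0   67.069   74.711
#>        group    32.10 3.670       0   24.799   39.401
```

With a lone binary predictor the intercept is exactly the control-group
mean and the coefficient exactly the difference of group means: here the
intervention group stood and walked 32.10 min/day more on POD 1. The whole
chain in one call: `run_pipeline(pipeline_config(list(seed = 1)))` prints
cohort accounting, descriptives, both regression models and their
selection traces. A thin CLI over these functions lives at
`inst/cli/actiward.R` (subcommands `simulate`, `classify`, `summarize`,
`analyze`, `pipeline`).

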