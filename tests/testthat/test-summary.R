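# Daily summaries: wear time, valid-day rule, POD indexing, analysis-day
# selection.

minutes_fixture <- function(day = as.Date("2019-03-12"), covered_min = 1440,
                            standing_min = 120, dynamic_min = 60) {
  start <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
  n <- covered_min
  lab <- rep("sedentary", n)
  lab[seq_len(standing_min)] <- "standing"
  lab[standing_min + seq_len(dynamic_min)] <- "dynamic"
  data.frame(minute_start = start + (seq_len(n) - 1) * 60,
             sedentary_s = ifelse(lab == "sedentary", 60L, 0L),
             standing_s = ifelse(lab == "standing", 60L, 0L),
             dynamic_s = ifelse(lab == "dynamic", 60L, 0L),
             covered_s = 60L)
}

test_that("a full day summarizes to its scheduled wear and active minutes", {
  mins <- minutes_fixture(standing_min = 120, dynamic_min = 60)
  d <- summarize_days(mins, as.Date("2019-03-11"), patient_id = "P001")
  expect_equal(nrow(d), 1)
  expect_equal(d$wear_h, 24)
  expect_true(d$valid)
  expect_equal(d$active_min, 180)
  expect_equal(d$pod, 1)
  # all-sedentary valid day
  d0 <- summarize_days(minutes_fixture(standing_min = 0, dynamic_min = 0),
                       as.Date("2019-03-11"))
  expect_equal(d0$active_min, 0)
  expect_true(d0$valid)
})

test_that("the 20 h wear threshold is an inclusive boundary", {
  d195 <- summarize_days(minutes_fixture(covered_min = round(19.5 * 60)),
                         as.Date("2019-03-12"))
  expect_false(d195$valid)
  d199 <- summarize_days(minutes_fixture(covered_min = round(19.9 * 60)),
                         as.Date("2019-03-12"))
  expect_false(d199$valid)
  d200 <- summarize_days(minutes_fixture(covered_min = 20 * 60),
                         as.Date("2019-03-12"))
  expect_true(d200$valid)
  expect_equal(d200$wear_h, 20)
})

test_that("active minutes never exceed wear time and shrink with coverage", {
  mins <- minutes_fixture(covered_min = 900, standing_min = 300,
                          dynamic_min = 100)
  d <- summarize_days(mins, as.Date("2019-03-12"))
  expect_lte(d$active_min, 60 * d$wear_h)
  # dropping records is monotone in both wear and active minutes
  for (keep_frac in c(0.8, 0.5, 0.2)) {
    sub <- mins[seq_len(round(nrow(mins) * keep_frac)), ]
    ds <- summarize_days(sub, as.Date("2019-03-12"))
    expect_lte(ds$wear_h, d$wear_h)
    expect_lte(ds$active_min, d$active_min)
  }
})

test_that("surgery after all data is an indexing error", {
  mins <- minutes_fixture()
  expect_error(summarize_days(mins, as.Date("2019-04-01")), "indexing")
})

test_that("analysis-day selection returns NA, never zero, for invalid days", {
  daily <- data.frame(
    patient_id = c("A", "A", "B", "C"),
    date = as.Date("2019-03-12") + c(0, 1, 1, 1),
    pod = c(0L, 1L, 1L, 1L),
    wear_h = c(10, 23.5, 10, 21),
    valid = c(FALSE, TRUE, FALSE, TRUE),
    active_min = c(5, 95, 40, 130))
  sel <- select_analysis_days(daily, pod = 1)
  expect_equal(sel$active_min[sel$patient_id == "A"], 95)
  expect_true(is.na(sel$active_min[sel$patient_id == "B"]))
  expect_equal(sel$active_min[sel$patient_id == "C"], 130)
  expect_equal(nrow(sel), 3)
})

test_that("scheduled active minutes are recovered end to end", {
  # noiseless: exact within bout-boundary effects
  sch <- simulate_schedule(t0(0), wear_s = 6 * 3600, active_min = 30,
                           seed = 21)
  truth <- tapply(sch$duration_s, sch$posture, sum)
  active_truth <- sum(truth[c("standing", "walking")], na.rm = TRUE) / 60
  sig <- simulate_signal(sch, sensor_config(), seed = 22)
  mins <- classify_signal(sig)
  d <- summarize_days(mins, as.Date("2019-03-11"))
  expect_equal(d$active_min, active_truth, tolerance = 2 / active_truth)
  expect_equal(d$wear_h, 6, tolerance = 0.01)
})
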