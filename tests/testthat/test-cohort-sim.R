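# Synthetic cohort generator: determinism, convergence, exclusion structure.

test_that("identical seeds give identical cohorts", {
  a <- simulate_cohort(cohort_params(seed = 5))
  b <- simulate_cohort(cohort_params(seed = 5))
  expect_identical(a$patients, b$patients)
  expect_identical(a$daily, b$daily)
  expect_identical(a$milas, b$milas)
  c <- simulate_cohort(cohort_params(seed = 6))
  expect_false(identical(a$patients$age, c$patients$age))
})

test_that("default cohort reproduces the enrollment-to-analysis accounting", {
  co <- simulate_cohort(cohort_params(seed = 2))
  tab <- analysis_table(co)
  expect_equal(nrow(co$patients), 97)
  expect_equal(nrow(tab), 88)
  expect_equal(sum(!is.na(tab$active_min_pod1)), 84)
  expect_equal(sum(!is.na(tab$recovered_on_pod1)), 84)
  acc <- cohort_accounting(97, c(delayed_fixation = 5, early_discharge = 1,
                                 malfunction = 3), n_with_pod1 = 84)
  expect_equal(acc$n_analyzed, 88)
  expect_equal(round(acc$pct_analyzed, 1), 90.7)
  expect_equal(round(acc$pct_with_pod1), 95)
})

test_that("a null group effect yields a near-zero fitted coefficient", {
  p <- cohort_params(n_control = 1000, n_intervention = 1000, effect_min = 0,
                     confounder_strengths = c(),
                     exclusions = c(delayed_fixation = 0L,
                                    early_discharge = 0L, malfunction = 0L),
                     n_excluded_per_group = c(0L, 0L), n_missing_pod1 = 0L,
                     n_missing_recovery = 0L, seed = 8)
  tab <- analysis_table(simulate_cohort(p))
  fit <- fit_linear(tab, predictors = "group")
  b <- fit$terms[fit$terms$term == "group", ]
  # Monte-Carlo error: |B| within ~3 SE of zero
  expect_lt(abs(b$estimate), 3 * b$se)
})

test_that("group means converge to their targets as n grows", {
  dev_for_n <- function(n, seed) {
    p <- cohort_params(n_control = n, n_intervention = n,
                       confounder_strengths = c(),
                       exclusions = c(delayed_fixation = 0L,
                                      early_discharge = 0L,
                                      malfunction = 0L),
                       n_excluded_per_group = c(0L, 0L), n_missing_pod1 = 0L,
                       n_missing_recovery = 0L, seed = seed)
    tab <- analysis_table(simulate_cohort(p))
    m <- tapply(tab$active_min_pod1, tab$group, mean)
    abs(m[["0"]] - 70.89) + abs(m[["1"]] - 70.89 - 32.10)
  }
  small <- mean(vapply(1:6, function(s) dev_for_n(50, s), numeric(1)))
  large <- mean(vapply(1:6, function(s) dev_for_n(2000, s), numeric(1)))
  expect_lt(large, small)
  expect_lt(large, 5)
})

test_that("fixed group means reconstruct a crude comparison exactly", {
  p <- cohort_params(n_control = 61, n_intervention = 23,
                     exclusions = c(delayed_fixation = 0L,
                                    early_discharge = 0L, malfunction = 0L),
                     n_excluded_per_group = c(0L, 0L), n_missing_pod1 = 0L,
                     pod1_group_means = c(70.89, 102.99), seed = 4)
  tab <- analysis_table(simulate_cohort(p))
  fit <- fit_linear(tab, predictors = "group")
  expect_equal(fit$terms$estimate[fit$terms$term == "group"], 32.10,
               tolerance = 1e-10)
})

test_that("injecting invalid days zeroes out targeted patients only", {
  p <- cohort_params(exclusions = c(delayed_fixation = 0L,
                                    early_discharge = 0L, malfunction = 0L),
                     n_excluded_per_group = c(0L, 0L), n_missing_pod1 = 0L,
                     seed = 11)
  daily <- simulate_cohort(p)$daily
  out <- inject_invalid_days(daily, "delayed_fixation", n_patients = 9,
                             seed = 99)
  valid_ids <- unique(out$patient_id[out$valid])
  expect_equal(length(valid_ids), 97 - 9)
  affected <- setdiff(unique(out$patient_id), valid_ids)
  expect_length(affected, 9)
  # untouched patients keep their records bit-for-bit
  keep <- out$patient_id %in% valid_ids
  expect_identical(out[keep, ], daily[daily$patient_id %in% valid_ids, ])
  # identity when nothing is injected; determinism under a seed
  expect_identical(inject_invalid_days(daily, "malfunction", 0), daily)
  expect_identical(inject_invalid_days(daily, "malfunction", 3, seed = 1),
                   inject_invalid_days(daily, "malfunction", 3, seed = 1))
  expect_error(inject_invalid_days(daily[0, ], "malfunction"), "empty")
})

test_that("planted confounding structure drives downstream selection", {
  # age shifts the linear main coefficient >= 10%; all else is clean
  p <- cohort_params(
    n_control = 300, n_intervention = 150,
    confounder_strengths = c(age = -1.5),
    covariate_shift = list(age_median = c(71, 62)),
    exclusions = c(delayed_fixation = 0L, early_discharge = 0L,
                   malfunction = 0L),
    n_excluded_per_group = c(0L, 0L), n_missing_pod1 = 0L,
    n_missing_recovery = 0L, seed = 13)
  tab <- analysis_table(simulate_cohort(p))
  sel <- select_confounders(tab, "active_min_pod1", "group",
                            model_type = "linear")
  expect_equal(sel$selected, "age")
  oracle <- cie_oracle(tab, "active_min_pod1", "group",
                       c("age", "sex", "bmi", "surgery", "asa_high"),
                       "linear")
  expect_identical(sel$selected, oracle)
})
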