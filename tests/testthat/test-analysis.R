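# Descriptives, regression fits, and change-in-estimate selection.

test_that("descriptives report medians, IQRs and group percentages", {
  cohort <- data.frame(group = rep(0:1, c(5, 3)),
                       age = c(1, 2, 3, 4, 5, 10, 20, 30),
                       sex = c(1, 1, 1, 0, 0, 1, 0, 0))
  d <- describe_cohort(cohort, continuous = "age", categorical = "sex")
  med <- d[d$variable == "age" & d$group == "0", ]
  expect_equal(med$median, 3)
  expect_equal(med$iqr, 2) # linear interpolation between order statistics
  males0 <- d[d$variable == "sex" & d$level == "0" & d$group == "0", ]
  expect_equal(males0$n, 2L)
  expect_equal(males0$pct, 40)
  # single patient: degenerate IQR of 0
  d1 <- describe_cohort(data.frame(group = 0, age = 50), continuous = "age",
                        categorical = character(0))
  expect_equal(d1$iqr, 0)
  expect_error(describe_cohort(data.frame(group = integer(0))), "empty")
})

test_that("a ward-cohort enrollment fixture reproduces printed percentages", {
  # 40 males among 64 control patients -> 62.5% (printed as 63)
  cohort <- data.frame(group = rep(0L, 64), sex = rep(c(0, 1), c(40, 24)))
  d <- describe_cohort(cohort, continuous = character(0), categorical = "sex")
  pct_male <- d$pct[d$level == "0"]
  expect_equal(pct_male, 100 * 40 / 64)
  expect_equal(floor(pct_male + 0.5), 63) # printed with half-up rounding
})

test_that("OLS matches the normal-equations oracle on random designs", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 40
    dat <- data.frame(group = rbinom(n, 1, 0.5), age = rnorm(n, 65, 9),
                      bmi = rnorm(n, 27, 4))
    dat$active_min_pod1 <- 70 + 25 * dat$group - 0.5 * dat$age + rnorm(n, 0, 20)
    fit <- fit_linear(dat, predictors = c("group", "age", "bmi"))
    X <- cbind(1, dat$group, dat$age, dat$bmi)
    oracle <- ols_oracle(X, dat$active_min_pod1)
    expect_equal(fit$terms$estimate, unname(oracle$beta), tolerance = 1e-8)
    expect_equal(fit$terms$se, unname(oracle$se), tolerance = 1e-8)
    expect_equal(fit$df_residual, oracle$df)
  }
})

test_that("a lone binary predictor recovers the group means exactly", {
  dat <- two_group_fixture()
  fit <- fit_linear(dat, predictors = "group")
  expect_equal(fit$terms$estimate[fit$terms$term == "(Intercept)"], 70.89)
  expect_equal(fit$terms$estimate[fit$terms$term == "group"],
               102.99 - 70.89)
  expect_equal(fit$n_used, 84)
})

test_that("degenerate linear fits behave: constants, perfect fits, collinearity", {
  dat <- data.frame(group = rep(0:1, each = 10), age = rnorm(20, 60),
                    active_min_pod1 = 5)
  # perfect fits make summary.lm warn; that is exactly the case under test
  fit <- suppressWarnings(fit_linear(dat, predictors = "group"))
  expect_equal(fit$terms$estimate[fit$terms$term == "group"], 0)

  exact <- data.frame(age = 1:10, active_min_pod1 = 2 * (1:10))
  fe <- suppressWarnings(fit_linear(exact, predictors = "age"))
  expect_equal(fe$terms$estimate[fe$terms$term == "age"], 2)
  expect_equal(fe$terms$se[fe$terms$term == "age"], 0, tolerance = 1e-12)

  dat$age2 <- 2 * dat$age
  expect_error(fit_linear(dat, predictors = c("age", "age2")),
               "collinear.*age2")
  expect_error(fit_linear(dat[1:2, ], predictors = c("group", "age")),
               "complete cases")
})

test_that("logistic fits match the 2x2 closed form and a likelihood grid", {
  # control: 10/30 recovered; intervention: 20/30 -> OR = (20*20)/(10*10) = 4
  dat <- data.frame(group = rep(0:1, each = 30),
                    recovered_on_pod1 = c(rep(1:0, c(10, 20)),
                                          rep(1:0, c(20, 10))))
  fit <- fit_logistic(dat, predictors = "group")
  b <- fit$terms[fit$terms$term == "group", ]
  expect_equal(b$estimate, log(4), tolerance = 1e-6)
  expect_equal(b$odds_ratio, 4, tolerance = 1e-6)
  expect_equal(b$or_ci_lower, exp(b$estimate - qnorm(0.975) * b$se),
               tolerance = 1e-10)

  # balanced, outcome independent of predictor -> B ~= 0
  null <- data.frame(group = rep(0:1, each = 20),
                     recovered_on_pod1 = rep(c(0, 1), 20))
  fn <- fit_logistic(null, predictors = "group")
  expect_equal(fn$terms$estimate[fn$terms$term == "group"], 0,
               tolerance = 1e-8)

  # 20-patient fixture vs nested-grid likelihood maximization
  set.seed(7)
  small <- data.frame(group = rep(0:1, each = 10),
                      recovered_on_pod1 = c(rbinom(10, 1, 0.3),
                                            rbinom(10, 1, 0.7)))
  fs <- fit_logistic(small, predictors = "group")
  oracle <- logistic_grid_oracle(small$group, small$recovered_on_pod1)
  expect_equal(fs$terms$estimate, oracle, tolerance = 1e-3)
})

test_that("separation and single-class outcomes are refused", {
  sep <- data.frame(group = rep(0:1, each = 15),
                    recovered_on_pod1 = rep(0:1, each = 15))
  expect_error(fit_logistic(sep, predictors = "group"), "separation")
  onecls <- data.frame(group = rep(0:1, each = 15), recovered_on_pod1 = 1)
  expect_error(fit_logistic(onecls, predictors = "group"), "single-class")
  expect_error(fit_logistic(data.frame(group = 0:1,
                                       recovered_on_pod1 = c(0.2, 0.8)),
                            predictors = "group"), "0/1")
})

test_that("t and z interval machinery matches closed forms", {
  ci <- confint_from_summary(10, 2, df = 30)
  expect_equal(unname(ci[, "lower"]), 10 - qt(0.975, 30) * 2)
  z <- confint_from_summary(1, 0.5, df = Inf)
  expect_equal(unname(z[, "upper"]), 1 + qnorm(0.975) * 0.5)
})

test_that("selection returns the crude model when nothing reaches 10%", {
  set.seed(31)
  n <- 300
  dat <- data.frame(group = rbinom(n, 1, 0.4), age = rnorm(n, 65, 9),
                    sex = rbinom(n, 1, 0.5))
  dat$active_min_pod1 <- 70 + 30 * dat$group + rnorm(n, 0, 30)
  sel <- select_confounders(dat, "active_min_pod1", "group",
                            candidates = c("age", "sex"),
                            model_type = "linear")
  expect_length(sel$selected, 0)
  expect_equal(sel$final$terms, sel$crude$terms)
  expect_true(all(!sel$trace$included))
})

test_that("a planted confounder is selected and the procedure then stops", {
  set.seed(32)
  n <- 400
  grp <- rbinom(n, 1, 0.35)
  age <- rnorm(n, 70 - 8 * grp, 7) # strongly group-associated
  dat <- data.frame(group = grp, age = age, sex = rbinom(n, 1, 0.5),
                    bmi = rnorm(n, 27, 4))
  dat$active_min_pod1 <- 160 + 30 * grp - 1.5 * age + rnorm(n, 0, 35)
  sel <- select_confounders(dat, "active_min_pod1", "group",
                            candidates = c("age", "sex", "bmi"),
                            model_type = "linear")
  expect_equal(sel$selected, "age")
  expect_true(all(sel$trace$pct_change[sel$trace$included] >= 10))
  # deterministic: same cohort, same trace
  sel2 <- select_confounders(dat, "active_min_pod1", "group",
                             candidates = c("age", "sex", "bmi"),
                             model_type = "linear")
  expect_identical(sel$trace, sel2$trace)
})

test_that("crude-reference mode and a zero crude coefficient are handled", {
  set.seed(33)
  dat <- random_small_cohort(80)
  sel <- select_confounders(dat, "active_min_pod1", "group",
                            candidates = c("age", "sex"),
                            model_type = "linear", reference = "crude")
  expect_true(all(sel$trace$reference_coef ==
                    sel$crude$terms$estimate[sel$crude$terms$term == "group"]))

  zero <- data.frame(group = rep(0:1, each = 4), age = rnorm(8),
                     active_min_pod1 = rep(c(1, 2, 3, 4), 2))
  expect_error(select_confounders(zero, "active_min_pod1", "group",
                                  candidates = "age", model_type = "linear"),
               "exactly 0")
})

test_that("selection agrees with a brute-force re-execution on random cohorts", {
  set.seed(34)
  cands <- c("age", "sex", "bmi", "asa_high")
  for (rep in 1:25) {
    dat <- random_small_cohort(60)
    sel <- select_confounders(dat, "active_min_pod1", "group", cands,
                              model_type = "linear")
    oracle <- cie_oracle(dat, "active_min_pod1", "group", cands, "linear")
    expect_identical(sel$selected, oracle)
  }
})
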