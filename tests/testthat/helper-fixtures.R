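# Shared fixtures and independent oracles for the test suite.

t0 <- function(h = 8) as.POSIXct(sprintf("2019-03-12 %02d:00:00", h), tz = "UTC")

# A single-posture schedule starting on a whole minute.
one_bout <- function(posture, duration_s, start = t0()) {
  posture_schedule(start, duration_s, posture)
}

# A mixed ward-style schedule with known per-posture seconds.
mixed_schedule <- function(start = t0()) {
  posture_schedule(
    start + c(0, 600, 780, 900, 1500, 1620, 3420),
    c(600, 180, 120, 600, 120, 1800, 300),
    c("lying", "standing", "walking", "sitting", "walking", "lying",
      "standing"))
}

# Outcome data with exact group means, reconstructing a published crude
# two-group comparison.
two_group_fixture <- function(n0 = 61, n1 = 23, m0 = 70.89, m1 = 102.99,
                              spread = 25) {
  dev0 <- seq(-spread, spread, length.out = n0)
  dev1 <- seq(-spread, spread, length.out = n1)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n0 + n1)),
    group = rep(c(0L, 1L), c(n0, n1)),
    active_min_pod1 = c(m0 + dev0 - mean(dev0), m1 + dev1 - mean(dev1)))
}

# --- independent oracles ---

# OLS via the normal equations, independent of lm().
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(beta = drop(beta), se = se, df = df)
}

# Logistic log-likelihood, for brute-force grid maximization.
logistic_loglik <- function(b, X, y) {
  eta <- drop(X %*% b)
  sum(y * eta - log1p(exp(eta)))
}

# Nested grid search over (intercept, slope); independent of glm().
logistic_grid_oracle <- function(x, y, lim = 6, levels = 6, grid_n = 41) {
  X <- cbind(1, x)
  center <- c(0, 0); width <- lim
  for (l in seq_len(levels)) {
    b0 <- seq(center[1] - width, center[1] + width, length.out = grid_n)
    b1 <- seq(center[2] - width, center[2] + width, length.out = grid_n)
    ll <- outer(b0, b1, Vectorize(function(a, b)
      logistic_loglik(c(a, b), X, y)))
    best <- arrayInd(which.max(ll), dim(ll))
    center <- c(b0[best[1]], b1[best[2]])
    width <- width * 2 / (grid_n - 1) * 2
  }
  center
}

# Step-by-step brute-force re-execution of the change-in-estimate
# procedure, written directly against lm()/glm() with no shared code.
cie_oracle <- function(data, outcome, main, candidates, model_type,
                       threshold = 10) {
  data <- data[complete.cases(data[c(outcome, main, candidates)]), ]
  coef_main <- function(preds) {
    f <- stats::reformulate(preds, outcome)
    fit <- if (model_type == "linear") lm(f, data = data) else
      glm(f, data = data, family = binomial())
    unname(coef(fit)[grep(paste0("^", main), names(coef(fit)))[1]])
  }
  selected <- character(0)
  b_cur <- coef_main(main)
  repeat {
    rem <- setdiff(candidates, selected)
    if (!length(rem)) break
    pct <- sapply(rem, function(cand)
      abs(coef_main(c(main, selected, cand)) - b_cur) / abs(b_cur) * 100)
    if (max(pct) < threshold) break
    pick <- rem[which.max(pct)]
    selected <- c(selected, pick)
    b_cur <- coef_main(c(main, selected))
  }
  selected
}

# Random small cohort used for selection-procedure stress tests.
random_small_cohort <- function(n = 60) {
  grp <- rbinom(n, 1, 0.4)
  age <- rnorm(n, 65 + 4 * grp, 8)
  sex <- rbinom(n, 1, 0.5)
  bmi <- rnorm(n, 27, 4)
  asa <- rbinom(n, 1, plogis(-1 + 0.8 * grp))
  y <- 60 + rnorm(1, 20, 10) * grp + rnorm(1, 0, 1.2) * age +
    rnorm(1, 0, 8) * sex + rnorm(1, 0, 2) * bmi + rnorm(1, 0, 15) * asa +
    rnorm(n, 0, 30)
  data.frame(group = grp, age = age, sex = sex, bmi = bmi, asa_high = asa,
             active_min_pod1 = y,
             recovered_on_pod1 = rbinom(n, 1, plogis(-0.3 + 0.9 * grp +
                                                       0.6 * asa)))
}
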