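# Cohort statistics: descriptives, linear and logistic regression fits in
# the study's reporting layout, and the iterative >= 10% change-in-estimate
# confounder-selection procedure.

#' t- or z-based confidence bounds from an estimate and standard error
#'
#' Linear-model intervals use the t distribution with the residual degrees
#' of freedom; logistic (Wald) intervals use the normal (\code{df = Inf}).
#'
#' @param estimate,se Coefficient and standard error.
#' @param df Residual degrees of freedom, \code{Inf} for a z interval.
#' @param level Confidence level (default 0.95).
#' @return A matrix with columns \code{lower}, \code{upper}.
#' @export
confint_from_summary <- function(estimate, se, df = Inf, level = 0.95) {
  crit <- if (is.finite(df)) qt(1 - (1 - level) / 2, df) else
    qnorm(1 - (1 - level) / 2)
  cbind(lower = estimate - crit * se, upper = estimate + crit * se)
}

#' Descriptive statistics per group
#'
#' Median and interquartile range for continuous variables (quartiles by
#' linear interpolation between order statistics), count and percent for
#' categorical/binary variables, computed within each level of the grouping
#' variable.
#'
#' @param cohort Patient data.frame.
#' @param group Name of the grouping column.
#' @param continuous,categorical Character vectors of column names; by
#'   default every numeric column with more than two distinct values is
#'   treated as continuous and the rest as categorical.
#' @return A long data.frame: \code{variable}, \code{level}, \code{group},
#'   \code{stat} (\code{"median (IQR)"} or \code{"n (%)"}), \code{median},
#'   \code{iqr}, \code{n}, \code{pct}.
#' @export
describe_cohort <- function(cohort, group = "group",
                            continuous = NULL, categorical = NULL) {
  if (!nrow(cohort)) stop_input("input error: empty cohort")
  assert_columns(cohort, group, "cohort")
  vars <- setdiff(names(cohort), c(group, "patient_id"))
  if (is.null(continuous)) {
    continuous <- vars[vapply(cohort[vars], function(v)
      is.numeric(v) && length(unique(v[!is.na(v)])) > 2, logical(1))]
  }
  if (is.null(categorical)) categorical <- setdiff(vars, continuous)

  rows <- list()
  for (g in sort(unique(cohort[[group]]))) {
    sub <- cohort[cohort[[group]] == g, , drop = FALSE]
    for (v in continuous) {
      x <- sub[[v]][!is.na(sub[[v]])]
      q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, group = as.character(g),
        stat = "median (IQR)", median = q[2], iqr = q[3] - q[1],
        n = NA_integer_, pct = NA_real_, stringsAsFactors = FALSE)
    }
    for (v in categorical) {
      x <- sub[[v]][!is.na(sub[[v]])]
      for (lev in sort(unique(as.character(cohort[[v]])))) {
        cnt <- sum(as.character(x) == lev)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev, group = as.character(g),
          stat = "n (%)", median = NA_real_, iqr = NA_real_,
          n = cnt, pct = 100 * cnt / length(x), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shared: assemble the reporting table for a fitted model.
fit_table <- function(fit, model_type) {
  s <- summary(fit)$coefficients
  est <- s[, 1L]; se <- s[, 2L]
  if (model_type == "linear") {
    dfres <- fit$df.residual
    ci <- confint_from_summary(est, se, df = dfres)
    p <- 2 * pt(-abs(est / se), dfres)
    data.frame(term = rownames(s), estimate = est, se = se, p_value = p,
               ci_lower = ci[, "lower"], ci_upper = ci[, "upper"],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    ci <- confint_from_summary(est, se, df = Inf)
    p <- 2 * pnorm(-abs(est / se))
    data.frame(term = rownames(s), estimate = est, se = se, p_value = p,
               ci_lower = ci[, "lower"], ci_upper = ci[, "upper"],
               odds_ratio = exp(est),
               or_ci_lower = exp(ci[, "lower"]),
               or_ci_upper = exp(ci[, "upper"]),
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

new_activity_fit <- function(fit, model_type, outcome, predictors) {
  structure(list(model_type = model_type, outcome = outcome,
                 predictors = predictors, terms = fit_table(fit, model_type),
                 n_used = length(fit$residuals),
                 df_residual = fit$df.residual, fit = fit),
            class = "activity_fit")
}

check_design_rank <- function(data, predictors, outcome) {
  form <- stats::reformulate(predictors, response = outcome)
  mm <- model.matrix(form, data)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop_input("singularity error: collinear term(s): ",
               paste(dropped, collapse = ", "))
  }
  form
}

#' Linear regression in the study's reporting layout
#'
#' Ordinary least squares for a continuous outcome (the POD1 active
#' minutes), reported as the study's tables do: coefficient B, standard
#' error, two-sided t-test p-value and the 95% CI
#' \eqn{B \pm t_{0.975, n-p-1} \cdot SE}. Complete-case: rows with a missing
#' outcome or predictor are dropped (missing values are never imputed).
#'
#' @param cohort Patient data.frame.
#' @param outcome Name of the outcome column (default
#'   \code{"active_min_pod1"}).
#' @param predictors Character vector of predictor column names.
#' @return An object of class \code{activity_fit}: list with
#'   \code{model_type}, \code{terms} (the reporting table), \code{n_used},
#'   \code{df_residual} and the underlying \code{lm} fit.
#' @export
fit_linear <- function(cohort, outcome = "active_min_pod1", predictors) {
  assert_columns(cohort, c(outcome, predictors), "cohort")
  use <- cohort[complete.cases(cohort[c(outcome, predictors)]), , drop = FALSE]
  if (nrow(use) < length(predictors) + 2) {
    stop_input("input error: need at least p + 2 complete cases")
  }
  form <- check_design_rank(use, predictors, outcome)
  new_activity_fit(lm(form, data = use), "linear", outcome, predictors)
}

#' Logistic regression in the study's reporting layout
#'
#' Maximum-likelihood logistic regression for a binary outcome (functional
#' recovery on POD1), with Wald standard errors, odds ratios
#' \eqn{e^B} and Wald CIs \eqn{e^{B \pm 1.96 \cdot SE}}. Complete-case.
#' Quasi- or complete separation is detected (divergent coefficients or
#' fitted probabilities at the 0/1 boundary) and raised as an error rather
#' than returning meaningless estimates.
#'
#' @param cohort Patient data.frame.
#' @param outcome Name of the binary (0/1) outcome column (default
#'   \code{"recovered_on_pod1"}).
#' @param predictors Character vector of predictor column names.
#' @return An object of class \code{activity_fit}; its \code{terms} table
#'   additionally carries \code{odds_ratio}, \code{or_ci_lower},
#'   \code{or_ci_upper}.
#' @export
fit_logistic <- function(cohort, outcome = "recovered_on_pod1", predictors) {
  assert_columns(cohort, c(outcome, predictors), "cohort")
  use <- cohort[complete.cases(cohort[c(outcome, predictors)]), , drop = FALSE]
  y <- use[[outcome]]
  if (!all(y %in% c(0, 1))) {
    stop_input("input error: outcome must be coded 0/1")
  }
  if (length(unique(y)) < 2) {
    stop_input("single-class error: both outcome classes must be present")
  }
  if (nrow(use) < length(predictors) + 2) {
    stop_input("input error: need at least p + 2 complete cases")
  }
  form <- check_design_rank(use, predictors, outcome)
  fit <- glm(form, data = use, family = binomial(),
             control = list(epsilon = 1e-8, maxit = 100))
  eta <- abs(fit$linear.predictors)
  if (!fit$converged || any(abs(coef(fit)) > 15) || any(eta > 15)) {
    stop_input("non-convergence error: complete or quasi-complete ",
               "separation detected; no estimates returned")
  }
  new_activity_fit(fit, "logistic", outcome, predictors)
}

#' @export
print.activity_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s regression of %s (n = %d complete cases)\n",
              if (x$model_type == "linear") "Linear" else "Logistic",
              x$outcome, x$n_used))
  tab <- x$terms
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Iterative change-in-estimate confounder selection
#'
#' Starting from the crude model (outcome ~ main determinant), every
#' remaining candidate is added one at a time to the current working model
#' and the percent change in the main determinant's coefficient is computed,
#' \eqn{|B_{with} - B_{current}| / |B_{current}| \times 100}. The candidate
#' producing the largest change of at least \code{threshold} percent is
#' admitted, and the process repeats against the enlarged model until no
#' candidate reaches the threshold. Ties are broken by the order of
#' \code{candidates}. With \code{reference = "crude"} the percent change is
#' always computed against the crude coefficient instead of the evolving
#' working model.
#'
#' @param cohort Patient data.frame. Rows incomplete on the outcome, main
#'   determinant or any candidate are dropped once up front so all models in
#'   the procedure are fitted to the same cases.
#' @param outcome Outcome column name.
#' @param main Name of the main determinant (binary group indicator).
#' @param candidates Character vector of candidate confounders, in
#'   tie-breaking order.
#' @param model_type \code{"linear"} or \code{"logistic"}.
#' @param threshold Percent change for admission (default 10).
#' @param reference \code{"current"} (default) or \code{"crude"}.
#' @return A list of class \code{cie_selection}: \code{final} (the final
#'   \code{activity_fit}), \code{crude} (the crude fit), \code{selected}
#'   (character vector in inclusion order) and \code{trace}, a data.frame
#'   with one row per candidate evaluation: \code{step},
#'   \code{candidate}, \code{reference_coef}, \code{adjusted_coef},
#'   \code{pct_change}, \code{included}.
#' @export
select_confounders <- function(cohort, outcome, main,
                               candidates = c("age", "sex", "bmi",
                                              "surgery", "asa_high"),
                               model_type = c("linear", "logistic"),
                               threshold = 10,
                               reference = c("current", "crude")) {
  model_type <- match.arg(model_type)
  reference <- match.arg(reference)
  assert_columns(cohort, c(outcome, main, candidates), "cohort")
  fitter <- if (model_type == "linear") fit_linear else fit_logistic
  use <- cohort[complete.cases(cohort[c(outcome, main, candidates)]), ,
                drop = FALSE]

  main_coef <- function(f) {
    tab <- f$terms
    hit <- grep(paste0("^", main), tab$term)
    tab$estimate[hit[1L]]
  }

  crude <- fitter(use, outcome, main)
  b_crude <- main_coef(crude)
  # an exactly-null crude association leaves the percent change undefined;
  # the tolerance only absorbs floating-point zero (e.g. identical group
  # means), far below any real coefficient
  zero_tol <- 1e-8 * max(sd(use[[outcome]]), .Machine$double.eps)
  if (abs(b_crude) < zero_tol) {
    stop_input("selection error: crude coefficient of `", main,
               "` is exactly 0; percent change is undefined")
  }

  selected <- character(0)
  current <- crude
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    b_ref <- if (reference == "crude") b_crude else main_coef(current)
    changes <- vapply(remaining, function(cand) {
      f <- fitter(use, outcome, c(main, selected, cand))
      main_coef(f)
    }, numeric(1))
    pct <- abs(changes - b_ref) / abs(b_ref) * 100
    eligible <- pct >= threshold
    pick <- if (any(eligible)) remaining[which.max(pct)] else NA_character_
    trace[[step]] <- data.frame(
      step = step, candidate = remaining,
      reference_coef = b_ref, adjusted_coef = unname(changes),
      pct_change = unname(pct),
      included = !is.na(pick) & remaining == pick,
      stringsAsFactors = FALSE)
    if (is.na(pick)) break
    selected <- c(selected, pick)
    current <- fitter(use, outcome, c(main, selected))
  }
  structure(list(final = current, crude = crude, selected = selected,
                 trace = do.call(rbind, trace), main = main,
                 threshold = threshold, reference = reference),
            class = "cie_selection")
}

#' @export
print.cie_selection <- function(x, ...) {
  cat(sprintf("Change-in-estimate selection (main determinant: %s, threshold %.0f%%)\n",
              x$main, x$threshold))
  cat("Selected confounders:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n\n")
  print(x$final)
  invisible(x)
}
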