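# Seeded cohort generator: covariates, POD1 outcomes, daily summaries and
# mILAS logs with the statistical structure of an orthopedic arthroplasty
# ward study (two-group quasi-experimental design, 2:1 control:intervention).

#' Parameters of the synthetic cohort generator
#'
#' The defaults describe the emulated study conditions: 64 control and 33
#' intervention patients enrolled; covariate marginals matching a typical
#' arthroplasty ward cohort (median age about 66, median BMI about 27.7,
#' mostly ASA 1-2, TKA majority in the control arm); a control-group mean of
#' about 70.9 minutes standing and walking on POD1 with a true group effect
#' of 32.1 minutes and residual SD 46.7; a recovery endpoint drawn from a
#' logistic model with control log-odds -0.31 and group log-odds ratio 1.0.
#' Exclusion structure: 9 enrolled patients (3 control, 6 intervention)
#' end with zero valid measurement days (reason codes delayed_fixation x5,
#' early_discharge x1, malfunction x3), and 4 further intervention patients
#' have no valid POD1 day but a valid POD2 day, plus 4 analyzed patients
#' with no mILAS log (missing recovery endpoint).
#'
#' @param n_control,n_intervention Enrolled patients per arm.
#' @param baseline_min Control-group mean POD1 active minutes (before
#'   confounder terms).
#' @param effect_min True group difference in POD1 active minutes.
#' @param outcome_sd_min Residual SD of POD1 active minutes.
#' @param confounder_strengths Named numeric vector: linear effect of each
#'   covariate on the outcome (age and bmi are centered first; binary
#'   covariates enter as 0/1). Default: age -0.81 min/year, others 0.
#' @param covariate_shift Named list overriding per-arm covariate
#'   distributions; see Details in the package vignette. Elements:
#'   \code{age_median} (length 2: control, intervention), \code{age_iqr},
#'   \code{bmi_median}, \code{bmi_iqr}, \code{p_female}, \code{p_tka},
#'   \code{p_asa3}.
#' @param recovery_model Named numeric vector of logistic coefficients for
#'   the recovery endpoint: \code{intercept}, \code{group}, optionally
#'   \code{asa_high}, \code{age} (age centered).
#' @param exclusions Named integer vector of enrolled patients with zero
#'   valid days, by reason: \code{delayed_fixation}, \code{early_discharge},
#'   \code{malfunction}.
#' @param n_excluded_per_group Length-2 integer: how many of the excluded
#'   patients come from the control / intervention arm.
#' @param n_missing_pod1 Analyzed (intervention-arm) patients whose POD1 day
#'   is invalid but who keep a valid POD2 day.
#' @param n_missing_recovery Analyzed patients with no mILAS log.
#' @param pod1_group_means Optional length-2 numeric: after simulation,
#'   recenter the POD1 active minutes of patients with a valid POD1 day so
#'   the two group means equal these values exactly (useful for
#'   reconstructing a published crude comparison).
#' @param surgery_date Date of surgery (all patients operated the same day
#'   in the fixture; POD indexing is per patient anyway).
#' @param seed Integer seed; identical seed gives an identical cohort.
#' @return A list of class \code{cohort_params}.
#' @export
cohort_params <- function(n_control = 64, n_intervention = 33,
                          baseline_min = 70.89, effect_min = 32.10,
                          outcome_sd_min = 46.7,
                          confounder_strengths = c(age = -0.81),
                          covariate_shift = list(),
                          recovery_model = c(intercept = -0.31, group = 1.00),
                          exclusions = c(delayed_fixation = 5L,
                                         early_discharge = 1L,
                                         malfunction = 3L),
                          n_excluded_per_group = c(3L, 6L),
                          n_missing_pod1 = 4L,
                          n_missing_recovery = 4L,
                          pod1_group_means = NULL,
                          surgery_date = as.Date("2019-03-11"),
                          seed = 1L) {
  if (n_control < 0 || n_intervention < 0) stop_input("counts must be >= 0")
  assert_positive(outcome_sd_min, "outcome_sd_min", strict = FALSE)
  if (sum(n_excluded_per_group) != sum(exclusions)) {
    stop_input("n_excluded_per_group must sum to the total exclusions")
  }
  cov_defaults <- list(
    age_median = c(66.60, 65.10), age_iqr = c(10.62, 13.72),
    bmi_median = c(27.73, 27.47), bmi_iqr = c(4.72, 4.70),
    p_female = c(0.38, 0.55), p_tka = c(0.77, 0.45),
    p_asa3 = c(0.17, 0.21))
  unknown <- setdiff(names(covariate_shift), names(cov_defaults))
  if (length(unknown)) {
    stop_input("unknown covariate_shift element(s): ",
               paste(unknown, collapse = ", "))
  }
  structure(list(
    n_control = n_control, n_intervention = n_intervention,
    baseline_min = baseline_min, effect_min = effect_min,
    outcome_sd_min = outcome_sd_min,
    confounder_strengths = confounder_strengths,
    covariates = modifyList(cov_defaults, covariate_shift),
    recovery_model = recovery_model,
    exclusions = exclusions, n_excluded_per_group = n_excluded_per_group,
    n_missing_pod1 = n_missing_pod1, n_missing_recovery = n_missing_recovery,
    pod1_group_means = pod1_group_means,
    surgery_date = as.Date(surgery_date), seed = as.integer(seed)),
    class = "cohort_params")
}

# Log-normal draw matched to a target median and IQR.
rlnorm_median_iqr <- function(n, med, iqr) {
  mu <- log(med)
  # IQR of lognormal = med * (exp(q * s) - exp(-q * s)), q = qnorm(.75)
  q <- qnorm(0.75)
  f <- function(s) med * (exp(q * s) - exp(-q * s)) - iqr
  s <- stats::uniroot(f, c(1e-6, 2))$root
  rlnorm(n, mu, s)
}

#' Simulate a two-arm ward cohort
#'
#' Draws covariates per arm, generates the latent POD1 active minutes from
#' a linear model (baseline + group effect + confounder terms + Gaussian
#' noise), the recovery endpoint from a logistic model, and materializes
#' per-patient daily summaries (POD0 partial surgery-day wear, a full POD1
#' day, and a POD2 day for the not-yet-discharged subset) plus mILAS
#' assessment logs consistent with the drawn recovery endpoint. The
#' exclusion structure (patients with zero valid days, invalid POD1,
#' missing mILAS logs) is applied deterministically to seeded random
#' patients, so accounting totals are reproducible.
#'
#' @param params A \code{\link{cohort_params}} object.
#' @return A list of class \code{ward_cohort} with elements
#'   \code{patients} (covariate table with exclusion codes),
#'   \code{daily} (per-patient daily summaries),
#'   \code{milas} (assessment logs), and \code{params}.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) stop_input("parameter error: need cohort_params")
  set.seed(params$seed)
  n <- params$n_control + params$n_intervention
  grp <- rep(c(0L, 1L), c(params$n_control, params$n_intervention))
  arm <- grp + 1L
  cv <- params$covariates

  age <- numeric(n); bmi <- numeric(n)
  for (a in 1:2) {
    idx <- arm == a
    age[idx] <- rlnorm_median_iqr(sum(idx), cv$age_median[a], cv$age_iqr[a])
    bmi[idx] <- rlnorm_median_iqr(sum(idx), cv$bmi_median[a], cv$bmi_iqr[a])
  }
  sex <- rbinom(n, 1, cv$p_female[arm])        # 1 = female
  surgery <- ifelse(rbinom(n, 1, cv$p_tka[arm]) == 1, "TKA", "THA")
  asa_high <- rbinom(n, 1, cv$p_asa3[arm])     # 1 = ASA class 3
  los_days <- pmax(2L, 2L + stats::rpois(n, 1.1))

  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    group = grp, age = age, sex = sex, bmi = bmi, surgery = surgery,
    asa_high = asa_high, los_days = los_days, stringsAsFactors = FALSE)

  # latent POD1 active minutes
  cs <- params$confounder_strengths
  lin <- params$baseline_min + params$effect_min * grp
  for (v in names(cs)) {
    x <- patients[[v]]
    if (v %in% c("age", "bmi")) x <- x - mean(x)
    if (v == "surgery") x <- as.integer(patients$surgery == "TKA")
    lin <- lin + cs[[v]] * x
  }
  active_latent <- pmax(0, lin + rnorm(n, sd = params$outcome_sd_min))

  # recovery endpoint from the logistic model
  rm_ <- params$recovery_model
  eta <- rm_[["intercept"]] + rm_[["group"]] * grp
  if ("asa_high" %in% names(rm_)) eta <- eta + rm_[["asa_high"]] * asa_high
  if ("age" %in% names(rm_)) eta <- eta + rm_[["age"]] * (age - mean(age))
  recovered_latent <- rbinom(n, 1, plogis(eta))

  # exclusion structure: zero-valid-day patients per arm, with reason codes
  excl_reasons <- rep(names(params$exclusions), params$exclusions)
  ctrl_ids <- which(grp == 0L); int_ids <- which(grp == 1L)
  excl_idx <- c(resample(ctrl_ids, params$n_excluded_per_group[1L]),
                resample(int_ids, params$n_excluded_per_group[2L]))
  patients$excluded_reason <- NA_character_
  patients$excluded_reason[excl_idx] <- excl_reasons

  analyzed_int <- setdiff(int_ids, excl_idx)
  miss_pod1_idx <- resample(analyzed_int, min(params$n_missing_pod1,
                                             length(analyzed_int)))
  analyzed_all <- setdiff(seq_len(n), excl_idx)
  rec_pool <- setdiff(analyzed_all, miss_pod1_idx)
  miss_rec_idx <- resample(rec_pool,
                           min(params$n_missing_recovery, length(rec_pool)))

  # daily summaries: POD0 (partial surgery-day wear), POD1 (full), POD2 for
  # patients still in hospital (los >= 4 counted from surgery day = day 1)
  sdate <- params$surgery_date
  daily <- list()
  pod1_noise <- runif(n, -0.4, 0.4) # small wear-time jitter, hours
  for (i in seq_len(n)) {
    reason <- patients$excluded_reason[i]
    rows <- list()
    if (is.na(reason) || reason == "malfunction") {
      # POD0: fixation during the first treatment session -> ~8-12 h wear
      rows$pod0 <- c(pod = 0, wear_h = 8 + 4 * runif(1), frac_active = 0.02)
      w1 <- 23.3 + pod1_noise[i]
      if (i %in% miss_pod1_idx) w1 <- 10 + 6 * runif(1) # device off too long
      rows$pod1 <- c(pod = 1, wear_h = w1, frac_active = NA)
      if (patients$los_days[i] >= 4 || i %in% miss_pod1_idx) {
        rows$pod2 <- c(pod = 2, wear_h = 22.5 + runif(1), frac_active = 0.08)
      }
      if (reason %in% "malfunction") {
        # device failed: every day is truncated below the validity threshold
        for (k in seq_along(rows)) rows[[k]]["wear_h"] <-
            min(rows[[k]]["wear_h"], 3 + 5 * runif(1))
      }
    } else if (reason == "delayed_fixation") {
      rows$pod1 <- c(pod = 1, wear_h = 6 + 8 * runif(1), frac_active = 0.05)
    } else { # early_discharge: home on POD1, only a short morning of data
      rows$pod0 <- c(pod = 0, wear_h = 9 + 3 * runif(1), frac_active = 0.02)
      rows$pod1 <- c(pod = 1, wear_h = 5 + 4 * runif(1), frac_active = 0.05)
    }
    m <- do.call(rbind, rows)
    d <- data.frame(patient_id = patients$patient_id[i],
                    date = sdate + m[, "pod"], pod = as.integer(m[, "pod"]),
                    wear_h = as.numeric(m[, "wear_h"]),
                    stringsAsFactors = FALSE)
    frac <- m[, "frac_active"]
    d$active_min <- ifelse(is.na(frac), active_latent[i],
                           frac * d$wear_h * 60)
    daily[[i]] <- d
  }
  daily <- do.call(rbind, daily)
  daily$valid <- daily$wear_h >= 20
  daily$active_min <- pmin(daily$active_min, daily$wear_h * 60)
  daily$sedentary_min <- daily$wear_h * 60 - daily$active_min
  daily <- daily[, c("patient_id", "date", "pod", "wear_h", "valid",
                     "active_min", "sedentary_min")]
  rownames(daily) <- NULL

  # optional exact recentering of the POD1 group means among valid POD1 days
  if (!is.null(params$pod1_group_means)) {
    v1 <- daily$pod == 1 & daily$valid
    for (a in 0:1) {
      ids <- patients$patient_id[grp == a]
      sel <- v1 & daily$patient_id %in% ids
      if (any(sel)) {
        daily$active_min[sel] <- daily$active_min[sel] -
          mean(daily$active_min[sel]) + params$pod1_group_means[a + 1L]
      }
    }
  }

  milas <- simulate_milas_logs(patients, recovered_latent, miss_rec_idx, sdate)

  structure(list(patients = patients, daily = daily, milas = milas,
                 params = params,
                 truth = list(active_min_pod1 = active_latent,
                              recovered_on_pod1 = recovered_latent)),
            class = "ward_cohort")
}

# mILAS trajectories consistent with the drawn recovery endpoint: totals
# decline from a high POD0 score; recovered patients reach 0 on POD1 (or
# already on POD0 in ~15% of cases), the rest stay positive through POD1.
simulate_milas_logs <- function(patients, recovered, missing_idx, sdate) {
  keep <- setdiff(seq_len(nrow(patients)), missing_idx)
  n_rows <- 2L * length(keep) # one assessment on POD0 and one on POD1
  pid <- character(n_rows); pod <- integer(n_rows)
  items_m <- matrix(0L, n_rows, 5L)
  stairs_flag <- logical(n_rows)
  r <- 0L
  for (i in keep) {
    needs_stairs <- runif(1) < 0.8
    zero_on_pod0 <- recovered[i] == 1 && runif(1) < 0.15
    day_totals <- if (recovered[i] == 1) {
      if (zero_on_pod0) c(0L, 0L) else c(sample(3:12, 1), 0L)
    } else {
      c(sample(8:20, 1), sample(1:6, 1))
    }
    for (d in 1:2) {
      r <- r + 1L
      pid[r] <- patients$patient_id[i]; pod[r] <- d - 1L
      stairs_flag[r] <- needs_stairs
      # split the day total over the items (walking hardest first; stairs
      # only when needed at home)
      pool <- day_totals[d]
      items <- integer(5)
      for (it in c(4L, 3L, 1L, 2L, if (needs_stairs) 5L)) {
        take <- min(pool, sample(0:6, 1, prob = 7:1))
        items[it] <- take
        pool <- pool - take
      }
      items[1L] <- items[1L] + min(pool, 6L - items[1L])
      items_m[r, ] <- items
    }
  }
  out <- data.frame(
    patient_id = pid,
    timestamp = as.POSIXct(sdate, tz = "UTC") + pod * 86400 + 10 * 3600,
    supine_to_sit = items_m[, 1L], sit_to_supine = items_m[, 2L],
    sit_to_stand = items_m[, 3L], walking = items_m[, 4L],
    stairs = items_m[, 5L], needs_stairs_at_home = stairs_flag,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Invalidate measurement days of randomly targeted patients
#'
#' Emulates the study's data-loss mechanisms. \code{"delayed_fixation"}
#' removes early coverage (the device was attached too late for any day to
#' reach the wear threshold); \code{"malfunction"} truncates every day's
#' wear. Either way the targeted patients end with zero valid measurement
#' days; all other patients' records are untouched.
#'
#' @param summaries Daily summaries (as from \code{\link{summarize_days}} or
#'   a \code{ward_cohort}'s \code{daily} element).
#' @param rule \code{"delayed_fixation"} or \code{"malfunction"}.
#' @param n_patients How many patients to affect (default 1).
#' @param seed Integer seed for the patient draw.
#' @param threshold_h Validity threshold used to recompute \code{valid}.
#' @return The summaries with affected patients' days set below the wear
#'   threshold and \code{valid} recomputed.
#' @export
inject_invalid_days <- function(summaries, rule = c("delayed_fixation",
                                                    "malfunction"),
                                n_patients = 1, seed = NULL,
                                threshold_h = 20) {
  assert_columns(summaries, c("patient_id", "wear_h", "valid"), "summaries")
  if (!nrow(summaries)) stop_input("input error: empty summaries")
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(summaries$patient_id)
  n_patients <- min(n_patients, length(ids))
  if (n_patients == 0) return(summaries)
  target <- resample(ids, n_patients)
  hit <- summaries$patient_id %in% target
  new_wear <- if (rule == "delayed_fixation") {
    pmin(summaries$wear_h[hit], runif(sum(hit), 4, threshold_h - 1))
  } else {
    pmin(summaries$wear_h[hit], runif(sum(hit), 1, threshold_h - 2))
  }
  scale <- ifelse(summaries$wear_h[hit] > 0, new_wear / summaries$wear_h[hit], 0)
  summaries$active_min[hit] <- summaries$active_min[hit] * scale
  if ("sedentary_min" %in% names(summaries)) {
    summaries$sedentary_min[hit] <- summaries$sedentary_min[hit] * scale
  }
  summaries$wear_h[hit] <- new_wear
  summaries$valid <- summaries$wear_h >= threshold_h
  summaries
}

#' Assemble the analysis table of a simulated cohort
#'
#' Joins the covariate table with the POD1 active minutes selected from the
#' daily summaries (valid days only) and the recovery endpoint derived from
#' the mILAS logs. Excluded patients (zero valid days) are dropped; missing
#' POD1 or recovery values stay \code{NA}.
#'
#' @param cohort A \code{ward_cohort} from \code{\link{simulate_cohort}}.
#' @return A data.frame, one row per analyzed patient: covariates plus
#'   \code{active_min_pod1} and \code{recovered_on_pod1}.
#' @export
analysis_table <- function(cohort) {
  if (!inherits(cohort, "ward_cohort")) stop_input("need a ward_cohort")
  pats <- cohort$patients
  valid_ids <- unique(cohort$daily$patient_id[cohort$daily$valid])
  analyzed <- pats[pats$patient_id %in% valid_ids, , drop = FALSE]
  pod1 <- select_analysis_days(
    cohort$daily[cohort$daily$patient_id %in% valid_ids, , drop = FALSE],
    pod = 1)
  analyzed$active_min_pod1 <- pod1$active_min[
    match(analyzed$patient_id, pod1$patient_id)]
  rec <- recovery_endpoint(cohort$milas, cohort$params$surgery_date)
  analyzed$recovered_on_pod1 <- rec$recovered_on_pod1[
    match(analyzed$patient_id, rec$patient_id)]
  rownames(analyzed) <- NULL
  analyzed
}
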