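#' Generate a synthetic perioperative cohort
#'
#' Draws a cohort of surgical patients with the statistical structure a
#' propensity-matched hypotension analysis assumes: realistic covariate
#' marginals, treatment assignment confounded by emergency status, epidural
#' use, case duration and physical-status class, per-case arterial-pressure
#' traces with stochastic hypotensive episodes, an alarm/index channel in
#' the treated arm, and postoperative creatinine trajectories whose
#' acute-kidney-injury risk increases with hypotension burden.
#'
#' Treatment ("HPI") is drawn Bernoulli on the logistic scale from the
#' configured assignment coefficients, so with the defaults emergency cases
#' are predominantly control and long epidural cases predominantly treated.
#' In the treated arm, the episode rate and mean duration are scaled by
#' `treatment_effect_multiplier`, an index alarm is planted
#' `alarm_lead_s` seconds before each incipient episode, and each incipient
#' episode is independently averted (alarm without a pressure dip) with
#' probability `alarm_aversion_prob`.
#'
#' The generator is bit-reproducible: identical configurations (including
#' the seed) give identical cohorts and traces.
#'
#' @param config a [sim_config()].
#' @return list with components `cohort` (data.frame, one row per patient;
#'   booleans as 0/1 integers, categoricals as the literal level strings,
#'   postoperative creatinine encoded as `"hours:value;..."`) and `traces`
#'   (named list of [vital_trace()] objects, one per patient).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  cov <- sample_covariates(n)
  grp <- assign_treatment(cov, config$assignment_coefficients)
  if (sum(grp == "HPI") < 2 || sum(grp == "non-HPI") < 2)
    stop("degenerate cohort: assignment left a treatment arm (nearly) ",
         "empty; weaken assignment_coefficients or enlarge n_patients",
         call. = FALSE)
  cov$group <- grp

  traces <- vector("list", n)
  creat <- character(n)
  for (i in seq_len(n)) {
    treated <- grp[i] == "HPI"
    case <- simulate_case(
      duration_min = cov$duration_min[i],
      treated = treated, config = config,
      patient_id = cov$patient_id[i]
    )
    traces[[i]] <- case$trace
    twa65 <- twa_below(case$trace, 65)
    ser <- generate_creatinine_series(
      list(preop_creatinine = cov$preop_creatinine[i]), twa65, config)
    creat[i] <- encode_creatinine_series(ser)
  }
  names(traces) <- cov$patient_id
  cov$postop_creatinine_series <- creat
  list(cohort = cov, traces = traces)
}

# covariate marginals loosely matching the demography of a perioperative
# registry of moderate/high-risk non-cardiac surgery (normal age, lognormal
# duration, class III-heavy physical status); exact families are a
# modelling choice, only summaries are emulated
sample_covariates <- function(n) {
  sex_male <- stats::rbinom(n, 1, 0.63)
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = round(clamp(stats::rnorm(n, 69, 10), 18, 95)),
    sex_male = sex_male,
    bsa = round(clamp(stats::rnorm(n, 1.92 + 0.12 * sex_male, 0.18),
                      1.3, 2.8), 2),
    bmi = round(clamp(stats::rnorm(n, 27.5, 4.5), 16, 55), 1),
    asa_class = sample(2:4, n, replace = TRUE, prob = c(0.28, 0.62, 0.10)),
    emergency = stats::rbinom(n, 1, 0.17),
    chf = stats::rbinom(n, 1, 0.08),
    copd = stats::rbinom(n, 1, 0.135),
    diabetes = stats::rbinom(n, 1, 0.21),
    hypertension = stats::rbinom(n, 1, 0.64),
    ace_inhibitor = stats::rbinom(n, 1, 0.245),
    beta_blocker = stats::rbinom(n, 1, 0.385),
    ccb = stats::rbinom(n, 1, 0.195),
    diuretic = stats::rbinom(n, 1, 0.22),
    at1_antagonist = stats::rbinom(n, 1, 0.235),
    preop_hb = round(clamp(stats::rnorm(n, 12.7, 2.1), 6, 18), 1),
    preop_creatinine = round(stats::rlnorm(n, log(0.95), 0.28), 2),
    surgical_approach = sample(
      c("laparoscopy", "laparotomy", "combined", "other"), n,
      replace = TRUE, prob = c(0.21, 0.44, 0.06, 0.29)),
    duration_min = round(clamp(30.5 + stats::rlnorm(n, log(170), 0.55),
                               31, 720)),
    epidural = stats::rbinom(n, 1, 0.46),
    map_induction = round(clamp(stats::rnorm(n, 95, 12), 60, 140)),
    hr_induction = round(clamp(stats::rnorm(n, 78, 13), 40, 140)),
    spo2_induction = round(clamp(stats::rnorm(n, 97, 1.6), 85, 100)),
    stringsAsFactors = FALSE
  )
}

# Bernoulli treatment assignment on the logistic scale; coefficient names
# other than "intercept" index covariate columns and multiply raw values
assign_treatment <- function(cov, coefficients) {
  lp <- rep(coefficients$intercept %||% 0, nrow(cov))
  for (nm in setdiff(names(coefficients), "intercept")) {
    if (!nm %in% names(cov))
      stop("assignment coefficient references unknown covariate: ", nm,
           call. = FALSE)
    lp <- lp + coefficients[[nm]] * as.numeric(cov[[nm]])
  }
  ifelse(stats::rbinom(nrow(cov), 1, expit(lp)) == 1, "HPI", "non-HPI")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one case: incipient episode process, aversion in the treated arm, the
# pressure trace and (treated only) the index channel
simulate_case <- function(duration_min, treated, config, patient_id) {
  mult <- if (treated) config$treatment_effect_multiplier else 1
  dur_s <- duration_min * 60
  rate <- config$episode_rate_per_hour * mult
  n_inc <- stats::rpois(1, rate * duration_min / 60)

  baseline <- clamp(stats::rnorm(1, config$map_baseline_mean,
                                 config$map_baseline_sd), 65, 95)

  episodes <- NULL
  alarms <- NULL
  if (n_inc > 0) {
    start_s <- sort(stats::runif(n_inc, 0, max(0, dur_s - 60)))
    depth <- clamp(stats::rgamma(n_inc, shape = 4,
                                 scale = config$episode_depth_mean / 4),
                   4, 45)
    len_s <- pmax(config$sample_interval_s,
                  stats::rgamma(n_inc, shape = 2,
                                scale = config$episode_duration_mean *
                                  60 * mult / 2))
    len_s <- pmin(len_s, dur_s - start_s)
    averted <- if (treated)
      stats::rbinom(n_inc, 1, config$alarm_aversion_prob) == 1
    else rep(FALSE, n_inc)
    episodes <- data.frame(start_s = start_s[!averted],
                           duration_s = len_s[!averted],
                           depth_mmHg = depth[!averted])
    alarms <- start_s   # every incipient episode leaves an alarm
  }

  trace <- generate_map_trace(
    duration_min, baseline, episodes,
    interval_s = config$sample_interval_s,
    noise_sd = config$map_noise_sd,
    drift_amplitude = config$drift_amplitude,
    patient_id = patient_id
  )

  if (treated) {
    trace$hpi_index <- index_channel(trace$t, alarms,
                                     config$alarm_lead_s,
                                     config$sample_interval_s)
    trace <- validate_vital_trace(trace)
  }
  list(trace = trace)
}

# 0-100 index series: low-level noise, raised to >= 85 in a 120-s hold
# window starting alarm_lead_s before each incipient episode onset
index_channel <- function(t, alarm_onsets, alarm_lead_s, interval_s,
                          hold_s = 120) {
  idx <- clamp(stats::rnorm(length(t), 30, 12), 0, 80)
  for (s in alarm_onsets) {
    a0 <- max(0, s - alarm_lead_s)
    hit <- t >= a0 & t <= a0 + hold_s
    idx[hit] <- clamp(stats::rnorm(sum(hit), 95, 3), 86, 100)
  }
  idx
}

#' Simulate a postoperative creatinine trajectory
#'
#' An AKI event is drawn with probability
#' `expit(logit(aki_base_prob) + aki_twa_slope * twa65)`. If AKI occurs,
#' the emitted series contains a value whose rise above baseline strictly
#' exceeds 0.3 mg/dL within 48 h (so the downstream classifier fires); if
#' not, every value stays strictly below both the 0.3 mg/dL delta and the
#' 1.5-fold ratio criterion. One value per 24 h for 7 days.
#'
#' @param record patient record (list or one-row data.frame) with a
#'   positive `preop_creatinine`.
#' @param twa65 the patient's TWA of hypotension below 65 mmHg, mmHg.
#' @param config a [sim_config()].
#' @return data.frame with columns `hours`, `creatinine`; attribute
#'   `aki_drawn` records the latent event indicator.
#' @export
generate_creatinine_series <- function(record, twa65, config) {
  b <- record$preop_creatinine
  stopifnot(is.numeric(b), b > 0, is.finite(twa65), twa65 >= 0)
  hours <- 24 * (1:7)
  p <- expit(logit(config$aki_base_prob) + config$aki_twa_slope * twa65)
  aki <- stats::rbinom(1, 1, p) == 1
  if (aki) {
    delta <- stats::runif(1, 0.35, 1.0)
    shape <- c(0.6, 1, 0.8, 0.6, 0.45, 0.35, 0.25)
    v <- b + delta * shape + stats::rnorm(7, 0, 0.02)
    v[2] <- max(v[2], b + 0.31)  # guarantee the 48-h delta criterion
  } else {
    cap <- min(0.25, 0.45 * b)
    v <- clamp(b + stats::rnorm(7, 0, 0.05), max(0.3, b - 0.25), b + cap)
  }
  out <- data.frame(hours = hours, creatinine = round(pmax(v, 0.1), 2))
  attr(out, "aki_drawn") <- aki
  out
}

# creatinine series <-> compact CSV-safe string ("24:0.92;48:1.31;...")
encode_creatinine_series <- function(series) {
  paste(sprintf("%g:%g", series$hours, series$creatinine), collapse = ";")
}

#' Decode a creatinine-series string from a cohort table
#'
#' @param x encoded string, `"hours:value;hours:value;..."`.
#' @return data.frame with columns `hours`, `creatinine`.
#' @export
decode_creatinine_series <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(hours = numeric(0), creatinine = numeric(0)))
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(hours = as.numeric(vapply(parts, `[`, "", 1)),
             creatinine = as.numeric(vapply(parts, `[`, "", 2)))
}

#' Write / read a cohort table (CSV)
#'
#' One row per patient; booleans as 0/1, categorical levels as literal
#' strings, creatinine series in the encoded `"hours:value;..."` form.
#'
#' @param cohort cohort data.frame as produced by [generate_cohort()].
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  if (!"patient_id" %in% names(df))
    stop("cohort CSV must contain a patient_id column", call. = FALSE)
  df
}

#' Names of the matching covariates in a cohort table
#'
#' The demographic and intraoperative variables that enter the propensity
#' model and the balance table (everything observed before outcome
#' assessment except identifiers, group label and outcomes).
#'
#' @return character vector of column names.
#' @export
matching_covariates <- function() {
  c("age", "sex_male", "bsa", "bmi", "asa_class", "emergency", "chf",
    "copd", "diabetes", "hypertension", "ace_inhibitor", "beta_blocker",
    "ccb", "diuretic", "at1_antagonist", "preop_hb", "preop_creatinine",
    "surgical_approach", "duration_min", "epidural", "map_induction",
    "hr_induction", "spo2_induction")
}
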