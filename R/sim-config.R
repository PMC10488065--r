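#' Simulation configuration for synthetic perioperative cohorts
#'
#' Bundles every tunable of the synthetic cohort generator: cohort size,
#' sampling interval of the arterial-pressure series, the log-odds weights
#' that drive confounded treatment assignment, the hypotensive-episode
#' process, the alarm channel of the treated (index-monitored) arm, and the
#' postoperative creatinine model.
#'
#' The episode process is a homogeneous Poisson process over the case
#' duration with gamma-distributed episode depths and durations. In the
#' treated ("HPI") arm the episode rate and mean duration are multiplied by
#' `treatment_effect_multiplier`, and each incipient episode is averted
#' (alarm left in the index channel, no pressure dip) independently with
#' probability `alarm_aversion_prob`.
#'
#' @param n_patients cohort size (>= 4).
#' @param seed integer seed; the generator is bit-reproducible given the
#'   full configuration.
#' @param sample_interval_s sampling interval of the pressure series in
#'   seconds (default 30, the interval of record systems this emulates).
#' @param assignment_coefficients named list of log-odds weights for the
#'   treatment-assignment model. Recognised names: `intercept`, `emergency`,
#'   `epidural` (per indicator), `duration_min` (per minute), `asa_class`
#'   (per class). The linear predictor is
#'   `intercept + sum(coef * covariate)`; all-zero coefficients give an
#'   expected 50/50 split.
#' @param episode_rate_per_hour expected hypotensive episodes per hour of
#'   surgery in the control arm.
#' @param episode_depth_mean mean episode depth below the patient's
#'   baseline pressure, mmHg (gamma, shape 4).
#' @param episode_duration_mean mean episode duration in minutes (gamma,
#'   shape 2, floored at one sampling interval).
#' @param treatment_effect_multiplier multiplier in (0, 1] applied to
#'   episode rate and mean duration in the treated arm; 1 means no direct
#'   effect on the episode process.
#' @param alarm_lead_s seconds by which an index alarm precedes the onset
#'   of an incipient episode (default 300 s, the 5-minute prediction
#'   horizon of the index this emulates).
#' @param alarm_aversion_prob probability that an alarmed incipient episode
#'   is averted in the treated arm.
#' @param aki_base_prob baseline probability of postoperative acute kidney
#'   injury at zero hypotension burden.
#' @param aki_twa_slope log-odds increment of AKI per mmHg of TWA below
#'   65 mmHg.
#' @param map_baseline_mean,map_baseline_sd mean and SD of the per-patient
#'   baseline mean arterial pressure, mmHg.
#' @param map_noise_sd SD of the per-sample Gaussian measurement noise,
#'   mmHg.
#' @param drift_amplitude amplitude of the slow intraoperative pressure
#'   drift, mmHg.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_patients = 800L,
                       seed = 1L,
                       sample_interval_s = 30,
                       assignment_coefficients = list(
                         intercept    = 0.80,
                         emergency    = -2.2,
                         epidural     = 1.1,
                         duration_min = 0.005,
                         asa_class    = -0.7
                       ),
                       episode_rate_per_hour = 1.0,
                       episode_depth_mean = 18,
                       episode_duration_mean = 3,
                       treatment_effect_multiplier = 0.85,
                       alarm_lead_s = 300,
                       alarm_aversion_prob = 0.6,
                       aki_base_prob = 0.08,
                       aki_twa_slope = 1.5,
                       map_baseline_mean = 78,
                       map_baseline_sd = 6,
                       map_noise_sd = 2,
                       drift_amplitude = 3) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    sample_interval_s = as.numeric(sample_interval_s),
    assignment_coefficients = assignment_coefficients,
    episode_rate_per_hour = as.numeric(episode_rate_per_hour),
    episode_depth_mean = as.numeric(episode_depth_mean),
    episode_duration_mean = as.numeric(episode_duration_mean),
    treatment_effect_multiplier = as.numeric(treatment_effect_multiplier),
    alarm_lead_s = as.numeric(alarm_lead_s),
    alarm_aversion_prob = as.numeric(alarm_aversion_prob),
    aki_base_prob = as.numeric(aki_base_prob),
    aki_twa_slope = as.numeric(aki_twa_slope),
    map_baseline_mean = as.numeric(map_baseline_mean),
    map_baseline_sd = as.numeric(map_baseline_sd),
    map_noise_sd = as.numeric(map_noise_sd),
    drift_amplitude = as.numeric(drift_amplitude)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 4)
    stop("n_patients must be at least 4", call. = FALSE)
  if (cfg$sample_interval_s <= 0)
    stop("sample_interval_s must be positive", call. = FALSE)
  if (cfg$episode_rate_per_hour <= 0)
    stop("episode_rate_per_hour must be positive", call. = FALSE)
  m <- cfg$treatment_effect_multiplier
  if (!is.finite(m) || m <= 0 || m > 1)
    stop("treatment_effect_multiplier must lie in (0, 1]", call. = FALSE)
  for (p in c("alarm_aversion_prob", "aki_base_prob")) {
    v <- cfg[[p]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop(p, " must lie in [0, 1]", call. = FALSE)
  }
  if (!is.list(cfg$assignment_coefficients) ||
      is.null(names(cfg$assignment_coefficients)))
    stop("assignment_coefficients must be a named list", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n_patients: %d, seed: %d, interval: %gs\n",
              x$n_patients, x$seed, x$sample_interval_s))
  cat(sprintf("  episodes: %.2f/h, depth %.0f mmHg, duration %.1f min\n",
              x$episode_rate_per_hour, x$episode_depth_mean,
              x$episode_duration_mean))
  cat(sprintf("  treatment: multiplier %.2f, aversion %.2f, lead %gs\n",
              x$treatment_effect_multiplier, x$alarm_aversion_prob,
              x$alarm_lead_s))
  ac <- unlist(x$assignment_coefficients)
  cat("  assignment: ",
      paste(sprintf("%s=%.3g", names(ac), ac), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unspecified keys keep their
#' defaults. `assignment_coefficients` is a nested mapping.
#'
#' @param path path to a YAML file.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' Write a simulation configuration to a YAML file
#'
#' @param config a `sim_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
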