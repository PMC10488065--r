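#' Construct a fixed-interval arterial-pressure trace
#'
#' A `vital_trace` holds one case's mean-arterial-pressure series sampled at
#' a constant interval, plus an optional 0-100 prediction-index series for
#' index-monitored cases.
#'
#' @param patient_id scalar character id.
#' @param t numeric vector of seconds from monitoring start; strictly
#'   increasing with constant step.
#' @param map_mmHg numeric vector of mean arterial pressures, same length
#'   as `t`.
#' @param hpi_index optional numeric vector in \[0, 100\], same length.
#' @return an object of class `vital_trace`.
#' @export
vital_trace <- function(patient_id, t, map_mmHg, hpi_index = NULL) {
  x <- structure(
    list(patient_id = as.character(patient_id),
         t = as.numeric(t),
         map_mmHg = as.numeric(map_mmHg),
         hpi_index = if (!is.null(hpi_index)) as.numeric(hpi_index)),
    class = "vital_trace"
  )
  validate_vital_trace(x)
}

validate_vital_trace <- function(x) {
  n <- length(x$t)
  if (n < 2L) stop("trace must contain at least two samples", call. = FALSE)
  if (length(x$map_mmHg) != n)
    stop("t and map_mmHg differ in length", call. = FALSE)
  if (!is.null(x$hpi_index) && length(x$hpi_index) != n)
    stop("hpi_index length differs from t", call. = FALSE)
  if (anyNA(x$map_mmHg) || any(!is.finite(x$map_mmHg)))
    stop("map_mmHg contains non-finite values", call. = FALSE)
  dt <- diff(x$t)
  if (any(dt <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * dt[1])
    stop("trace is not uniformly sampled", call. = FALSE)
  x
}

# sampling interval in seconds
trace_dt <- function(trace) trace$t[2] - trace$t[1]

# full monitoring span in minutes: n samples each representing one interval
monitoring_time_min <- function(trace) {
  length(trace$t) * trace_dt(trace) / 60
}

#' @export
print.vital_trace <- function(x, ...) {
  cat(sprintf(
    "<vital_trace %s: %d samples @ %gs, MAP %.0f-%.0f mmHg%s>\n",
    x$patient_id, length(x$t), trace_dt(x),
    min(x$map_mmHg), max(x$map_mmHg),
    if (is.null(x$hpi_index)) "" else ", with index channel"))
  invisible(x)
}

#' Synthesize one arterial-pressure trace with planted hypotensive episodes
#'
#' The trace is `baseline + drift + noise - deficit`, clipped to
#' \[20, 200\] mmHg. Each episode subtracts its depth over its window with
#' raised-cosine onset and offset ramps; where episodes overlap the deepest
#' deficit wins sample-wise.
#'
#' @param duration_min case duration in minutes.
#' @param baseline baseline pressure, mmHg.
#' @param episodes data.frame (or NULL) with columns `start_s`,
#'   `duration_s`, `depth_mmHg`; episodes must start within the case.
#' @param interval_s sampling interval, seconds.
#' @param noise_sd SD of per-sample Gaussian noise, mmHg.
#' @param drift_amplitude amplitude of a slow sinusoidal drift, mmHg
#'   (default 0: no drift, so a noise-free call returns the deterministic
#'   baseline-minus-deficit signal).
#' @param patient_id id stored on the trace.
#' @return a [vital_trace()].
#' @export
generate_map_trace <- function(duration_min, baseline, episodes = NULL,
                               interval_s = 30, noise_sd = 0,
                               drift_amplitude = 0,
                               patient_id = "case") {
  stopifnot(duration_min > 0, interval_s > 0)
  n <- max(2L, as.integer(round(duration_min * 60 / interval_s)))
  t <- (seq_len(n) - 1L) * interval_s
  map <- rep(baseline, n)

  if (drift_amplitude > 0) {
    period_s <- stats::runif(1, 30, 60) * 60
    phase <- stats::runif(1, 0, 2 * pi)
    map <- map + drift_amplitude * sin(2 * pi * t / period_s + phase)
  }
  if (noise_sd > 0) map <- map + stats::rnorm(n, 0, noise_sd)

  if (!is.null(episodes) && nrow(episodes) > 0) {
    if (any(episodes$depth_mmHg <= 0))
      stop("episode depths must be positive", call. = FALSE)
    if (any(episodes$start_s < 0 | episodes$start_s > duration_min * 60))
      stop("episodes must start within the case", call. = FALSE)
    deficit <- rep(0, n)
    for (k in seq_len(nrow(episodes))) {
      deficit <- pmax(deficit, episode_deficit(
        t, episodes$start_s[k], episodes$duration_s[k],
        episodes$depth_mmHg[k]))
    }
    map <- map - deficit
  }

  vital_trace(patient_id, t, clamp(map, 20, 200))
}

# raised-cosine deficit envelope for one episode, evaluated at sample times
episode_deficit <- function(t, start_s, duration_s, depth) {
  ramp <- min(30, duration_s / 3)
  pos <- t - start_s
  w <- numeric(length(t))
  inside <- pos >= 0 & pos <= duration_s
  w[inside] <- 1
  if (ramp > 0) {
    up <- inside & pos < ramp
    dn <- inside & pos > duration_s - ramp
    w[up] <- 0.5 - 0.5 * cos(pi * pos[up] / ramp)
    w[dn] <- 0.5 - 0.5 * cos(pi * (duration_s - pos[dn]) / ramp)
  }
  depth * w
}

#' Write / read trace tables (long CSV)
#'
#' One row per sample: `patient_id, t_s, map_mmHg, hpi_index` (empty for
#' cases without an index channel).
#'
#' @param traces list of [vital_trace()] objects.
#' @param path CSV path.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   returns a named list of `vital_trace` objects.
#' @export
write_traces_csv <- function(traces, path) {
  frames <- lapply(traces, function(tr) {
    data.frame(patient_id = tr$patient_id, t_s = tr$t,
               map_mmHg = tr$map_mmHg,
               hpi_index = if (is.null(tr$hpi_index)) NA_real_ else
                 tr$hpi_index)
  })
  utils::write.csv(do.call(rbind, frames), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "t_s", "map_mmHg", "hpi_index")
  if (!all(need %in% names(df)))
    stop("trace CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, factor(df$patient_id, unique(df$patient_id))),
                function(d) {
    d <- d[order(d$t_s), ]
    hpi <- if (all(is.na(d$hpi_index))) NULL else d$hpi_index
    vital_trace(d$patient_id[1], d$t_s, d$map_mmHg, hpi)
  })
  out[unique(df$patient_id)]
}
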