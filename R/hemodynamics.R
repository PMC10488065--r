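#' Time-weighted average of hypotension below a threshold
#'
#' Total pressure-deficit area below `threshold` divided by total
#' monitoring time. On a uniformly sampled trace with interval `dt` this is
#' `sum(max(0, threshold - map_i) * dt) / (N * dt)`, i.e. the mean
#' per-sample deficit; the rectangle rule is used without interpolation at
#' threshold crossings. Units mmHg; 0 when no sample is below threshold.
#'
#' @param trace a [vital_trace()].
#' @param threshold hypotension threshold, mmHg (commonly 65, 60, 55).
#' @return scalar TWA in mmHg.
#' @export
twa_below <- function(trace, threshold) {
  validate_vital_trace(trace)
  mean(pmax(0, threshold - trace$map_mmHg))
}

#' Segment a trace into hypotensive episodes
#'
#' Maximal runs of consecutive samples with `map < threshold`. Runs
#' separated by at most `merge_gap_s` of above-threshold samples are
#' merged; merged runs shorter than `min_duration_s` are discarded.
#' Each sample represents one full sampling interval, so a run of k
#' samples lasts `k * dt` seconds.
#'
#' @param trace a [vital_trace()].
#' @param threshold hypotension threshold, mmHg.
#' @param min_duration_s minimum episode duration, seconds (default 60,
#'   the one-minute convention of the hypotension literature).
#' @param merge_gap_s maximum above-threshold gap merged into one episode,
#'   seconds (default 0).
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`;
#'   episodes are disjoint and ordered.
#' @export
detect_episodes <- function(trace, threshold, min_duration_s = 60,
                            merge_gap_s = 0) {
  validate_vital_trace(trace)
  stopifnot(min_duration_s >= 0, merge_gap_s >= 0)
  dt <- trace_dt(trace)
  below <- trace$map_mmHg < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(first = starts[r$values], last = ends[r$values])
  if (nrow(runs) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  # merge runs whose separating gap is <= merge_gap_s
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap_s <- (runs$first[k] - merged$last[nrow(merged)] - 1L) * dt
      if (gap_s <= merge_gap_s) {
        merged$last[nrow(merged)] <- runs$last[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  dur <- (merged$last - merged$first + 1L) * dt
  keep <- dur >= min_duration_s
  merged <- merged[keep, , drop = FALSE]
  data.frame(
    start_s = trace$t[merged$first],
    end_s = trace$t[merged$first] + dur[keep],
    duration_s = dur[keep],
    row.names = NULL
  )
}

#' Cumulative time below a threshold
#'
#' `dt` times the number of samples with `map < threshold`, in minutes.
#' Counts every below-threshold sample regardless of episode filtering.
#'
#' @inheritParams detect_episodes
#' @return minutes below threshold.
#' @export
cumulative_duration_below <- function(trace, threshold) {
  validate_vital_trace(trace)
  sum(trace$map_mmHg < threshold) * trace_dt(trace) / 60
}

#' Count prediction-index alarms
#'
#' One alarm is one maximal run of consecutive samples with
#' `hpi_index >= index_threshold`. The at-or-above convention follows the
#' index's described trigger ("equal or greater than 85"); the threshold is
#' configurable.
#'
#' @param trace a [vital_trace()] carrying an index channel.
#' @param index_threshold alarm threshold on the 0-100 index (default 85).
#' @return integer alarm count.
#' @export
count_alarms <- function(trace, index_threshold = 85) {
  validate_vital_trace(trace)
  if (is.null(trace$hpi_index))
    stop("trace ", trace$patient_id,
         " has no index channel; alarm count is undefined (not zero)",
         call. = FALSE)
  r <- rle(trace$hpi_index >= index_threshold)
  sum(r$values)
}

#' Prevented-event arithmetic
#'
#' Per patient: `max(0, n_alarms - n_events)` — every alarm in excess of a
#' realized hypotensive event is counted as a prevented event, floored at
#' zero. Aggregate over a group by summing per-patient values.
#'
#' @param n_alarms alarm count(s).
#' @param n_events realized hypotensive event count(s).
#' @return prevented-event count(s), same length as the inputs.
#' @export
prevented_events <- function(n_alarms, n_events) {
  stopifnot(all(n_alarms >= 0), all(n_events >= 0))
  pmax(0, n_alarms - n_events)
}

#' Fold ratio of group median event counts
#'
#' Ratio of the median per-patient event count in group A to that in group
#' B (e.g. "control patients experienced 1.5-fold more hypotensive
#' events").
#'
#' @param events_a,events_b per-patient event counts in each group.
#' @return `median(events_a) / median(events_b)`.
#' @export
events_fold_ratio <- function(events_a, events_b) {
  stats::median(events_a) / stats::median(events_b)
}

#' Per-patient hypotension endpoint bundle
#'
#' Computes the full endpoint set from one trace: TWA at each threshold,
#' episode count and cumulative duration below the primary threshold, alarm
#' count (if an index channel is present) and monitoring time.
#'
#' @param trace a [vital_trace()].
#' @param thresholds decreasing vector of thresholds, mmHg; the first is
#'   the primary threshold used for event counts and durations.
#' @param min_duration_s,merge_gap_s episode delimitation parameters, see
#'   [detect_episodes()].
#' @param index_threshold alarm threshold, see [count_alarms()].
#' @return one-row data.frame of class `hypotension_summary` with columns
#'   `patient_id`, `twa_65`, `twa_60`, `twa_55`, `n_events_65`,
#'   `cum_duration_65_min`, `n_alarms_ge85` (NA without index channel) and
#'   `monitoring_time_min`.
#' @export
summarize_patient <- function(trace, thresholds = c(65, 60, 55),
                              min_duration_s = 60, merge_gap_s = 0,
                              index_threshold = 85) {
  validate_vital_trace(trace)
  stopifnot(length(thresholds) == 3, !is.unsorted(rev(thresholds)))
  twas <- vapply(thresholds, function(th) twa_below(trace, th), numeric(1))
  eps <- detect_episodes(trace, thresholds[1], min_duration_s, merge_gap_s)
  out <- data.frame(
    patient_id = trace$patient_id,
    twa_65 = twas[1], twa_60 = twas[2], twa_55 = twas[3],
    n_events_65 = nrow(eps),
    cum_duration_65_min = cumulative_duration_below(trace, thresholds[1]),
    n_alarms_ge85 = if (is.null(trace$hpi_index)) NA_integer_ else
      count_alarms(trace, index_threshold),
    monitoring_time_min = monitoring_time_min(trace),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hypotension_summary", class(out))
  out
}

#' Endpoint table for a whole cohort
#'
#' @param traces list of [vital_trace()] objects.
#' @param ... passed to [summarize_patient()].
#' @return data.frame with one [summarize_patient()] row per trace.
#' @export
summarize_cohort <- function(traces, ...) {
  out <- do.call(rbind, lapply(traces, summarize_patient, ...))
  rownames(out) <- NULL
  out
}
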