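#' Summarise one fly's trial
#'
#' Whole-trial totals over all flight events (uncropped: the totals cover the
#' full 4 h): total distance, total flight time, number of flights, the
#' flight-time-weighted mean speed, and the spontaneous flight-initiation
#' statistic (mean seconds of idle time per flight initiated). A fly that
#' never flew gets zero totals and an `NA` initiation statistic -- the
#' statistic is undefined, not zero.
#'
#' @param events Flight-event table for one fly (see [segment_flights()]).
#' @param config An [experiment_config()].
#' @param fly_id Identifier used when `events` is empty.
#' @return A one-row data.frame: `fly_id`, `total_distance`, `flight_time`,
#'   `n_flights`, `mean_speed`, `mean_time_to_initiate`.
#' @export
summarize_fly <- function(events, config = experiment_config(), fly_id = NULL) {
  if (is.null(fly_id)) {
    fly_id <- if (nrow(events)) events$fly_id[1L] else "fly"
  }
  n <- nrow(events)
  flight_time <- if (n) sum(events$duration) else 0
  data.frame(
    fly_id = fly_id,
    total_distance = if (n) sum(events$distance) else 0,
    flight_time = flight_time,
    n_flights = n,
    mean_speed = if (n) {
      stats::weighted.mean(events$mean_speed, events$duration, na.rm = TRUE)
    } else NA_real_,
    mean_time_to_initiate = if (n) {
      mean_time_to_initiate(flight_time, n, config$trial_duration)
    } else NA_real_
  )
}

#' Mean time to initiate a flight
#'
#' Idle (non-flying) time divided by the number of flights:
#' `(trial_duration - flight_time) / n_flights`. A fair measure of migratory
#' restlessness: counting flights alone penalises flies that fly long
#' uninterrupted bouts.
#'
#' @param flight_time Total seconds spent flying, in `[0, trial_duration]`.
#' @param n_flights Number of flights; must be at least 1.
#' @param trial_duration Trial length in seconds. Default 14400.
#' @return Mean seconds of idle time per initiated flight.
#' @export
mean_time_to_initiate <- function(flight_time, n_flights,
                                  trial_duration = 14400) {
  if (any(n_flights < 1)) {
    stop("mean_time_to_initiate is undefined for flies with zero flights",
         call. = FALSE)
  }
  if (any(flight_time < 0 | flight_time > trial_duration)) {
    stop("flight_time must lie in [0, trial_duration]", call. = FALSE)
  }
  (trial_duration - flight_time) / n_flights
}

#' Per-minute time transect of one fly
#'
#' Samples the last second of every minute (the half-open window
#' `[60 m - 1, 60 m)` for minute `m`): the count of forward transitions that
#' fall inside a designated flight event, whether the fly was flying, and the
#' implied speed (count times sector width, hence quantised to multiples of
#' 0.0353 m/s). Arm rocking and movement too short to be a flight are
#' excluded because only transitions inside flight events are counted.
#' Normalised time is `m / n_minutes` on (0, 1], so its log is finite at the
#' first sample.
#'
#' @param series Kinematic series from [compute_kinematics()].
#' @param events Flight-event table from [segment_flights()].
#' @param geometry A [mill_geometry()].
#' @param config An [experiment_config()].
#' @param fly_id Fly identifier for the output rows.
#' @return A data.frame with one row per minute: `fly_id`, `minute`, `flying`,
#'   `n_events_last_second`, `speed`, `time_norm`, `time_log`.
#' @export
time_transect <- function(series, events, geometry = mill_geometry(),
                          config = experiment_config(), fly_id = NULL) {
  n_min <- as.integer(floor(config$trial_duration / 60))
  if (is.null(fly_id)) {
    fly_id <- if (nrow(events)) events$fly_id[1L] else "fly"
  }
  counts <- integer(n_min)
  if (nrow(series) && nrow(events)) {
    t <- series$t_s
    in_flight <- rep(FALSE, length(t))
    for (i in seq_len(nrow(events))) {
      in_flight <- in_flight | (t >= events$start[i] & t <= events$end[i])
    }
    keep <- series$sense == 1L & in_flight & (t %% 60) >= 59
    minute <- floor(t[keep] / 60) + 1L
    minute <- minute[minute <= n_min]
    tab <- table(minute)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  m <- seq_len(n_min)
  data.frame(
    fly_id = fly_id, minute = m, flying = counts > 0L,
    n_events_last_second = counts,
    speed = counts * distance_per_transition(geometry),
    time_norm = m / n_min, time_log = log(m / n_min)
  )
}

#' Population activity curve
#'
#' Per-minute proportion of flies flying across a cohort's transect samples,
#' with binomial standard errors.
#'
#' @param samples Row-bound [time_transect()] tables for one or more flies.
#' @return A data.frame with one row per minute: `minute`, `n_flies`,
#'   `n_flying`, `proportion_flying`, `se`.
#' @export
activity_curve <- function(samples) {
  stopifnot(nrow(samples) >= 1L)
  minutes <- sort(unique(samples$minute))
  n <- vapply(minutes, function(m) sum(samples$minute == m), integer(1))
  fl <- vapply(minutes, function(m) {
    sum(samples$flying[samples$minute == m])
  }, integer(1))
  p <- fl / n
  data.frame(minute = minutes, n_flies = n, n_flying = fl,
             proportion_flying = p, se = sqrt(p * (1 - p) / n))
}
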