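#' The soft speed cut-off for flight designation
#'
#' Forward movement counts as flight when speed is at least `v_high`
#' (0.20 m/s), or at least `v_low` (0.10 m/s) while the insect is accelerating
#' at `a_min` (0.10 m/s^2) or more. The acceleration clause admits genuine
#' take-offs that have not yet reached cruising speed while rejecting the
#' arm's own coast-down (whose insect acceleration is near zero once drag is
#' added back).
#'
#' @param speed Speed(s), m/s. `NA` (first transition, sense change) is never
#'   flight.
#' @param insect_accel Insect acceleration(s), m/s^2; `NA` disables the
#'   low-speed clause.
#' @param thresholds A [segmentation_thresholds()].
#' @return Logical vector.
#' @export
designate_flight <- function(speed, insect_accel,
                             thresholds = segmentation_thresholds()) {
  sp <- !is.na(speed)
  acc <- !is.na(insect_accel)
  (sp & speed >= thresholds$v_high) |
    (sp & acc & speed >= thresholds$v_low & insect_accel >= thresholds$a_min)
}

#' Segment a kinematic series into discrete flight events
#'
#' Finds maximal runs of qualifying forward transitions (see
#' [designate_flight()]), bridging internal non-qualifying gaps of at most
#' `max_gap` seconds, and discards runs shorter than `min_flight_duration`.
#' Backward-sense transitions never qualify. Per-event aggregates weight
#' time-dependent quantities (speed, acceleration) by time, while distance is
#' the transition count times the sector width.
#'
#' @param series A kinematic series from [compute_kinematics()].
#' @param thresholds A [segmentation_thresholds()].
#' @param config An [experiment_config()] (for the trial duration used by the
#'   normalised start time).
#' @param fly_id Fly identifier attached to the events.
#' @param geometry A [mill_geometry()].
#' @return A data.frame of flight events ordered by start time, with columns
#'   `fly_id`, `start`, `end`, `n_transitions`, `distance`, `duration`,
#'   `mean_speed`, `mean_insect_accel`, `start_time_norm`, `cropped_flag`
#'   (initialised `FALSE`; see [crop_late_flights()]).
#' @export
segment_flights <- function(series, thresholds = segmentation_thresholds(),
                            config = experiment_config(), fly_id = "fly",
                            geometry = mill_geometry()) {
  empty <- data.frame(
    fly_id = character(), start = numeric(), end = numeric(),
    n_transitions = integer(), distance = numeric(), duration = numeric(),
    mean_speed = numeric(), mean_insect_accel = numeric(),
    start_time_norm = numeric(), cropped_flag = logical()
  )
  if (!nrow(series)) return(empty)
  d <- distance_per_transition(geometry)

  qualifies <- series$sense == 1L &
    designate_flight(series$speed, series$insect_accel, thresholds)
  qi <- which(qualifies)
  if (!length(qi)) return(empty)
  qt <- series$t_s[qi]
  # new event wherever consecutive qualifying transitions are further apart
  # than the bridgeable gap
  brk <- c(TRUE, diff(qt) > thresholds$max_gap)
  grp <- cumsum(brk)
  starts <- tapply(qt, grp, min)
  ends <- tapply(qt, grp, max)

  out <- lapply(seq_along(starts), function(g) {
    s <- starts[[g]]; e <- ends[[g]]
    if (e - s < thresholds$min_flight_duration) return(NULL)
    inside <- series$t_s >= s & series$t_s <= e & series$sense == 1L
    n_tr <- sum(inside)
    w <- series$dt[inside]
    sp <- series$speed[inside]
    ia <- series$insect_accel[inside]
    ok_sp <- !is.na(sp) & !is.na(w)
    ok_ia <- !is.na(ia) & !is.na(w)
    data.frame(
      fly_id = fly_id, start = s, end = e, n_transitions = n_tr,
      distance = n_tr * d, duration = e - s,
      mean_speed = if (any(ok_sp)) sum(sp[ok_sp] * w[ok_sp]) / sum(w[ok_sp]) else NA_real_,
      mean_insect_accel = if (any(ok_ia)) sum(ia[ok_ia] * w[ok_ia]) / sum(w[ok_ia]) else NA_real_,
      start_time_norm = s / config$trial_duration,
      cropped_flag = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out[order(out$start), , drop = FALSE]
}

#' Flag flights initiated in the final minutes of the trial
#'
#' Flights initiated during the last `crop_window` seconds (10 min by default)
#' are flagged: their durations are censored by the trial end, so per-flight
#' distributional analyses exclude them. Whole-trial per-fly totals keep all
#' events.
#'
#' @param events A flight-event table from [segment_flights()].
#' @param config An [experiment_config()].
#' @return The table with `cropped_flag` set (`TRUE` when
#'   `start > trial_duration - crop_window`).
#' @export
crop_late_flights <- function(events, config = experiment_config()) {
  if (!nrow(events)) return(events)
  events$cropped_flag <- events$start > config$trial_duration - config$crop_window
  events
}
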