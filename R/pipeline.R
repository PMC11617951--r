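#' Process one fly's raw event log end to end
#'
#' Runs the two error-correction passes (direction glitches, then
#' acceleration-outlier smoothing), computes the kinematic series, segments
#' flight events, applies the end-of-trial crop flag, and summarises the fly.
#'
#' @param log A [raw_event_log()].
#' @param geometry A [mill_geometry()].
#' @param config An [experiment_config()].
#' @return A list: `series` (kinematic series), `flights` (event table with
#'   `cropped_flag`), `summary` (one-row per-fly summary), `transect`
#'   (per-minute samples), `corrections` (the two pass reports).
#' @export
process_fly <- function(log, geometry = mill_geometry(),
                        config = experiment_config()) {
  p1 <- correct_direction_errors(log, geometry, config$kinematics)
  p2 <- smooth_acceleration_outliers(p1$log, geometry, config$kinematics)
  series <- compute_kinematics(p2$log, geometry, config$kinematics)
  flights <- segment_flights(series, config$thresholds, config,
                             fly_id = log$fly_id, geometry = geometry)
  flights <- crop_late_flights(flights, config)
  list(
    series = series,
    flights = flights,
    summary = summarize_fly(flights, config, fly_id = log$fly_id),
    transect = time_transect(series, flights, geometry, config,
                             fly_id = log$fly_id),
    corrections = list(direction = p1$report, acceleration = p2$report)
  )
}

#' Process a cohort of event logs
#'
#' [process_fly()] over a list of logs, with results row-bound into cohort
#' tables and joined to metadata.
#'
#' @param logs Named list of [raw_event_log()] (e.g. from
#'   [simulate_cohort()]).
#' @param metadata Optional metadata data.frame (see [fly_metadata()]) joined
#'   onto the per-fly summaries by `fly_id`.
#' @param geometry A [mill_geometry()].
#' @param config An [experiment_config()].
#' @return A list: `flights`, `summaries`, `transect` (cohort tables), and
#'   `corrections` (per-fly list of pass reports).
#' @export
process_cohort <- function(logs, metadata = NULL,
                           geometry = mill_geometry(),
                           config = experiment_config()) {
  res <- lapply(logs, process_fly, geometry = geometry, config = config)
  flights <- do.call(rbind, c(lapply(res, `[[`, "flights"),
                              list(make.row.names = FALSE)))
  summaries <- do.call(rbind, c(lapply(res, `[[`, "summary"),
                                list(make.row.names = FALSE)))
  transect <- do.call(rbind, c(lapply(res, `[[`, "transect"),
                               list(make.row.names = FALSE)))
  if (!is.null(metadata)) {
    summaries <- merge(summaries, metadata, by = "fly_id", sort = FALSE)
  }
  list(flights = flights, summaries = summaries, transect = transect,
       corrections = lapply(res, `[[`, "corrections"))
}
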