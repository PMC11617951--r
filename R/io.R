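#' Construct a raw event log
#'
#' One fly's trial as recorded by the photointerrupter: an ordered stream of
#' timestamped directed transitions. Sense +1 is the fly's assigned forward
#' rotation direction (the clockwise/anti-clockwise convention is resolved at
#' acquisition time, so analysis code never sees it); -1 is backward movement
#' such as arm rocking.
#'
#' @param fly_id Fly identifier (length-1 character).
#' @param t_s Numeric vector of timestamps, seconds from trial start, strictly
#'   increasing, all within `[0, trial_duration]`.
#' @param sense Integer vector of directed senses, +1 or -1, same length as
#'   `t_s`.
#' @param trial_duration Trial length in seconds. Default 14400.
#' @return An object of class `raw_event_log` with fields `fly_id`, `events`
#'   (data.frame `t_s`, `sense`) and `trial_duration`.
#' @export
raw_event_log <- function(fly_id, t_s, sense, trial_duration = 14400) {
  stopifnot(length(fly_id) == 1L, length(t_s) == length(sense))
  t_s <- as.numeric(t_s)
  sense <- as.integer(sense)
  if (length(t_s)) {
    if (anyNA(t_s) || anyNA(sense)) {
      stop("event log: missing timestamp or sense", call. = FALSE)
    }
    bad <- which(!sense %in% c(-1L, 1L))
    if (length(bad)) {
      stop(sprintf("event log: sense must be +1 or -1 (row %d)", bad[1L]),
           call. = FALSE)
    }
    bad <- which(t_s < 0 | t_s > trial_duration)
    if (length(bad)) {
      stop(sprintf("event log: timestamp outside [0, %g] (row %d)",
                   trial_duration, bad[1L]), call. = FALSE)
    }
    if (length(t_s) > 1L) {
      bad <- which(diff(t_s) <= 0)
      if (length(bad)) {
        stop(sprintf("event log: timestamps not strictly increasing (row %d)",
                     bad[1L] + 1L), call. = FALSE)
      }
    }
  }
  structure(
    list(fly_id = as.character(fly_id),
         events = data.frame(t_s = t_s, sense = sense),
         trial_duration = as.numeric(trial_duration)),
    class = "raw_event_log"
  )
}

#' @export
print.raw_event_log <- function(x, ...) {
  cat(sprintf("<raw_event_log> fly %s: %d transitions over %g s (%d backward)\n",
              x$fly_id, nrow(x$events), x$trial_duration,
              sum(x$events$sense == -1L)))
  invisible(x)
}

#' Read a raw event log from delimited text
#'
#' Expects the documented event-log dialect: a CSV with header
#' `fly_id,t_s,sense`, one transition per row. Out-of-order timestamps are
#' rejected (not silently sorted), with the offending row named.
#'
#' @param path Path to an events CSV.
#' @param fly_id Optional fly to extract when the file holds several; must be
#'   given in that case.
#' @param trial_duration Trial length in seconds. Default 14400.
#' @return A [raw_event_log()].
#' @export
read_event_log <- function(path, fly_id = NULL, trial_duration = 14400) {
  if (!file.exists(path)) stop("event-log file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "t_s", "sense")
  if (!all(need %in% names(df))) {
    stop("event-log file must have columns fly_id,t_s,sense: ", path,
         call. = FALSE)
  }
  ids <- unique(df$fly_id)
  if (is.null(fly_id)) {
    if (length(ids) > 1L) {
      stop("event-log file holds several flies; supply fly_id", call. = FALSE)
    }
    fly_id <- if (length(ids)) ids else "unknown"
  } else {
    df <- df[df$fly_id == fly_id, , drop = FALSE]
  }
  raw_event_log(fly_id, df$t_s, df$sense, trial_duration = trial_duration)
}

#' Write a raw event log as delimited text
#'
#' @param log A [raw_event_log()].
#' @param path Output CSV path.
#' @param append Append without header (for multi-fly files). Default FALSE.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, append = FALSE) {
  stopifnot(inherits(log, "raw_event_log"))
  df <- data.frame(fly_id = log$fly_id, t_s = log$events$t_s,
                   sense = log$events$sense)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}

#' Assemble per-fly metadata
#'
#' Validates and level-codes the hand-recorded covariates: seasonal morph
#' (summer sedentary vs autumn migratory), ordinal body condition
#' (thin < medium < fat, abdominal plumpness proxying fuel stores), ordinal
#' size (small < moderate < large), sex, and the randomly assigned rotation
#' direction. Baselines follow the published convention: morph = summer,
#' direction = anti-clockwise.
#'
#' @param df A data.frame with columns `fly_id`, `morph`, `condition`, `size`,
#'   `sex`, `direction` (and optionally `capture_date`).
#' @return The data.frame with columns coerced to the documented factor
#'   codings.
#' @export
fly_metadata <- function(df) {
  need <- c("fly_id", "morph", "condition", "size", "sex", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  chk <- function(x, levels, what) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad)) stop(sprintf("metadata: unknown %s level '%s'", what, bad[1L]),
                          call. = FALSE)
  }
  chk(df$morph, c("summer", "autumn"), "morph")
  chk(df$condition, c("thin", "medium", "fat"), "condition")
  chk(df$size, c("small", "moderate", "large"), "size")
  chk(df$sex, c("male", "female"), "sex")
  chk(df$direction, c("anti-clockwise", "clockwise"), "direction")
  df$fly_id <- as.character(df$fly_id)
  df$morph <- factor(df$morph, levels = c("summer", "autumn"))
  df$condition <- factor(df$condition, levels = c("thin", "medium", "fat"),
                         ordered = TRUE)
  df$size <- factor(df$size, levels = c("small", "moderate", "large"),
                    ordered = TRUE)
  df$sex <- factor(df$sex, levels = c("male", "female"))
  df$direction <- factor(df$direction, levels = c("anti-clockwise", "clockwise"))
  df
}

#' Read per-fly metadata from CSV
#'
#' @param path Path to `metadata.csv`.
#' @return A validated metadata data.frame (see [fly_metadata()]).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  fly_metadata(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write pipeline result tables
#'
#' Writes the flight-event table, the per-fly summary table and the per-minute
#' time-transect table as CSV with deterministic column order so re-reading
#' reproduces the values.
#'
#' @param flights Flight-event table from [segment_flights()] /
#'   [crop_late_flights()].
#' @param fly_summaries Per-fly summary table from [summarize_fly()].
#' @param transect Time-transect table from [time_transect()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_results <- function(flights, fly_summaries, transect, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(flights = file.path(dir, "flights.csv"),
             fly_summary = file.path(dir, "fly_summary.csv"),
             transect = file.path(dir, "transect.csv"))
  cols <- list(
    flights = c("fly_id", "start", "end", "n_transitions", "distance",
                "duration", "mean_speed", "mean_insect_accel",
                "start_time_norm", "cropped_flag"),
    fly_summary = c("fly_id", "total_distance", "flight_time", "n_flights",
                    "mean_speed", "mean_time_to_initiate"),
    transect = c("fly_id", "minute", "flying", "n_events_last_second",
                 "speed", "time_norm", "time_log")
  )
  tabs <- list(flights = flights, fly_summary = fly_summaries,
               transect = transect)
  for (nm in names(tabs)) {
    tab <- tabs[[nm]]
    keep <- intersect(cols[[nm]], names(tab))
    extra <- setdiff(names(tab), keep)
    utils::write.csv(tab[, c(keep, extra), drop = FALSE], paths[[nm]],
                     row.names = FALSE)
  }
  invisible(paths)
}
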