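#' No-load deceleration model of the mill arm
#'
#' The free-spinning arm loses speed to bearing friction and air resistance.
#' This is modelled as `decel(v) = c0 + c1 * v` (m/s^2, always >= 0 for
#' v >= 0). Adding `decel(v)` back onto the observed acceleration of the arm
#' yields the acceleration contributed by the insect itself, so that a
#' coasting (thrust-off) arm shows insect acceleration near zero.
#'
#' Defaults are the simulator's arm truth; for real hardware the model is
#' calibrated from a spin-down trial with [estimate_no_load_decel()].
#'
#' @param c0 Speed-independent friction term, m/s^2. Default 0.05.
#' @param c1 Speed-proportional drag term, 1/s. Default 0.5.
#' @return An object of class `decel_model`, callable via [decelerate()].
#' @export
decel_model <- function(c0 = 0.05, c1 = 0.5) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0) {
    stop("decel_model: c0 must be a finite non-negative number", call. = FALSE)
  }
  if (!is.numeric(c1) || length(c1) != 1L || !is.finite(c1) || c1 < 0) {
    stop("decel_model: c1 must be a finite non-negative number", call. = FALSE)
  }
  structure(list(c0 = as.numeric(c0), c1 = as.numeric(c1)), class = "decel_model")
}

#' Evaluate a no-load deceleration model
#'
#' @param model A [decel_model()].
#' @param v Speed(s) in m/s.
#' @return Deceleration magnitude(s) in m/s^2.
#' @export
decelerate <- function(model, v) {
  stopifnot(inherits(model, "decel_model"))
  model$c0 + model$c1 * v
}

#' @export
print.decel_model <- function(x, ...) {
  cat(sprintf("<decel_model> decel(v) = %.4g + %.4g * v  [m/s^2]\n", x$c0, x$c1))
  invisible(x)
}

#' Kinematics configuration
#'
#' Parameters of the transition-stream error-correction passes and the derived
#' kinematic series.
#'
#' @param residual_window Trailing window, in transitions, of the rolling mean
#'   subtracted from speed to form residual speed. Default 16, exactly one
#'   wheel rotation, which detrends sector-width asymmetry.
#' @param max_biological_accel Magnitude bound, m/s^2, beyond which an implied
#'   insect acceleration is treated as a timing glitch rather than thrust.
#'   Default 20.
#' @param no_load A [decel_model()] for the arm.
#' @param min_interval Debounce floor between consecutive timestamps, seconds.
#'   Default 0.001.
#' @param max_reversal_run Longest run of opposite-sense transitions that the
#'   direction-error pass may reclassify. Default 2.
#' @param reversal_accel Acceleration magnitude, m/s^2, plausibly available to
#'   a tethered insect for a genuine stop-and-reverse of the loaded arm; sets
#'   the minimum physical duration of a true reversal in the direction-error
#'   pass. Much smaller than `max_biological_accel` (brief forward thrust
#'   spikes far exceed what sustained braking plus re-acceleration through a
#'   reversal can achieve). Default 2.
#' @return A list of class `kinematics_config`.
#' @export
kinematics_config <- function(residual_window = 16L,
                              max_biological_accel = 20,
                              no_load = decel_model(),
                              min_interval = 0.001,
                              max_reversal_run = 2L,
                              reversal_accel = 2) {
  stopifnot(residual_window >= 2, max_biological_accel > 0, min_interval > 0,
            max_reversal_run >= 1, reversal_accel > 0,
            inherits(no_load, "decel_model"))
  structure(
    list(
      residual_window = as.integer(residual_window),
      max_biological_accel = as.numeric(max_biological_accel),
      no_load = no_load,
      min_interval = as.numeric(min_interval),
      max_reversal_run = as.integer(max_reversal_run),
      reversal_accel = as.numeric(reversal_accel)
    ),
    class = "kinematics_config"
  )
}

#' Flight-designation thresholds
#'
#' The soft speed cut-off: forward movement is flight if speed >= `v_high`
#' (0.20 m/s), or if speed >= `v_low` (0.10 m/s) while the insect is
#' accelerating at >= `a_min` (0.10 m/s^2). Qualifying transitions are grouped
#' into flight events, bridging internal non-qualifying gaps up to `max_gap`
#' seconds and discarding events shorter than `min_flight_duration` seconds.
#'
#' @param v_high Unconditional flight speed threshold, m/s.
#' @param v_low Conditional flight speed threshold, m/s.
#' @param a_min Insect-acceleration threshold enabling the low-speed clause,
#'   m/s^2.
#' @param min_flight_duration Shortest retained event, seconds.
#' @param max_gap Longest bridged non-qualifying interval within an event,
#'   seconds.
#' @return A list of class `segmentation_thresholds`.
#' @export
segmentation_thresholds <- function(v_high = 0.20, v_low = 0.10, a_min = 0.10,
                                    min_flight_duration = 1.0, max_gap = 1.0) {
  stopifnot(v_low > 0, v_high > v_low, a_min > 0,
            min_flight_duration >= 0, max_gap >= 0)
  structure(
    list(v_high = v_high, v_low = v_low, a_min = a_min,
         min_flight_duration = min_flight_duration, max_gap = max_gap),
    class = "segmentation_thresholds"
  )
}

#' Experiment configuration
#'
#' @param trial_duration Trial length in seconds. Default 14400 (4 h).
#' @param crop_window Seconds before trial end; flights initiated inside this
#'   window are flagged and excluded from per-flight analyses (they still
#'   count toward whole-trial per-fly totals). Default 600 (10 min).
#' @param thresholds A [segmentation_thresholds()].
#' @param kinematics A [kinematics_config()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(trial_duration = 14400,
                              crop_window = 600,
                              thresholds = segmentation_thresholds(),
                              kinematics = kinematics_config()) {
  stopifnot(trial_duration > 0, crop_window > 0, crop_window < trial_duration,
            inherits(thresholds, "segmentation_thresholds"),
            inherits(kinematics, "kinematics_config"))
  structure(
    list(trial_duration = trial_duration, crop_window = crop_window,
         thresholds = thresholds, kinematics = kinematics),
    class = "experiment_config"
  )
}

#' Write an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- list(
    trial_duration = config$trial_duration,
    crop_window = config$crop_window,
    segmentation = unclass(config$thresholds),
    kinematics = list(
      residual_window = config$kinematics$residual_window,
      max_biological_accel = config$kinematics$max_biological_accel,
      min_interval = config$kinematics$min_interval,
      max_reversal_run = config$kinematics$max_reversal_run,
      no_load = unclass(config$kinematics$no_load)
    )
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' @param path A YAML file written by [write_config()] (missing keys fall back
#'   to defaults).
#' @return An [experiment_config()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  seg <- x$segmentation %||% list()
  kin <- x$kinematics %||% list()
  nl <- kin$no_load %||% list()
  experiment_config(
    trial_duration = x$trial_duration %||% 14400,
    crop_window = x$crop_window %||% 600,
    thresholds = do.call(segmentation_thresholds,
                         seg[names(seg) %in% names(formals(segmentation_thresholds))]),
    kinematics = kinematics_config(
      residual_window = kin$residual_window %||% 16L,
      max_biological_accel = kin$max_biological_accel %||% 20,
      min_interval = kin$min_interval %||% 0.001,
      max_reversal_run = kin$max_reversal_run %||% 2L,
      no_load = decel_model(c0 = nl$c0 %||% 0.05, c1 = nl$c1 %||% 0.5)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
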