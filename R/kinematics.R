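#' First error pass: repair recorded direction glitches
#'
#' The dual-channel sensor occasionally reports a spurious change of travel
#' direction. A short run of opposite-sense transitions flanked on both sides
#' by consistent-sense runs is reclassified to the flanking sense when its
#' timing is incompatible with a physical reversal of the spinning arm:
#' stopping, reversing over the run's sectors and resuming the local speed `v`
#' cannot take less than `2 v / a + 2 sqrt(2 n d / a)` seconds (brake and
#' re-accelerate plus traverse `n` sectors of width `d` out and back at the
#' reversal acceleration `a = reversal_accel`). Slow sustained alternation
#' (arm rocking) is left untouched. The pass is conservative: every change is
#' listed in the report.
#'
#' @param log A [raw_event_log()].
#' @param geometry A [mill_geometry()].
#' @param config A [kinematics_config()]; uses `max_reversal_run` and
#'   `reversal_accel`.
#' @return A list with `log` (corrected [raw_event_log()]) and `report`
#'   (data.frame `row`, `t_s`, `old_sense`, `new_sense`; zero rows when
#'   nothing was changed).
#' @export
correct_direction_errors <- function(log, geometry = mill_geometry(),
                                     config = kinematics_config()) {
  stopifnot(inherits(log, "raw_event_log"))
  empty_report <- data.frame(row = integer(), t_s = numeric(),
                             old_sense = integer(), new_sense = integer())
  ev <- log$events
  n <- nrow(ev)
  if (n < 3L) return(list(log = log, report = empty_report))

  d <- distance_per_transition(geometry)
  a_rev <- config$reversal_accel
  k <- config$max_reversal_run
  r <- rle(ev$sense)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$lengths)
  flip <- integer(0)
  if (nruns >= 3L) {
    for (j in 2:(nruns - 1L)) {
      len <- r$lengths[j]
      if (len > k) next
      # flanking runs (opposite sense by construction) must be substantive
      if (r$lengths[j - 1L] < 2L || r$lengths[j + 1L] < 2L) next
      s <- starts[j]; e <- ends[j]
      t_before <- ev$t_s[s - 1L]
      t_after <- ev$t_s[e + 1L]
      span <- t_after - t_before
      # local speed from up to 3 same-sense intervals on each flank
      prev_t <- ev$t_s[max(starts[j - 1L], s - 4L):(s - 1L)]
      next_t <- ev$t_s[(e + 1L):min(ends[j + 1L], e + 4L)]
      dts <- c(diff(prev_t), diff(next_t))
      if (!length(dts)) next
      v_local <- d / stats::median(dts)
      t_min <- 2 * v_local / a_rev + 2 * sqrt(2 * len * d / a_rev)
      if (span < t_min) flip <- c(flip, s:e)
    }
  }
  if (!length(flip)) return(list(log = log, report = empty_report))
  report <- data.frame(row = flip, t_s = ev$t_s[flip],
                       old_sense = ev$sense[flip],
                       new_sense = -ev$sense[flip])
  ev$sense[flip] <- -ev$sense[flip]
  out <- raw_event_log(log$fly_id, ev$t_s, ev$sense,
                       trial_duration = log$trial_duration)
  list(log = out, report = report)
}

#' Second error pass: smooth timing glitches implying impossible acceleration
#'
#' A mistimed transition makes one inter-event interval too short and its
#' neighbour too long, implying a pair of large opposite accelerations that no
#' tethered insect can produce on a loaded mill. Any timestamp whose flanking
#' finite-difference insect accelerations both exceed `max_biological_accel`
#' in magnitude is treated as a glitch and re-placed by linear interpolation
#' between the nearest trusted timestamps (flanking data fill the gap). The
#' pass repeats until clean and is idempotent on clean streams.
#'
#' @inheritParams correct_direction_errors
#' @param max_passes Safety bound on the repair iterations. Default 6.
#' @return A list with `log` (repaired [raw_event_log()]) and `report`
#'   (data.frame `row`, `t_old`, `t_new`, `pass`).
#' @export
smooth_acceleration_outliers <- function(log, geometry = mill_geometry(),
                                         config = kinematics_config(),
                                         max_passes = 6L) {
  stopifnot(inherits(log, "raw_event_log"))
  t <- log$events$t_s
  sense <- log$events$sense
  n <- length(t)
  report <- data.frame(row = integer(), t_old = numeric(), t_new = numeric(),
                       pass = integer())
  if (n < 4L) return(list(log = log, report = report))
  d <- distance_per_transition(geometry)
  a_bound <- config$max_biological_accel
  nl <- config$no_load

  for (pass in seq_len(max_passes)) {
    dt <- c(NA, diff(t))
    speed <- c(NA, ifelse(sense[-1L] == sense[-n], d / dt[-1L], NA))
    acc <- c(NA, diff(speed) / dt[-1L])
    insect <- acc + decelerate(nl, speed)
    big <- !is.na(insect) & abs(insect) > a_bound
    # a mistimed transition produces a pair of adjacent out-of-range
    # accelerations; whether the short interval precedes or follows the
    # culprit depends on the glitch sign, so both endpoints of the offending
    # interval are re-placed from flanking data
    pair <- which(big[-n] & big[-1L])  # j with big[j] & big[j+1]
    suspect <- sort(unique(c(pair - 1L, pair)))
    suspect <- setdiff(suspect, c(1L, n))
    if (!length(suspect)) break
    good <- setdiff(seq_len(n), suspect)
    t_new <- t
    t_new[suspect] <- stats::approx(good, t[good], xout = suspect)$y
    report <- rbind(report, data.frame(row = suspect, t_old = t[suspect],
                                       t_new = t_new[suspect], pass = pass))
    t <- t_new
  }
  out <- raw_event_log(log$fly_id, t, sense, trial_duration = log$trial_duration)
  list(log = out, report = report)
}

#' Compute the per-transition kinematic series
#'
#' For each transition: speed (sector width over the interval since the
#' previous same-sense transition), residual speed (speed minus a trailing
#' rolling mean over `residual_window` transitions -- one wheel rotation by
#' default, which detrends sector-width asymmetry), observed acceleration
#' (two-point finite difference of speed), and insect acceleration (observed
#' acceleration plus the arm's no-load deceleration at that speed, so that
#' pure coasting reads as zero insect thrust).
#'
#' @param log A corrected [raw_event_log()].
#' @inheritParams correct_direction_errors
#' @return A data.frame with columns `t_s`, `sense`, `dt`, `speed`,
#'   `residual_speed`, `observed_accel`, `insect_accel`; zero rows when the
#'   log has fewer than two events. Speed is `NA` at the first event and
#'   across sense changes.
#' @export
compute_kinematics <- function(log, geometry = mill_geometry(),
                               config = kinematics_config()) {
  stopifnot(inherits(log, "raw_event_log"))
  t <- log$events$t_s
  sense <- log$events$sense
  n <- length(t)
  cols <- c("t_s", "sense", "dt", "speed", "residual_speed",
            "observed_accel", "insect_accel")
  if (n < 2L) {
    return(stats::setNames(
      data.frame(numeric(0), integer(0), numeric(0), numeric(0), numeric(0),
                 numeric(0), numeric(0)), cols))
  }
  d <- distance_per_transition(geometry)
  dt <- c(NA, diff(t))
  speed <- c(NA, ifelse(sense[-1L] == sense[-n], d / dt[-1L], NA))
  observed <- c(NA, diff(speed) / dt[-1L])
  insect <- observed + decelerate(config$no_load, speed)
  residual <- speed - rolling_mean_trailing(speed, config$residual_window)
  data.frame(t_s = t, sense = sense, dt = dt, speed = speed,
             residual_speed = residual, observed_accel = observed,
             insect_accel = insect)
}

# Trailing (causal) rolling mean with partial windows; NA entries are skipped
# rather than poisoning the window.
rolling_mean_trailing <- function(x, window) {
  n <- length(x)
  ok <- !is.na(x)
  cs <- cumsum(ifelse(ok, x, 0))
  cc <- cumsum(ok)
  lag_cs <- c(rep(0, min(window, n)), cs[seq_len(max(0L, n - window))])
  lag_cc <- c(rep(0, min(window, n)), cc[seq_len(max(0L, n - window))])
  s <- cs - lag_cs
  k <- cc - lag_cc
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Estimate the arm's no-load deceleration from a spin-down trial
#'
#' Given an event log of the free-spinning arm decaying from an initial speed
#' to rest, fits `decel(v) = c0 + c1 * v` by least squares of the observed
#' `-dv/dt` against speed.
#'
#' @param spin_down_log A [raw_event_log()] of a free spin-down (see
#'   [simulate_spin_down()]).
#' @param geometry A [mill_geometry()].
#' @param min_points Minimum usable transitions. Default 10.
#' @return A list with `model` (a [decel_model()]), `residual_sd` (m/s^2) and
#'   `n_points`.
#' @export
estimate_no_load_decel <- function(spin_down_log, geometry = mill_geometry(),
                                   min_points = 10L) {
  stopifnot(inherits(spin_down_log, "raw_event_log"))
  t <- spin_down_log$events$t_s
  if (length(t) < min_points) {
    stop(sprintf("insufficient data: %d transitions (< %d) in spin-down log",
                 length(t), min_points), call. = FALSE)
  }
  d <- distance_per_transition(geometry)
  v <- d / diff(t)                       # speed over each interval
  tm <- (t[-1L] + t[-length(t)]) / 2     # interval midpoints
  a <- diff(v) / diff(tm)                # dv/dt between intervals
  vmid <- (v[-1L] + v[-length(v)]) / 2
  keep <- is.finite(a) & is.finite(vmid)
  if (sum(keep) < min_points - 2L) {
    stop("insufficient data: too few finite speed differences", call. = FALSE)
  }
  if (stats::sd(vmid[keep]) < 1e-9) {
    # degenerate spin-down (no measurable decay): constant-speed arm
    fit <- stats::lm(y ~ 1, data = data.frame(y = -a[keep]))
    cf <- c(stats::coef(fit)[[1]], 0)
  } else {
    fit <- stats::lm(y ~ vmid, data = data.frame(y = -a[keep],
                                                 vmid = vmid[keep]))
    cf <- stats::coef(fit)
  }
  list(model = decel_model(c0 = max(cf[[1]], 0), c1 = max(cf[[2]], 0)),
       residual_sd = stats::sigma(fit),
       n_points = sum(keep))
}
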