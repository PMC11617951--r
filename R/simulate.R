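#' Simulation scenario for a synthetic flight-mill cohort
#'
#' Bundles the generative parameters of the synthetic cohort. Defaults encode
#' the study conditions: 141 flies in the published morph x condition x
#' direction design with the published group-mean distances as targets,
#' population flight activity decaying exponentially from 78% occupancy in
#' the first minute to 8% in the last, commanded bout speeds declining from a
#' 0.84 m/s early median to a 0.35 m/s level after mid-trial, per-fly
#' heterogeneity through a Gamma multiplier with dispersion 2.29, a linear
#' no-load drag model for the arm, and hardware noise (direction glitches,
#' low-speed arm rocking, timestamp jitter at 1 ms polling resolution).
#'
#' @param n_flies Cohort size. Default 141.
#' @param trial_duration Trial seconds. Default 14400.
#' @param p_start,p_end Flight-occupancy endpoints of the exponential decay.
#'   Defaults 0.78 and 0.08.
#' @param speed_start,speed_late Early-trial and late-trial medians of the
#'   commanded bout speed, m/s. Defaults 0.84 and 0.35; the decline is linear
#'   until `speed_level_frac` of the trial, then level.
#' @param speed_level_frac Fraction of the trial after which commanded speed
#'   stays at `speed_late`. Default 0.5 (2 h).
#' @param mean_bout_duration Median of the per-fly mean bout duration, s
#'   (log-normal across flies, sdlog `bout_duration_lsd`). Default 180.
#' @param bout_duration_lsd Between-fly spread of mean bout duration (sdlog).
#'   Default 0.5.
#' @param speed_lsd Within-fly lognormal spread of commanded bout speeds.
#'   Default 0.2.
#' @param gamma_dispersion Dispersion of the per-fly Gamma distance
#'   multiplier. Default 2.29.
#' @param ramp_accel Thrust-limited acceleration of the trapezoidal bout
#'   profile, m/s^2. Default 2.
#' @param speed_clamp Commanded plateau speed bounds, m/s. Default
#'   c(0.25, 2.0).
#' @param arm A [decel_model()]: the arm's true no-load drag.
#' @param geometry A [mill_geometry()].
#' @param glitch_rate Probability a transition's sense is recorded flipped.
#'   Default 1e-4.
#' @param rocking_per_hour Expected rocking episodes per idle hour. Default 6.
#' @param rocking_speed Apparent speed of rocking transitions, m/s.
#'   Default 0.05.
#' @param jitter_sd Gaussian timestamp jitter, s. Default 2e-4.
#' @param polling Timestamp quantisation (hardware polling resolution), s.
#'   Default 1e-3.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_flies = 141L, trial_duration = 14400,
                         p_start = 0.78, p_end = 0.08,
                         speed_start = 0.84, speed_late = 0.35,
                         speed_level_frac = 0.5,
                         mean_bout_duration = 180, bout_duration_lsd = 0.5,
                         speed_lsd = 0.2, gamma_dispersion = 2.29,
                         ramp_accel = 2, speed_clamp = c(0.25, 2.0),
                         arm = decel_model(), geometry = mill_geometry(),
                         glitch_rate = 1e-4, rocking_per_hour = 6,
                         rocking_speed = 0.05, jitter_sd = 2e-4,
                         polling = 1e-3) {
  stopifnot(p_start >= 0, p_start <= 1, p_end >= 0, p_end <= 1,
            glitch_rate >= 0, rocking_per_hour >= 0, jitter_sd >= 0,
            polling >= 0, speed_clamp[1] > 0, speed_clamp[2] > speed_clamp[1])
  structure(
    list(n_flies = as.integer(n_flies), trial_duration = trial_duration,
         p_start = p_start, p_end = p_end,
         speed_start = speed_start, speed_late = speed_late,
         speed_level_frac = speed_level_frac,
         mean_bout_duration = mean_bout_duration,
         bout_duration_lsd = bout_duration_lsd, speed_lsd = speed_lsd,
         gamma_dispersion = gamma_dispersion, ramp_accel = ramp_accel,
         speed_clamp = speed_clamp, arm = arm, geometry = geometry,
         glitch_rate = glitch_rate, rocking_per_hour = rocking_per_hour,
         rocking_speed = rocking_speed, jitter_sd = jitter_sd,
         polling = polling),
    class = "sim_scenario"
  )
}

#' Published cohort design
#'
#' Cell sizes of the published distance prediction table
#' (direction x morph x condition, 141 flies) with the group-mean distances
#' used as simulator targets; size frequencies follow the speed table's
#' direction margins.
#'
#' @return A 12-row data.frame: `direction`, `morph`, `condition`, `n`,
#'   `mean_distance`.
#' @export
cohort_design <- function() .cohort_design()

.cohort_design <- function() {
  g <- expand.grid(condition = c("thin", "medium", "fat"),
                   morph = c("summer", "autumn"),
                   direction = c("anti-clockwise", "clockwise"),
                   stringsAsFactors = FALSE)[, 3:1]
  g$n <- c(3, 9, 6, 5, 19, 13, 4, 11, 4, 13, 30, 24)
  g$mean_distance <- c(171.8, 482.1, 789.6, 371.0, 1041.2, 1705.4,
                       339.2, 951.8, 1559.0, 732.6, 2055.8, 3367.1)
  g
}

.size_margins <- list("anti-clockwise" = c(small = 7, moderate = 44, large = 4),
                      "clockwise" = c(small = 21, moderate = 56, large = 9))
.sex_p_male <- c(summer = 12 / 37, autumn = 3 / 93)

# Allocate `n` flies over the 12-cell design proportionally (exact at the
# published n = 141), largest-remainder rounding.
.allocate_design <- function(n) {
  g <- .cohort_design()
  exact <- g$n * n / sum(g$n)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  g$n_alloc <- base
  g
}

#' Simulate one fly's ground-truth bout schedule
#'
#' Bout initiations follow an inhomogeneous Bernoulli-per-second process
#' (realised through its exponential waiting times) whose flight occupancy
#' decays exponentially between the scenario's endpoint probabilities; bout
#' durations are exponential around the fly's mean; commanded plateau speeds
#' follow the declining population speed profile and are then rescaled so the
#' fly's scheduled distance matches its group-mean target times a Gamma
#' heterogeneity multiplier (within the commanded speed bounds -- low-target
#' flies saturate at the lower bound rather than stop flying, since occupancy
#' is the primary calibrated quantity).
#'
#' @param scenario A [sim_scenario()].
#' @param mean_distance Group-mean target distance, m (NA skips distance
#'   calibration).
#' @param seed Optional integer seed for this fly's substream.
#' @return A data.frame of bouts: `start`, `duration`, `speed` (commanded
#'   plateau, m/s), plus attribute `gamma_multiplier`.
#' @export
simulate_bouts <- function(scenario, mean_distance = NA, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- scenario$trial_duration
  p0 <- scenario$p_start; p1 <- scenario$p_end
  g_mult <- if (scenario$gamma_dispersion > 0) {
    stats::rgamma(1, shape = 1 / scenario$gamma_dispersion,
                  rate = 1 / scenario$gamma_dispersion)
  } else 1
  D <- stats::rlnorm(1, log(scenario$mean_bout_duration) -
                       scenario$bout_duration_lsd^2 / 2,
                     scenario$bout_duration_lsd)
  D <- min(max(D, 30), 600)
  occupancy <- function(t) {
    if (p0 <= 0 || p1 <= 0) return(0)
    p0 * exp(-log(p0 / p1) * t / T)
  }
  base_speed <- function(t) {
    tl <- scenario$speed_level_frac * T
    ifelse(t >= tl, scenario$speed_late,
           scenario$speed_start +
             (scenario$speed_late - scenario$speed_start) * t / tl)
  }

  starts <- numeric(0); durs <- numeric(0)
  t <- 0
  # the trial starts with the stationary occupancy: some flies are already
  # airborne at minute one
  if (stats::runif(1) < occupancy(0)) {
    dur <- min(max(stats::rexp(1, 1 / D), 5), T)
    starts <- 0; durs <- dur; t <- dur
  }
  while (t < T) {
    p <- occupancy(t)
    if (p <= 0 || p >= 1) break
    hazard <- p / (D * (1 - p))
    idle <- stats::rexp(1, hazard)
    t <- t + idle
    if (t >= T) break
    dur <- min(max(stats::rexp(1, 1 / D), 5), T - t)
    starts <- c(starts, t); durs <- c(durs, dur)
    t <- t + dur
  }
  if (!length(starts)) {
    out <- data.frame(start = numeric(0), duration = numeric(0),
                      speed = numeric(0))
    attr(out, "gamma_multiplier") <- g_mult
    return(out)
  }
  speed <- base_speed(starts) * stats::rlnorm(length(starts), 0,
                                              scenario$speed_lsd)
  if (is.finite(mean_distance) && mean_distance > 0) {
    scheduled <- sum(durs * speed)
    mult <- min(max(mean_distance * g_mult / scheduled, 0.3), 3)
    speed <- speed * mult
  }
  speed <- pmin(pmax(speed, scenario$speed_clamp[1]), scenario$speed_clamp[2])
  out <- data.frame(start = starts, duration = durs, speed = speed)
  attr(out, "gamma_multiplier") <- g_mult
  out
}

# ---- arm coasting physics -------------------------------------------------

# time for the unpowered arm to decay from v0 to v_target (Inf if unreachable)
.coast_time_to <- function(v0, arm, v_target) {
  c0 <- arm$c0; c1 <- arm$c1
  if (v_target >= v0) return(0)
  if (c1 > 0) {
    vc <- c0 / c1
    if (v_target + vc <= 0) return(Inf)
    log((v0 + vc) / (v_target + vc)) / c1
  } else if (c0 > 0) {
    (v0 - v_target) / c0
  } else {
    Inf
  }
}

# arc length travelled in coast time tau (vectorised over tau)
.coast_arc <- function(v0, arm, tau) {
  c0 <- arm$c0; c1 <- arm$c1
  if (c1 > 0) {
    vc <- c0 / c1
    (v0 + vc) / c1 * (1 - exp(-c1 * tau)) - vc * tau
  } else if (c0 > 0) {
    tau <- pmin(tau, v0 / c0)
    v0 * tau - c0 * tau^2 / 2
  } else {
    v0 * tau
  }
}

.coast_speed <- function(v0, arm, tau) {
  c0 <- arm$c0; c1 <- arm$c1
  if (c1 > 0) {
    vc <- c0 / c1
    pmax((v0 + vc) * exp(-c1 * tau) - vc, 0)
  } else if (c0 > 0) {
    pmax(v0 - c0 * tau, 0)
  } else {
    rep(v0, length(tau))
  }
}

# times (relative to thrust-off) of coast transitions every d metres of arc,
# up to tau_end
.coast_transition_times <- function(v0, arm, d, tau_end) {
  if (!is.finite(tau_end) || tau_end <= 0 || v0 <= 0) return(numeric(0))
  S <- .coast_arc(v0, arm, tau_end)
  K <- floor(S / d + 1e-9)
  if (K < 1) return(numeric(0))
  k <- seq_len(K)
  c0 <- arm$c0; c1 <- arm$c1
  if (c1 == 0 && c0 > 0) {
    disc <- pmax(v0^2 - 2 * c0 * k * d, 0)
    return((v0 - sqrt(disc)) / c0)
  }
  if (c1 == 0 && c0 == 0) return(k * d / v0)
  # exponential drag: Newton from below on the concave arc function
  tau <- k * d / v0
  for (it in 1:60) {
    f <- .coast_arc(v0, arm, tau) - k * d
    v <- .coast_speed(v0, arm, tau)
    v <- pmax(v, 1e-9)
    step <- f / v
    tau <- tau - step
    if (max(abs(step)) < 1e-12) break
  }
  pmin(pmax(tau, 0), tau_end)
}

# ---- transition rendering -------------------------------------------------

#' Render a bout schedule into a raw transition stream
#'
#' Integrates the arm's motion under each bout's trapezoidal thrust profile
#' (thrust-limited ramp, plateau, thrust-off) and the no-load drag
#' `decel(v)`, emitting one transition per sector width of arc, including the
#' coast-down after thrust ends. Optionally injects hardware noise: isolated
#' direction glitches, low-speed rocking episodes during idle gaps
#' (alternating sense below the flight threshold), Gaussian timestamp jitter
#' and polling quantisation. Ground truth records, per bout, the thrust-off
#' time, the time the coasting arm drops below the unconditional flight
#' threshold `v_high` (the behavioural end of the flight as the decoder can
#' see it) and the transition count up to that point, plus the injected
#' artifact catalog.
#'
#' @param bouts A bout schedule from [simulate_bouts()].
#' @param scenario A [sim_scenario()].
#' @param fly_id Identifier for the emitted log.
#' @param noise Inject glitches/rocking/jitter per the scenario? Default TRUE;
#'   FALSE renders a noiseless stream.
#' @param seed Optional seed for the noise substream.
#' @param v_high Speed at which the coasting arm stops looking like flight,
#'   m/s. Default 0.20.
#' @return A list: `log` (a [raw_event_log()]) and `truth` (list with `bouts`
#'   data.frame -- `start`, `thrust_off`, `flight_end`, `n_transitions`,
#'   `n_to_flight_end` --, totals `distance`, `flight_time`, `n_bouts`, and
#'   the `glitch_times` / `rocking` catalogs).
#' @export
render_transitions <- function(bouts, scenario, fly_id = "fly", noise = TRUE,
                               seed = NULL, v_high = 0.20) {
  if (!is.null(seed)) set.seed(seed)
  geom <- scenario$geometry
  d <- distance_per_transition(geom)
  arm <- scenario$arm
  T <- scenario$trial_duration
  v_min <- d / 5  # below one transition per 5 s the arm is effectively stopped
  nb <- nrow(bouts)

  t_all <- numeric(0); sense_all <- numeric(0); owner <- integer(0)
  truth_rows <- vector("list", nb)
  busy <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nb)) {
    v <- bouts$speed[i]; start <- bouts$start[i]; dur <- bouts$duration[i]
    a_r <- scenario$ramp_accel
    t_ramp <- v / a_r
    if (dur < t_ramp) { t_ramp <- dur; v <- a_r * dur }
    s_ramp <- a_r * t_ramp^2 / 2
    S_thrust <- s_ramp + v * (dur - t_ramp)
    k <- seq_len(floor(S_thrust / d + 1e-9))
    tt <- ifelse(k * d <= s_ramp,
                 sqrt(2 * k * d / a_r),
                 t_ramp + (k * d - s_ramp) / v)
    thrust_off <- start + dur
    # coast: until the arm is effectively stopped, the next bout begins, or
    # the trial ends
    next_start <- if (i < nb) bouts$start[i + 1L] else T
    tau_stop <- .coast_time_to(v, arm, v_min)
    tau_end <- min(tau_stop, next_start - thrust_off, T - thrust_off)
    tau_end <- max(tau_end, 0)
    ct <- .coast_transition_times(v, arm, d, tau_end)
    times <- c(start + tt, thrust_off + ct)
    times <- times[times <= T]
    # behavioural flight end: coast crossing of v_high (truncated coasts end
    # at the truncation)
    tau_cross <- if (v > v_high) min(.coast_time_to(v, arm, v_high), tau_end)
                 else 0
    flight_end <- thrust_off + tau_cross
    truth_rows[[i]] <- data.frame(
      start = start, thrust_off = thrust_off, flight_end = flight_end,
      speed = v, n_transitions = length(times),
      n_to_flight_end = sum(times <= flight_end + 1e-12)
    )
    t_all <- c(t_all, times)
    sense_all <- c(sense_all, rep(1L, length(times)))
    owner <- c(owner, rep(i, length(times)))
    busy <- rbind(busy, c(start, thrust_off + tau_end))
  }
  truth_bouts <- if (nb) do.call(rbind, truth_rows) else
    data.frame(start = numeric(0), thrust_off = numeric(0),
               flight_end = numeric(0), speed = numeric(0),
               n_transitions = integer(0), n_to_flight_end = integer(0))

  rocking <- data.frame(start = numeric(0), end = numeric(0),
                        n = integer(0))
  glitch_times <- numeric(0)
  if (noise) {
    # rocking episodes in idle gaps
    gaps <- cbind(c(0, busy[, 2]), c(busy[, 1], T))
    gaps <- gaps[gaps[, 2] - gaps[, 1] > 15, , drop = FALSE]
    period <- d / scenario$rocking_speed
    for (gi in seq_len(nrow(gaps))) {
      L <- gaps[gi, 2] - gaps[gi, 1]
      n_ep <- stats::rpois(1, L / 3600 * scenario$rocking_per_hour)
      for (ep in seq_len(n_ep)) {
        len <- 4L + 2L * stats::rpois(1, 2)
        ivals <- period * stats::rlnorm(len, 0, 0.2)
        span <- sum(ivals)
        if (span + 4 > L) next
        t0 <- stats::runif(1, gaps[gi, 1] + 2, gaps[gi, 2] - 2 - span)
        tt <- t0 + cumsum(ivals)
        s0 <- sample(c(-1L, 1L), 1)
        ss <- rep_len(c(s0, -s0), len)
        t_all <- c(t_all, tt); sense_all <- c(sense_all, ss)
        owner <- c(owner, rep(0L, len))
        rocking <- rbind(rocking,
                         data.frame(start = tt[1], end = tt[len], n = len))
      }
    }
    ord <- order(t_all)
    t_all <- t_all[ord]; sense_all <- as.integer(sense_all[ord])
    # direction glitches
    if (scenario$glitch_rate > 0 && length(t_all)) {
      hit <- which(stats::runif(length(t_all)) < scenario$glitch_rate)
      sense_all[hit] <- -sense_all[hit]
      glitch_times <- t_all[hit]
    }
    # timestamp jitter + polling quantisation
    if (scenario$jitter_sd > 0) {
      t_all <- t_all + stats::rnorm(length(t_all), 0, scenario$jitter_sd)
    }
    if (scenario$polling > 0) {
      t_all <- round(t_all / scenario$polling) * scenario$polling
    }
    t_all <- pmin(pmax(t_all, 0), T)
    # restore strict monotonicity where jitter/quantisation collided
    if (length(t_all) > 1L) {
      for (rep_i in 1:5) {
        bad <- which(diff(t_all) <= 0)
        if (!length(bad)) break
        t_all[bad + 1L] <- t_all[bad] + max(scenario$polling, 1e-6)
      }
      ord <- order(t_all)
      t_all <- t_all[ord]; sense_all <- sense_all[ord]
    }
  } else {
    ord <- order(t_all)
    t_all <- t_all[ord]; sense_all <- as.integer(sense_all[ord])
  }

  log <- raw_event_log(fly_id, t_all, sense_all, trial_duration = T)
  truth <- list(
    bouts = truth_bouts,
    n_bouts = nb,
    distance = sum(truth_bouts$n_to_flight_end) * d,
    flight_time = sum(truth_bouts$flight_end - truth_bouts$start),
    glitch_times = glitch_times,
    rocking = rocking
  )
  list(log = log, truth = truth)
}

#' Simulate a free spin-down trial of the arm
#'
#' Starts the unloaded arm at `v0` and lets drag bring it to rest, emitting
#' transitions until the speed drops below one transition per 5 seconds.
#' Used to calibrate [estimate_no_load_decel()].
#'
#' @param geometry A [mill_geometry()].
#' @param arm A [decel_model()].
#' @param v0 Initial speed, m/s (> 0).
#' @param seed Optional seed (for timestamp jitter).
#' @param jitter_sd Gaussian timestamp jitter, s. Default 0 (noiseless).
#' @param fly_id Identifier for the log. Default "spin_down".
#' @return A [raw_event_log()] (trial duration set to cover the decay).
#' @export
simulate_spin_down <- function(geometry = mill_geometry(),
                               arm = decel_model(), v0 = 2, seed = NULL,
                               jitter_sd = 0, fly_id = "spin_down") {
  stopifnot(v0 > 0)
  if (!is.null(seed)) set.seed(seed)
  d <- distance_per_transition(geometry)
  v_min <- d / 5
  tau_end <- .coast_time_to(v0, arm, v_min)
  if (!is.finite(tau_end)) tau_end <- 600  # frictionless arm: cap the record
  tt <- .coast_transition_times(v0, arm, d, tau_end)
  if (jitter_sd > 0 && length(tt)) {
    tt <- sort(tt + stats::rnorm(length(tt), 0, jitter_sd))
    tt <- tt[tt > 0]
    tt <- tt[c(TRUE, diff(tt) > 0)]
  }
  t_last <- if (length(tt)) tt[length(tt)] else 1
  raw_event_log(fly_id, tt, rep(1L, length(tt)),
                trial_duration = max(tau_end, t_last) + 1)
}

#' Simulate morphometric measurements
#'
#' Draws size/condition categories (frequencies following the published
#' specimen table, lightly smoothed so unobserved cells remain possible) and
#' generates dry mass as the published additive cell estimate plus Gaussian
#' noise, and wing length as the published size mean plus Gaussian noise.
#' Supports testing linear-model recovery of the morphometric table
#' structure.
#'
#' @param n Number of specimens.
#' @param seed Optional seed.
#' @param mass_sd Residual sd of dry mass, mg. Default 1.5 (consistent with
#'   the printed cell standard errors at the specimen counts).
#' @param wing_sd Residual sd of wing length, mm. Default 0.25.
#' @return A data.frame: `size`, `condition`, `dry_mass_mg`,
#'   `wing_length_mm`.
#' @export
simulate_morphometrics <- function(n, seed = NULL, mass_sd = 1.5,
                                   wing_sd = 0.25) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  fixtures <- flight_models()
  dm <- do.call(rbind, lapply(fixtures$morphometrics$dry_mass$cells,
                              as.data.frame))
  wl <- do.call(rbind, lapply(fixtures$morphometrics$wing_length$cells,
                              as.data.frame))
  cell <- sample(nrow(dm), n, replace = TRUE, prob = dm$n_obs + 0.5)
  size <- dm$size[cell]
  condition <- dm$condition[cell]
  mass <- dm$estimate[cell] + stats::rnorm(n, 0, mass_sd)
  wing <- wl$estimate[match(size, wl$size)] + stats::rnorm(n, 0, wing_sd)
  data.frame(size = size, condition = condition,
             dry_mass_mg = pmax(mass, 0.1), wing_length_mm = pmax(wing, 0.5))
}

#' Simulate a full synthetic cohort
#'
#' Builds the cohort metadata from the published group design (scaled to
#' `n_flies`), then per fly draws a bout schedule and renders it to a raw
#' transition stream. Every fly uses its own seed substream derived from
#' `seed`, so cohorts are reproducible and extensible without perturbing
#' existing flies.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer base seed.
#' @param noise Inject hardware noise? Default TRUE.
#' @return A list: `metadata` (see [fly_metadata()]), `logs` (named list of
#'   [raw_event_log()]), `truth` (named list of per-fly ground truth, see
#'   [render_transitions()]).
#' @export
simulate_cohort <- function(scenario = sim_scenario(), seed = 1,
                            noise = TRUE) {
  design <- .allocate_design(scenario$n_flies)
  set.seed(seed %% .Machine$integer.max)
  meta <- design[rep(seq_len(nrow(design)), design$n_alloc),
                 c("direction", "morph", "condition", "mean_distance")]
  rownames(meta) <- NULL
  # size frequencies follow the direction margins of the published design
  meta$size <- NA_character_
  for (dir in names(.size_margins)) {
    idx <- which(meta$direction == dir)
    m <- .size_margins[[dir]]
    pool <- sample(rep(names(m), times = ceiling(m / sum(m) * length(idx) + 1)))
    meta$size[idx] <- pool[seq_along(idx)]
  }
  meta$sex <- ifelse(stats::runif(nrow(meta)) < .sex_p_male[meta$morph],
                     "male", "female")
  meta$fly_id <- sprintf("fly%03d", seq_len(nrow(meta)))
  meta <- fly_metadata(meta[, c("fly_id", "morph", "condition", "size", "sex",
                                "direction", "mean_distance")])

  logs <- vector("list", nrow(meta))
  truth <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    fly_seed <- (seed + 104729 * i) %% 2147483647L
    bouts <- simulate_bouts(scenario, mean_distance = meta$mean_distance[i],
                            seed = fly_seed)
    r <- render_transitions(bouts, scenario, fly_id = meta$fly_id[i],
                            noise = noise)
    logs[[i]] <- r$log
    truth[[i]] <- r$truth
  }
  names(logs) <- names(truth) <- meta$fly_id
  list(metadata = meta, logs = logs, truth = truth)
}
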