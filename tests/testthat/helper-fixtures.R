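# Shared fixture builders. All synthetic, generated in code at test time.

default_geom <- mill_geometry()
dpt <- distance_per_transition(default_geom)

# forward transition stream at constant speed v over [t0, t0 + duration]
constant_speed_log <- function(v, duration, t0 = 0, trial_duration = 14400,
                               fly_id = "const") {
  tt <- seq(t0 + dpt / v, t0 + duration, by = dpt / v)
  raw_event_log(fly_id, tt, rep(1L, length(tt)),
                trial_duration = trial_duration)
}

# slow alternating-sense stream (arm rocking)
rocking_log <- function(n = 20, period = 0.7, t0 = 10,
                        trial_duration = 14400) {
  tt <- t0 + seq_len(n) * period
  raw_event_log("rock", tt, rep_len(c(1L, -1L), n),
                trial_duration = trial_duration)
}

# small quiet scenario for fast module tests
tiny_scenario <- function(n_flies = 8, ...) {
  sim_scenario(n_flies = n_flies, ...)
}

# single-bout schedule in the shape simulate_bouts() returns
one_bout <- function(start, duration, speed) {
  data.frame(start = start, duration = duration, speed = speed)
}

# expand the published 12-cell design into a 141-row covariate table
design_cohort_table <- function() {
  g <- cohort_design()
  g[rep(seq_len(nrow(g)), g$n), c("direction", "morph", "condition")]
}
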