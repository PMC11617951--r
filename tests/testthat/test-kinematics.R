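test_that("direction pass repairs isolated reversals and spares rocking", {
  # clean uniform stream: untouched, empty report
  clean <- constant_speed_log(0.6, 30)
  r <- correct_direction_errors(clean)
  expect_equal(nrow(r$report), 0L)
  expect_equal(r$log$events, clean$events)

  # [+,+,-,+,+] at 20 Hz: the middle event cannot be a physical reversal of
  # an arm spinning at ~0.7 m/s
  lg <- raw_event_log("f", seq(0.05, by = 0.05, length.out = 9),
                      c(1, 1, 1, 1, -1, 1, 1, 1, 1))
  r <- correct_direction_errors(lg)
  expect_equal(r$report$row, 5L)
  expect_equal(r$report$new_sense, 1L)
  expect_true(all(r$log$events$sense == 1L))

  # slow alternating stream (arm rocking): preserved
  rock <- rocking_log(n = 24)
  r <- correct_direction_errors(rock)
  expect_equal(nrow(r$report), 0L)
  expect_equal(r$log$events$sense, rock$events$sense)

  # length-2 reversal run inside a fast stream is also repaired
  s <- rep(1L, 12); s[6:7] <- -1L
  lg2 <- raw_event_log("f", seq(0.05, by = 0.05, length.out = 12), s)
  r2 <- correct_direction_errors(lg2)
  expect_equal(sort(r2$report$row), c(6L, 7L))

  # empty log passes through
  r3 <- correct_direction_errors(raw_event_log("e", numeric(0), integer(0)))
  expect_equal(nrow(r3$report), 0L)
})

test_that("acceleration pass restores glitched timestamps from flanking data", {
  v <- 1.0
  tt <- seq(dpt / v, 40, by = dpt / v)
  n <- length(tt)
  lg <- raw_event_log("f", tt, rep(1L, n), 100)

  # clean constant-speed series: unchanged (idempotent)
  r0 <- smooth_acceleration_outliers(lg)
  expect_equal(nrow(r0$report), 0L)
  expect_equal(r0$log$events$t_s, tt)

  # one timestamp shifted enough to imply ~100 m/s^2: restored
  tt1 <- tt; tt1[400] <- tt[400] + 0.02
  r1 <- smooth_acceleration_outliers(raw_event_log("f", tt1, rep(1L, n), 100))
  expect_gt(nrow(r1$report), 0L)
  sp <- compute_kinematics(r1$log)$speed
  expect_lt(max(abs(sp[-1] - v) / v), 0.10)

  # two adjacent glitches: both repaired using flanking data
  tt2 <- tt; tt2[200] <- tt[200] + 0.02; tt2[201] <- tt[201] - 0.015
  r2 <- smooth_acceleration_outliers(raw_event_log("f", tt2, rep(1L, n), 100))
  sp2 <- compute_kinematics(r2$log)$speed
  expect_lt(max(abs(sp2[-1] - v) / v), 0.10)

  # repairing a repaired stream changes nothing further
  r3 <- smooth_acceleration_outliers(r1$log)
  expect_equal(nrow(r3$report), 0L)
})

test_that("kinematic series recovers speed, residual speed and insect acceleration", {
  # constant speed: speed exact, residual ~ 0 after one-rotation warm-up
  lg <- constant_speed_log(0.6, 60)
  ks <- compute_kinematics(lg)
  expect_equal(ks$speed[-1], rep(0.6, nrow(ks) - 1), tolerance = 1e-9)
  expect_lt(max(abs(ks$residual_speed[-(1:17)])), 1e-9)

  # coasting arm: drag cancels, insect acceleration ~ 0 and below 0.05
  arm <- decel_model(0.05, 0.5)
  sp <- simulate_spin_down(arm = arm, v0 = 2)
  ks <- compute_kinematics(sp, config = kinematics_config(no_load = arm))
  ia <- ks$insect_accel[!is.na(ks$insect_accel)]
  expect_lt(max(abs(ia)), 0.05)
  expect_lt(abs(mean(ia)), 0.01)

  # commanded trapezoid: the decoded acceleration recovers the commanded ramp
  # within discretisation error, and the drag correction is exactly additive
  sc <- sim_scenario(arm = arm, ramp_accel = 2)
  r <- render_transitions(one_bout(100, 60, 1.2), sc, noise = FALSE)
  ks <- compute_kinematics(r$log, config = kinematics_config(no_load = arm))
  ramp <- which(ks$t_s > 100.2 & ks$t_s < 100 + 1.2 / 2 - 0.1 &
                  !is.na(ks$observed_accel))
  expect_equal(mean(ks$observed_accel[ramp]), 2, tolerance = 0.15)
  expect_equal(ks$insect_accel[ramp],
               ks$observed_accel[ramp] + decelerate(arm, ks$speed[ramp]),
               tolerance = 1e-12)
  # during the plateau the insect's thrust exactly balances drag, so the
  # insect acceleration reads as decel(v)
  plateau <- which(ks$t_s > 102 & ks$t_s < 159)
  expect_equal(mean(ks$insect_accel[plateau]), decelerate(arm, 1.2),
               tolerance = 0.05)

  # degenerate input
  expect_equal(nrow(compute_kinematics(raw_event_log("e", 1, 1L))), 0L)
})

test_that("no-load deceleration is recovered from spin-down trials", {
  # mixed friction + drag within 10%
  est <- estimate_no_load_decel(simulate_spin_down(arm = decel_model(0.05, 0.5),
                                                   v0 = 2))
  expect_equal(est$model$c0, 0.05, tolerance = 0.10)
  expect_equal(est$model$c1, 0.5, tolerance = 0.10)

  # frictionless: both terms ~ 0
  est0 <- estimate_no_load_decel(simulate_spin_down(arm = decel_model(0, 0),
                                                    v0 = 1))
  expect_lt(est0$model$c0, 1e-6)
  expect_lt(est0$model$c1, 1e-6)

  # pure linear drag: c0 ~ 0 and the decay is exponential
  arm <- decel_model(0, 0.4)
  sp <- simulate_spin_down(arm = arm, v0 = 2)
  est1 <- estimate_no_load_decel(sp)
  expect_lt(est1$model$c0, 0.01)
  expect_equal(est1$model$c1, 0.4, tolerance = 0.10)
  # interval speeds track the analytic decay while intervals stay short
  # relative to the decay timescale
  ks <- compute_kinematics(sp)
  ok <- !is.na(ks$speed) & ks$speed > 0.2
  pred <- 2 * exp(-0.4 * (ks$t_s[ok] - ks$dt[ok] / 2))
  expect_lt(max(abs(ks$speed[ok] - pred) / pred), 0.02)

  # too little data
  expect_error(
    estimate_no_load_decel(raw_event_log("s", c(1, 2, 3), c(1L, 1L, 1L))),
    "insufficient"
  )
})

test_that("correction passes are no-ops on clean simulated streams", {
  coh <- simulate_cohort(tiny_scenario(3), seed = 8, noise = FALSE)
  for (lg in coh$logs) {
    p1 <- correct_direction_errors(lg)
    expect_equal(nrow(p1$report), 0L)
    p2 <- smooth_acceleration_outliers(p1$log)
    expect_equal(nrow(p2$report), 0L)
    expect_equal(p2$log$events$t_s, lg$events$t_s)
  }
})
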