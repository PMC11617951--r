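test_that("seeded simulations are byte-reproducible", {
  a <- simulate_cohort(tiny_scenario(3), seed = 7, noise = TRUE)
  b <- simulate_cohort(tiny_scenario(3), seed = 7, noise = TRUE)
  expect_identical(lapply(a$logs, `[[`, "events"),
                   lapply(b$logs, `[[`, "events"))
  expect_identical(a$metadata, b$metadata)
  c2 <- simulate_cohort(tiny_scenario(3), seed = 8, noise = TRUE)
  expect_false(identical(a$logs[[1]]$events, c2$logs[[1]]$events))
})

test_that("zero occupancy yields zero bouts", {
  sc <- sim_scenario(p_start = 0, p_end = 0)
  bouts <- simulate_bouts(sc, mean_distance = 500, seed = 4)
  expect_equal(nrow(bouts), 0L)
  r <- render_transitions(bouts, sc, noise = FALSE)
  expect_equal(nrow(r$log$events), 0L)
  expect_equal(r$truth$n_bouts, 0L)
})

test_that("rendered transition counts follow arc-length counting", {
  sc <- sim_scenario()
  r <- render_transitions(one_bout(10, 45, 0.8), sc, noise = FALSE)
  # thrust-phase transitions: floor(arc / sector width) +- 1, where the ramp
  # replaces the first ramp-time seconds of plateau travel
  v <- 0.8; a <- sc$ramp_accel
  arc <- v^2 / (2 * a) + v * (45 - v / a)
  n_thrust <- sum(r$log$events$t_s <= 55)
  expect_lte(abs(n_thrust - floor(arc / dpt)), 1)
  # constant-speed check without ramp correction at coarser tolerance
  expect_equal(n_thrust * dpt, arc, tolerance = 0.01)
  # coast appends further transitions with growing intervals
  coast_t <- r$log$events$t_s[r$log$events$t_s > 55]
  expect_gt(length(coast_t), 1)
  expect_true(all(diff(diff(coast_t)) > -1e-9))
})

test_that("spin-down logs follow the closed-form arm physics", {
  # linear drag: exponential decay of inter-transition speeds
  arm <- decel_model(0, 0.5)
  lg <- simulate_spin_down(arm = arm, v0 = 2)
  t <- lg$events$t_s
  v_obs <- dpt / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  v_true <- 2 * exp(-0.5 * tm)
  expect_lt(max(abs(v_obs - v_true) / v_true), 0.02)

  # pure friction: linear decay, stop by v0/c0
  arm2 <- decel_model(0.2, 0)
  lg2 <- simulate_spin_down(arm = arm2, v0 = 1)
  expect_lt(max(lg2$events$t_s), 1 / 0.2 + 1e-9)
  # starting below one transition per 5 s: (near-)empty log
  lg3 <- simulate_spin_down(arm = arm2, v0 = dpt / 5 * 0.9)
  expect_lte(nrow(lg3$events), 1L)
  # round trip through the estimator recovers the arm within 10%
  est <- estimate_no_load_decel(simulate_spin_down(arm = decel_model(0.05, 0.5),
                                                   v0 = 2.5))
  expect_equal(est$model$c0, 0.05, tolerance = 0.1)
  expect_equal(est$model$c1, 0.5, tolerance = 0.1)
})

test_that("noiseless rendering leaves no work for the correction passes", {
  coh <- simulate_cohort(tiny_scenario(2), seed = 19, noise = FALSE)
  for (lg in coh$logs) {
    expect_equal(nrow(correct_direction_errors(lg)$report), 0L)
  }
  # with glitches disabled but other noise on, pass-1 reports stay empty on
  # rock-free streams
  sc <- sim_scenario(glitch_rate = 0, rocking_per_hour = 0)
  bouts <- simulate_bouts(sc, mean_distance = 1000, seed = 5)
  r <- render_transitions(bouts, sc, noise = TRUE, seed = 5)
  expect_equal(nrow(correct_direction_errors(r$log)$report), 0L)
})

test_that("simulated bout counts match the published range", {
  sc <- sim_scenario()
  counts <- vapply(1:141, function(i) {
    nrow(simulate_bouts(sc, mean_distance = 1000, seed = 1000 + i))
  }, integer(1))
  expect_gte(mean(counts >= 1 & counts <= 216), 0.99)
})

test_that("morphometric draws reproduce the published table structure", {
  # zero noise: exact published cells
  m0 <- simulate_morphometrics(60, seed = 2, mass_sd = 0, wing_sd = 0)
  i <- which(m0$condition == "medium" & m0$size == "small")
  expect_true(length(i) > 0)
  expect_equal(unique(m0$dry_mass_mg[i]), 7.5)
  expect_equal(unique(m0$wing_length_mm[m0$size == "large"]), 5.84)

  # additive linear-model refit on a large draw recovers the cell means
  m <- simulate_morphometrics(1000, seed = 3)
  fit <- lm(dry_mass_mg ~ condition + size, data = m)
  pred <- predict(fit, expand.grid(condition = c("thin", "medium", "fat"),
                                   size = c("small", "moderate", "large")),
                  se.fit = TRUE)
  truth <- prediction_tables()$dry_mass
  truth <- truth[order(truth$size, truth$condition), ]
  grid <- expand.grid(condition = c("thin", "medium", "fat"),
                      size = c("small", "moderate", "large"))
  truth_ord <- vapply(seq_len(9), function(i) {
    truth$fit[truth$condition == grid$condition[i] & truth$size == grid$size[i]]
  }, numeric(1))
  expect_true(all(abs(pred$fit - truth_ord) <= 2 * pred$se.fit + 0.15))
})
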