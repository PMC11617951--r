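test_that("orthonormal polynomial contrasts have the defining properties", {
  cm <- poly_contrasts()
  # frozen values from Gram-Schmidt orthonormalisation of centred (1,2,3)
  expect_equal(cm[, "linear"], c(-0.70710678, 0, 0.70710678),
               tolerance = 1e-7)
  expect_equal(cm[, "quadratic"], c(0.40824829, -0.81649658, 0.40824829),
               tolerance = 1e-7)
  # zero-sum, orthogonal, unit norm, linear strictly increasing
  expect_equal(colSums(cm), c(linear = 0, quadratic = 0), tolerance = 1e-12)
  expect_equal(sum(cm[, 1] * cm[, 2]), 0, tolerance = 1e-12)
  expect_equal(colSums(cm^2), c(linear = 1, quadratic = 1), tolerance = 1e-12)
  expect_true(all(diff(cm[, "linear"]) > 0))
  # agrees with the standard reference implementation
  expect_equal(unname(cm), unname(stats::contr.poly(3)), tolerance = 1e-12)
  expect_error(poly_contrasts(4), "only 3-level")
})

test_that("design rows encode baselines, contrasts and interactions", {
  fx <- flight_models()
  spec <- fx$models$distance
  r <- design_row(list(morph = "summer", direction = "anti-clockwise",
                       condition = "thin"), spec)
  expect_equal(unname(r), c(1, 0, 0, -0.70710678, 0.40824829),
               tolerance = 1e-7)
  r2 <- design_row(list(morph = "autumn", direction = "clockwise",
                        condition = "fat"), spec)
  expect_equal(unname(r2), c(1, 1, 1, 0.70710678, 0.40824829),
               tolerance = 1e-7)
  r3 <- design_row(list(morph = "summer", direction = "anti-clockwise",
                        condition = "medium"), spec)
  expect_equal(unname(r3[4:5]), c(0, -0.81649658), tolerance = 1e-7)
  # interactions multiply: autumn x condition_linear in the initiation model
  ri <- design_row(list(morph = "autumn", condition = "fat"),
                   fx$models$flight_initiation)
  expect_equal(unname(ri[["morph_autumn:condition_linear"]]), 0.70710678,
               tolerance = 1e-7)
  expect_error(design_row(list(morph = "summer", direction = "anti-clockwise",
                               condition = "plump"), spec), "unknown")
})

test_that("back-transformed group predictions reproduce the published tables", {
  tabs <- prediction_tables()
  # spot values, printed to 1 dp / 3 dp
  cell <- function(tab, ...) {
    sel <- Reduce(`&`, Map(function(col, val) tab[[col]] == val,
                           names(list(...)), list(...)))
    tab$fit[sel]
  }
  expect_equal(cell(tabs$distance, direction = "anti-clockwise",
                    morph = "summer", condition = "thin"),
               171.8, tolerance = 0.02)
  expect_equal(cell(tabs$distance, direction = "clockwise",
                    morph = "autumn", condition = "fat"),
               3367.1, tolerance = 0.02)
  expect_equal(cell(tabs$mean_speed, direction = "anti-clockwise",
                    size = "small"), 0.461, tolerance = 0.02)
  expect_equal(cell(tabs$flight_initiation, morph = "summer",
                    condition = "thin"), 3443, tolerance = 0.01)
  expect_equal(cell(tabs$flight_initiation, morph = "summer",
                    condition = "fat"), 407, tolerance = 0.01)

  # every published cell within 2% (printed coefficients are rounded);
  # ordering follows the prediction grid (direction fastest, then morph)
  printed_distance <- c(171.8, 339.2, 371.0, 732.6, 482.1, 951.8, 1041.2,
                        2055.8, 789.6, 1559.0, 1705.4, 3367.1)
  expect_equal(tabs$distance$fit, printed_distance, tolerance = 0.02)
  printed_speed <- c(0.461, 0.528, 0.651, 0.744, 0.674, 0.771)
  expect_equal(tabs$mean_speed$fit, printed_speed, tolerance = 0.02)
  printed_init <- c(3443, 1175, 1389, 641, 407, 571)
  expect_equal(tabs$flight_initiation$fit, printed_init, tolerance = 0.011)

  # block shapes
  expect_equal(nrow(tabs$distance), 12L)
  expect_equal(nrow(tabs$mean_speed), 6L)
  expect_equal(nrow(tabs$flight_initiation), 6L)
  expect_equal(nrow(tabs$dry_mass), 9L)
  expect_equal(nrow(tabs$wing_length), 3L)
})

test_that("morphometric blocks are additive as published", {
  tabs <- prediction_tables()
  dm <- tabs$dry_mass
  # no interaction: the fat-minus-medium difference is constant across sizes
  diffs <- vapply(c("small", "moderate", "large"), function(sz) {
    dm$fit[dm$condition == "fat" & dm$size == sz] -
      dm$fit[dm$condition == "medium" & dm$size == sz]
  }, numeric(1))
  expect_lt(diff(range(diffs)), 1e-9)
  expect_equal(unname(diffs[1]), 4.0, tolerance = 0.05)
  # medium/small cell matches the printed 7.5 within printed precision
  expect_equal(dm$fit[dm$condition == "medium" & dm$size == "small"], 7.5,
               tolerance = 0.01)
  expect_equal(tabs$wing_length$fit, c(4.95, 5.45, 5.84))
})

test_that("the printed effect sizes follow from the model coefficients", {
  fx <- flight_models()
  b <- fx$models$distance$coefficients
  cm <- poly_contrasts()
  # fat:thin distance ratio: the quadratic term cancels
  ratio <- unname(exp(b[["condition_linear"]] *
                        (cm[3, "linear"] - cm[1, "linear"])))
  expect_equal(ratio, exp(b[["condition_linear"]] * sqrt(2)))
  expect_equal(round(ratio, 1), 4.6)
  # clockwise vs anti-clockwise: +97% distance, +14% speed
  expect_equal(round(100 * (exp(b[["direction_clockwise"]]) - 1)), 97)
  s <- fx$models$mean_speed$coefficients
  expect_equal(round(100 * (exp(s[["direction_clockwise"]]) - 1)), 14)
})

test_that("IRLS Gamma fitting agrees with closed forms and the reference GLM", {
  set.seed(31)
  # intercept-only: coefficient is log of the sample mean
  y <- rgamma(80, shape = 2, scale = 3)
  f0 <- fit_gamma_glm_log(matrix(1, 80, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(unname(f0$coefficients), log(mean(y)), tolerance = 1e-9)

  # cross-implementation agreement to 1e-6 on a fixed dataset
  X <- cbind("(Intercept)" = 1, x1 = rnorm(150), x2 = rbinom(150, 1, 0.4))
  mu <- exp(0.5 + 0.8 * X[, "x1"] - 0.6 * X[, "x2"])
  y <- rgamma(150, shape = 1.5, scale = mu / 1.5)
  fit <- fit_gamma_glm_log(X, y)
  ref <- stats::glm(y ~ x1 + x2, data = data.frame(X), family = Gamma("log"),
                    control = stats::glm.control(epsilon = 1e-12))
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-6)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
  expect_equal(fit$null_deviance, ref$null.deviance, tolerance = 1e-8)
  expect_equal(fit$dispersion, summary(ref)$dispersion, tolerance = 1e-6)

  # rescaling equivariance: y -> c*y shifts only the intercept by log(c)
  fit2 <- fit_gamma_glm_log(X, 10 * y)
  expect_equal(unname(fit2$coefficients - fit$coefficients),
               c(log(10), 0, 0), tolerance = 1e-7)

  # contract errors
  expect_error(fit_gamma_glm_log(X, c(y[-1], -1)), "positive")
  expect_error(fit_gamma_glm_log(cbind(X, x1b = X[, "x1"]), y),
               "rank deficient")
})

test_that("deviance pseudo-R2 is the explained-deviance fraction", {
  expect_equal(pseudo_r2(10, 10), 0)
  expect_equal(pseudo_r2(10, 0), 1)
  expect_error(pseudo_r2(0, 0), "undefined")
  expect_error(pseudo_r2(10, -1), "non-negative")
  # matches a hand-computed deviance ratio on a synthetic cohort fit
  set.seed(33)
  dat <- design_cohort_table()
  fx <- flight_models()
  spec <- fx$models$distance
  X <- design_matrix(dat, names(spec$coefficients))
  y <- rgamma(nrow(X), shape = 1 / 2.29,
              scale = exp(drop(X %*% spec$coefficients)) * 2.29)
  fit <- fit_gamma_glm_log(X, y)
  expect_equal(pseudo_r2(fit$null_deviance, fit$deviance),
               1 - fit$deviance / fit$null_deviance)
  expect_gt(pseudo_r2(fit$null_deviance, fit$deviance), 0)
})

test_that("time-dependent published models have the reported shapes", {
  fx <- flight_models()
  act <- evaluate_time_models(fx$models$activity, 1:240,
                              list(morph = "autumn", condition = "fat"))
  # activity decays monotonically through the trial
  expect_true(all(diff(act$fit) < 0))
  expect_true(all(act$fit > 0 & act$fit < 1))

  sp_fat <- evaluate_time_models(fx$models$transect_speed, 1:240,
                                 list(morph = "autumn", condition = "fat",
                                      size = "moderate",
                                      direction = "clockwise"))
  sp_thin <- evaluate_time_models(fx$models$transect_speed, 1:240,
                                  list(morph = "autumn", condition = "thin",
                                       size = "moderate",
                                       direction = "clockwise"))
  # fat flies start faster than thin flies and converge by the end
  expect_gt(sp_fat$fit[1] / sp_thin$fit[1], 1.3)
  expect_lt(abs(log(sp_fat$fit[240] / sp_thin$fit[240])), 0.1)
  # domain contract
  expect_error(evaluate_time_models(fx$models$activity, 0,
                                    list(morph = "summer", condition = "fat")),
               "time")
  expect_error(evaluate_time_models(fx$models$activity, 300,
                                    list(morph = "summer", condition = "fat")),
               "time")
})
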