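#' Orthonormal polynomial contrasts for a 3-level ordered factor
#'
#' Splits an ordinal three-level factor (body condition thin/medium/fat, size
#' small/moderate/large) into a linear and a quadratic component. Columns are
#' built by Gram-Schmidt orthonormalisation of the centred level indices and
#' their squares: each column sums to zero, the two are orthogonal, and each
#' has unit Euclidean norm, so effects on the two components are directly
#' comparable.
#'
#' @param k Number of levels; only 3 is supported (the published models use
#'   only 3-level ordinal factors).
#' @return A 3 x 2 matrix with columns `linear` and `quadratic`.
#' @examples
#' poly_contrasts()
#' @export
poly_contrasts <- function(k = 3L) {
  if (k != 3L) stop("poly_contrasts: only 3-level ordinal factors are supported",
                    call. = FALSE)
  x <- seq_len(k)
  basis <- cbind(x - mean(x), (x - mean(x))^2)
  # Gram-Schmidt against the constant and each other, then normalise
  for (j in seq_len(ncol(basis))) {
    v <- basis[, j] - mean(basis[, j])
    if (j > 1L) {
      for (i in seq_len(j - 1L)) {
        v <- v - sum(v * basis[, i]) * basis[, i]
      }
    }
    basis[, j] <- v / sqrt(sum(v^2))
  }
  colnames(basis) <- c("linear", "quadratic")
  rownames(basis) <- NULL
  basis
}

#' Load the published model specifications
#'
#' Reads the versioned fixture of printed regression equations (coefficients,
#' standard errors, links, dispersions) and the morphometric prediction
#' tables.
#'
#' @param path Fixture path; defaults to the copy shipped with the package.
#' @return A list with `models` (named list of `model_spec` objects),
#'   `morphometrics`, `baselines` and `contrast_convention`.
#' @export
flight_models <- function(path = system.file("extdata", "models.yaml",
                                             package = "hovermill")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("model fixture not found", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  models <- lapply(names(raw$models), function(nm) {
    m <- raw$models[[nm]]
    structure(
      list(name = nm, link = m$link, family = m$family,
           coefficients = unlist(m$coefficients),
           se = unlist(m$se),
           dispersion = m$dispersion %||% NA_real_,
           n_obs = m$n_obs %||% NA_integer_,
           response = m$response, units = m$units),
      class = "model_spec"
    )
  })
  names(models) <- names(raw$models)
  list(models = models, morphometrics = raw$morphometrics,
       baselines = raw$baselines,
       contrast_convention = raw$contrast_convention)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s, %s link): %d coefficients\n",
              x$name, x$family, x$link, length(x$coefficients)))
  invisible(x)
}

# level lookup tables used by design construction
.ordinal_levels <- list(condition = c("thin", "medium", "fat"),
                        size = c("small", "moderate", "large"))

# value of one elementary design term for a covariate set
.design_term <- function(term, cov, contrasts) {
  switch(term,
    "(Intercept)" = 1,
    morph_autumn = as.numeric(as.character(cov$morph) == "autumn"),
    direction_clockwise = as.numeric(as.character(cov$direction) == "clockwise"),
    sex_female = as.numeric(as.character(cov$sex) == "female"),
    condition_linear = contrasts[match(as.character(cov$condition),
                                       .ordinal_levels$condition), "linear"],
    condition_quadratic = contrasts[match(as.character(cov$condition),
                                          .ordinal_levels$condition), "quadratic"],
    size_linear = contrasts[match(as.character(cov$size),
                                  .ordinal_levels$size), "linear"],
    size_quadratic = contrasts[match(as.character(cov$size),
                                     .ordinal_levels$size), "quadratic"],
    time = cov$time,
    time_log = if (!is.null(cov$time_log)) cov$time_log else log(cov$time),
    stop(sprintf("unknown design term '%s'", term), call. = FALSE)
  )
}

#' Build the design row for a covariate combination
#'
#' Maps covariates onto the coefficient names of a model spec: 0/1 indicators
#' for morph (baseline summer) and direction (baseline anti-clockwise),
#' orthonormal polynomial contrast values for condition and size, normalised
#' time and log-time where present, and products for interaction terms
#' (names joined with `:`).
#'
#' @param covariates A list or one-row data.frame with the covariates the
#'   model needs (`morph`, `condition`, `size`, `direction`, `time`, ...).
#' @param spec A `model_spec` from [flight_models()].
#' @param contrasts Contrast matrix from [poly_contrasts()].
#' @return Named numeric vector aligned with `spec$coefficients`.
#' @export
design_row <- function(covariates, spec, contrasts = poly_contrasts()) {
  cov <- as.list(covariates)
  for (nm in intersect(names(cov), c("condition", "size"))) {
    lv <- .ordinal_levels[[nm]]
    if (!as.character(cov[[nm]]) %in% lv) {
      stop(sprintf("unknown %s level '%s'", nm, cov[[nm]]), call. = FALSE)
    }
  }
  vals <- vapply(names(spec$coefficients), function(cf) {
    parts <- strsplit(cf, ":", fixed = TRUE)[[1L]]
    prod(vapply(parts, .design_term, numeric(1), cov = cov,
                contrasts = contrasts))
  }, numeric(1))
  vals
}

#' Build a design matrix from a covariate table
#'
#' Row-wise [design_row()] for fitting and prediction over many observations.
#'
#' @param data A data.frame of covariates.
#' @param coef_names Character vector of coefficient names (see
#'   [design_row()] for the naming scheme).
#' @param contrasts Contrast matrix from [poly_contrasts()].
#' @return A numeric matrix, `nrow(data)` x `length(coef_names)`.
#' @export
design_matrix <- function(data, coef_names, contrasts = poly_contrasts()) {
  fake_spec <- list(coefficients = stats::setNames(numeric(length(coef_names)),
                                                   coef_names))
  X <- t(vapply(seq_len(nrow(data)), function(i) {
    design_row(data[i, , drop = FALSE], fake_spec, contrasts)
  }, numeric(length(coef_names))))
  colnames(X) <- coef_names
  X
}

.linkinv <- function(link) {
  switch(link, log = exp, logit = stats::plogis, identity = identity,
         stop("unknown link: ", link, call. = FALSE))
}

#' Predict the response for one covariate combination
#'
#' Evaluates the linear predictor of a printed model and back-transforms it
#' through the inverse link (e.g. `exp` for the log-link Gamma models, as in
#' the published prediction tables). The standard error on the link scale is
#' propagated from the printed coefficient standard errors assuming
#' independence (coefficient covariances are unpublished), so it is
#' approximate.
#'
#' @param spec A `model_spec` from [flight_models()].
#' @param covariates Covariate list (see [design_row()]).
#' @param contrasts Contrast matrix from [poly_contrasts()].
#' @return A list: `eta` (linear predictor), `fit` (response scale),
#'   `se_link` (approximate SE of `eta`).
#' @export
predict_group <- function(spec, covariates, contrasts = poly_contrasts()) {
  row <- design_row(covariates, spec, contrasts)
  eta <- sum(spec$coefficients * row)
  se <- if (!is.null(spec$se) && length(spec$se) == length(row)) {
    sqrt(sum((spec$se * row)^2))
  } else NA_real_
  list(eta = eta, fit = .linkinv(spec$link)(eta), se_link = se)
}

#' Reproduce the published prediction tables
#'
#' Evaluates the printed models over the factorial covariate grids of the
#' published tables: distance (direction x morph x condition, 12 cells),
#' mean speed (direction x size, 6 cells), flight initiation
#' (morph x condition, 6 cells), and the morphometric blocks -- dry mass from
#' an additive condition + size linear model refit to the printed cell
#' estimates (no interaction), and wing length from its size-only model.
#'
#' @param fixtures Output of [flight_models()].
#' @return A named list of data.frames: `distance`, `mean_speed`,
#'   `flight_initiation`, `dry_mass`, `wing_length`.
#' @export
prediction_tables <- function(fixtures = flight_models()) {
  ms <- fixtures$models
  grid_predict <- function(spec, grid) {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      predict_group(spec, grid[i, , drop = FALSE])
    })
    grid$fit <- vapply(res, `[[`, numeric(1), "fit")
    grid$se_link <- vapply(res, `[[`, numeric(1), "se_link")
    grid
  }
  distance <- grid_predict(ms$distance, expand.grid(
    direction = c("anti-clockwise", "clockwise"),
    morph = c("summer", "autumn"),
    condition = c("thin", "medium", "fat"),
    stringsAsFactors = FALSE))
  speed <- grid_predict(ms$mean_speed, expand.grid(
    direction = c("anti-clockwise", "clockwise"),
    size = c("small", "moderate", "large"),
    stringsAsFactors = FALSE))
  initiation <- grid_predict(ms$flight_initiation, expand.grid(
    morph = c("summer", "autumn"),
    condition = c("thin", "medium", "fat"),
    stringsAsFactors = FALSE))

  dm_cells <- do.call(rbind, lapply(fixtures$morphometrics$dry_mass$cells,
                                    as.data.frame))
  dm_fit <- stats::lm(estimate ~ condition + size, data = dm_cells)
  dry_mass <- dm_cells[, c("condition", "size")]
  dry_mass$fit <- stats::predict(dm_fit, dry_mass)
  wl_cells <- do.call(rbind, lapply(fixtures$morphometrics$wing_length$cells,
                                    as.data.frame))
  wing_length <- data.frame(size = wl_cells$size, fit = wl_cells$estimate)

  list(distance = distance, mean_speed = speed, flight_initiation = initiation,
       dry_mass = dry_mass, wing_length = wing_length)
}

#' Fit a Gamma GLM with log link by IRLS
#'
#' Iteratively reweighted least squares for a Gamma-distributed positive
#' response with log link. For this link the IRLS working weights are
#' constant, so each step is an ordinary least-squares solve on the working
#' response `eta + (y - mu)/mu`. Iterates to a relative deviance change below
#' `tol` (default 1e-10, at most `max_iter` iterations). The dispersion is
#' the Pearson moment estimator; standard errors come from the usual
#' `phi * (X'X)^{-1}`.
#'
#' @param X Numeric design matrix (including the intercept column), full rank.
#' @param y Positive response vector.
#' @param tol Relative deviance convergence tolerance. Default 1e-10.
#' @param max_iter Maximum IRLS iterations. Default 100.
#' @return An object of class `gamma_glm`: `coefficients`, `se`, `dispersion`,
#'   `null_deviance`, `deviance`, `df_residual`, `fitted`, `iterations`,
#'   `converged`.
#' @export
fit_gamma_glm_log <- function(X, y, tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("fit_gamma_glm_log: response must be finite and positive",
         call. = FALSE)
  }
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design/response dimension mismatch", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) stop("fit_gamma_glm_log: design matrix is rank deficient",
                        call. = FALSE)
  gamma_dev <- function(mu) 2 * sum(-log(y / mu) + (y - mu) / mu)

  eta <- qr.fitted(qx, log(y))
  dev <- gamma_dev(exp(eta))
  beta <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta <- qr.coef(qx, z)
    eta_new <- drop(X %*% beta)
    dev_new <- gamma_dev(exp(eta_new))
    done <- abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol
    eta <- eta_new
    dev <- dev_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("fit_gamma_glm_log: IRLS did not converge in %d iterations",
                 max_iter), call. = FALSE)
  }
  mu <- exp(eta)
  phi <- sum(((y - mu) / mu)^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtXinv) * phi)
  names(se) <- names(beta) <- colnames(X)
  # intercept-only null fit: the log-link Gamma MLE of a constant mean is the
  # sample mean
  null_dev <- gamma_dev(rep(mean(y), n))
  structure(
    list(coefficients = beta, se = se, dispersion = phi,
         null_deviance = null_dev, deviance = dev, df_residual = n - p,
         fitted = mu, iterations = iter, converged = converged),
    class = "gamma_glm"
  )
}

#' @export
print.gamma_glm <- function(x, ...) {
  cat(sprintf("<gamma_glm> %d coefficients, dispersion %.3f, pseudo-R2 %.3f\n",
              length(x$coefficients), x$dispersion,
              pseudo_r2(x$null_deviance, x$deviance)))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Deviance pseudo-R-squared
#'
#' `1 - residual deviance / null deviance`: the fraction of the null deviance
#' explained by the model.
#'
#' @param null_deviance Null (intercept-only) deviance, > 0.
#' @param residual_deviance Residual deviance, in `[0, null_deviance]` for a
#'   nested comparison.
#' @return A fraction in `[0, 1]`.
#' @export
pseudo_r2 <- function(null_deviance, residual_deviance) {
  if (any(null_deviance <= 0)) {
    stop("pseudo_r2 is undefined for null deviance <= 0", call. = FALSE)
  }
  if (any(residual_deviance < 0)) {
    stop("residual deviance must be non-negative", call. = FALSE)
  }
  1 - residual_deviance / null_deviance
}

#' Evaluate time-dependent printed models over a minute grid
#'
#' Evaluates the fixed-effect linear predictor of the transect-speed
#' (log link) or activity (logit link) model over trial minutes for a fixed
#' covariate combination, and back-transforms to the response scale. Used for
#' trajectory plots and qualitative shape checks (activity decay, early-trial
#' speed decline).
#'
#' @param spec A `model_spec` with `time`/`time_log` terms.
#' @param minutes Integer minutes into the trial, each in `[1, n_minutes]`.
#' @param covariates Covariate list (morph, condition, size, direction as the
#'   model requires).
#' @param n_minutes Minutes in the trial. Default 240.
#' @return A data.frame `minute`, `time_norm`, `eta`, `fit`.
#' @export
evaluate_time_models <- function(spec, minutes, covariates, n_minutes = 240L) {
  time_norm <- minutes / n_minutes
  if (any(time_norm <= 0 | time_norm > 1)) {
    stop("normalised time must lie in (0, 1]", call. = FALSE)
  }
  inv <- .linkinv(spec$link)
  eta <- vapply(time_norm, function(tn) {
    cov <- c(as.list(covariates), list(time = tn))
    sum(spec$coefficients * design_row(cov, spec))
  }, numeric(1))
  data.frame(minute = minutes, time_norm = time_norm, eta = eta,
             fit = inv(eta))
}
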