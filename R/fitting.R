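#' Fit the apparent reaction order of a rate dataset
#'
#' Ordinary least squares of log(rate) on log(concentration). The slope is
#' the apparent reaction order; fractional orders (2/3, 4/3, 5/3)
#' distinguish the discrete nearest-neighbor models from first-order
#' collision/Smoluchowski kinetics. Fitting is done in log space with equal
#' weights because measured rates typically span more than an order of
#' magnitude and the models are power laws.
#'
#' A degenerate dataset with all rates equal returns order 0 with infinite
#' standard error (flagged via `degenerate = TRUE`), not an error.
#'
#' @param ds A [rate_dataset()] with at least 2 points, all rates > 0.
#' @return An object of class `power_law_fit`: `order`, `order_stderr`,
#'   `log_prefactor` (intercept of log(rate) on log(C in 1/m^3)),
#'   `r_squared`, `degenerate`, `data`.
#' @examples
#' ds <- yoyo_lambda_dataset()
#' fit <- fit_power_law(ds)
#' coef(fit)  # order ~0.67: the ~2/3 apparent order of the dye-DNA data
#' @export
fit_power_law <- function(ds) {
  stopifnot(inherits(ds, "rate_dataset"))
  m <- ds$measurements
  if (nrow(m) < 2L) stop("need at least 2 measurements", call. = FALSE)
  if (any(m$rate <= 0)) stop("all rates must be > 0 for a log-log fit",
                             call. = FALSE)
  lx <- log(m$concentration)
  ly <- log(m$rate)
  if (isTRUE(all.equal(stats::var(ly), 0)) || stats::var(ly) == 0) {
    out <- list(order = 0, order_stderr = Inf, log_prefactor = mean(ly),
                r_squared = 0, degenerate = TRUE, data = m, fit = NULL)
    class(out) <- "power_law_fit"
    return(out)
  }
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # noiseless data fit perfectly
  out <- list(order = unname(stats::coef(fit)[2]),
              order_stderr = unname(sm$coefficients[2, 2]),
              log_prefactor = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              degenerate = FALSE, data = m, fit = fit)
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> rate = k * C^order\n")
  cat(sprintf("  order:  %.4f +/- %.4f\n", x$order, x$order_stderr))
  cat(sprintf("  ln(k):  %.4f   R^2: %.4f   n: %d\n",
              x$log_prefactor, x$r_squared, nrow(x$data)))
  if (x$degenerate) cat("  (degenerate: all rates equal)\n")
  invisible(x)
}

#' @export
summary.power_law_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) print(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(order = object$order, log_prefactor = object$log_prefactor)
}

#' @export
predict.power_law_fit <- function(object, concentration = NULL, ...) {
  if (is.null(concentration)) concentration <- object$data$concentration
  exp(object$log_prefactor) * concentration^object$order
}

#' @export
residuals.power_law_fit <- function(object, ...) {
  log(object$data$rate) - log(predict(object))
}

#' @export
plot.power_law_fit <- function(x, ...) {
  graphics::plot(x$data$concentration, x$data$rate, log = "xy",
                 xlab = "concentration (1/m^3)", ylab = "rate (1/s)",
                 main = sprintf("apparent order %.3f", x$order), ...)
  cg <- exp(seq(log(min(x$data$concentration)),
                log(max(x$data$concentration)), length.out = 50))
  graphics::lines(cg, predict(x, cg))
  invisible(x)
}

#' Per-concentration model inversion table
#'
#' For each measurement, computes the mean separation L, the reshuffle time
#' t_c, and the geometry parameter of each time-independent model inverted
#' from the measured rate, plus the cylinder-convention effective radii.
#' This is the per-row "what geometry would each model need" summary used
#' to compare the model family on one dataset.
#'
#' @param ds A [rate_dataset()].
#' @param D Relative diffusion coefficient, m^2/s.
#' @param ell Cylinder length for the effective-radius conventions, m.
#' @return A data.frame of class `inversion_table`, one row per
#'   measurement, in bench units matching single-molecule reporting
#'   practice: `conc_nM`, `L_um`, `tc_us`, `rate_per_s`, `a_1e3`
#'   (0D fraction x 10^3), `r0_1d_nm`, `A_nm2`, `r0_2d_nm`,
#'   `V_1e4_nm3` (x 10^4 nm^3), `r0_3d_nm`.
#' @examples
#' invert_dataset(yoyo_lambda_dataset(), D = 2.9e-10)
#' @export
invert_dataset <- function(ds, D, ell = 1e-6) {
  stopifnot(inherits(ds, "rate_dataset"))
  .check_pos(D, "D")
  m <- ds$measurements
  if (nrow(m) == 0L) {
    out <- data.frame(conc_nM = numeric(0), L_um = numeric(0),
                      tc_us = numeric(0), rate_per_s = numeric(0),
                      a_1e3 = numeric(0), r0_1d_nm = numeric(0),
                      A_nm2 = numeric(0), r0_2d_nm = numeric(0),
                      V_1e4_nm3 = numeric(0), r0_3d_nm = numeric(0))
    class(out) <- c("inversion_table", "data.frame")
    return(out)
  }
  C <- m$concentration
  r <- m$rate
  a  <- unname(invert_model("discrete_0d", r, C, D))
  r0 <- unname(invert_model("smoluchowski_1d", r, C, D))
  A  <- unname(invert_model("discrete_2d", r, C, D))
  V0 <- unname(invert_model("discrete_3d", r, C, D))
  out <- data.frame(
    conc_nM = number_density_to_nM(C),
    L_um = mean_separation(C) * 1e6,
    tc_us = critical_time(D, C) * 1e6,
    rate_per_s = r,
    a_1e3 = a * 1e3,
    r0_1d_nm = r0 * 1e9,
    A_nm2 = A * 1e18,
    r0_2d_nm = cylinder_radius_from_area(A, ell) * 1e9,
    V_1e4_nm3 = V0 * 1e27 / 1e4,
    r0_3d_nm = cylinder_radius_from_volume(V0, ell) * 1e9
  )
  class(out) <- c("inversion_table", "data.frame")
  out
}

#' Global single-parameter geometry fit
#'
#' Least-squares fit of a model's single geometry parameter to a whole
#' dataset, minimizing the sum of squared log-residuals
#' sum (log r_pred - log r_obs)^2. Because every time-independent model is
#' linear in its geometry parameter, the minimizer is closed form: the
#' geometric mean of the per-point inversions.
#'
#' @param ds A [rate_dataset()] with all rates > 0.
#' @param D Diffusion coefficient, m^2/s.
#' @param model Time-independent model id or alias.
#' @return An object of class `geometry_fit`: `model`, `geometry_symbol`,
#'   `best_parameter` (SI), `residual_norm` (RMS log residual),
#'   `per_point_residuals` (log r_obs - log r_pred), `data`, `D`.
#' @examples
#' fit_constant_geometry(yoyo_lambda_dataset(), 2.9e-10, "discrete_0d")
#' @export
fit_constant_geometry <- function(ds, D, model) {
  stopifnot(inherits(ds, "rate_dataset"))
  .check_pos(D, "D")
  m <- .match_model(model)
  if (model_registry()[[m]]$time_dependent) {
    stop(sprintf("model '%s' is time-dependent; constant-geometry fits cover the time-independent family", m),
         call. = FALSE)
  }
  mm <- ds$measurements
  if (any(mm$rate <= 0)) stop("all rates must be > 0", call. = FALSE)
  per_point <- unname(invert_model(m, mm$rate, mm$concentration, D))
  best <- exp(mean(log(per_point)))
  pred <- predict_rate(m, best, D, mm$concentration)
  res <- log(mm$rate) - log(pred)
  out <- list(model = m,
              geometry_symbol = model_registry()[[m]]$geometry_symbol,
              best_parameter = best,
              residual_norm = sqrt(mean(res^2)),
              per_point_residuals = res,
              per_point_inversions = per_point,
              data = mm, D = D)
  class(out) <- "geometry_fit"
  out
}

#' @export
print.geometry_fit <- function(x, ...) {
  cat(sprintf("<geometry_fit> model %s: %s = %.4g (SI), RMS log-residual %.4f (n = %d)\n",
              x$model, x$geometry_symbol, x$best_parameter,
              x$residual_norm, nrow(x$data)))
  invisible(x)
}

#' @export
coef.geometry_fit <- function(object, ...) {
  stats::setNames(object$best_parameter, object$geometry_symbol)
}

#' @export
predict.geometry_fit <- function(object, concentration = NULL, ...) {
  if (is.null(concentration)) concentration <- object$data$concentration
  predict_rate(object$model, object$best_parameter, object$D, concentration)
}

#' @export
residuals.geometry_fit <- function(object, ...) object$per_point_residuals

#' @export
summary.geometry_fit <- function(object, ...) {
  print(object)
  df <- data.frame(conc_nM = number_density_to_nM(object$data$concentration),
                   rate_obs = object$data$rate,
                   rate_pred = predict(object),
                   log_residual = object$per_point_residuals)
  print(df, row.names = FALSE)
  invisible(object)
}

#' @export
plot.geometry_fit <- function(x, ...) {
  graphics::plot(x$data$concentration, x$data$rate, log = "xy",
                 xlab = "concentration (1/m^3)", ylab = "rate (1/s)",
                 main = sprintf("%s fit, RMS log-res %.3f", x$model,
                                x$residual_norm), ...)
  cg <- exp(seq(log(min(x$data$concentration)),
                log(max(x$data$concentration)), length.out = 50))
  graphics::lines(cg, predict(x, cg))
  invisible(x)
}

#' Simulate datasets from a fitted geometry model
#'
#' Draws `nsim` synthetic datasets from the fitted model curve with
#' lognormal multiplicative noise at the fitted residual scale.
#'
#' @param object A `geometry_fit`.
#' @param nsim Number of datasets.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return A list of [rate_dataset()] objects.
#' @export
simulate.geometry_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- stats::sd(object$per_point_residuals)
  if (!is.finite(sigma)) sigma <- 0
  lapply(seq_len(nsim), function(i) {
    r <- predict(object) * exp(stats::rnorm(nrow(object$data), 0, sigma))
    rate_dataset(object$data$concentration, r,
                 label = sprintf("sim %d from %s fit", i, object$model))
  })
}

#' Rank the time-independent models on one dataset
#'
#' Runs [fit_constant_geometry()] for every time-independent model and
#' ranks the fits by RMS log-residual (ties broken by canonical model id
#' order). Because every model is a pure power law in C, the residual norm
#' is determined by the mismatch between the model's concentration
#' exponent and the dataset's apparent order.
#'
#' @param ds A [rate_dataset()] with >= 3 points.
#' @param D Diffusion coefficient, m^2/s.
#' @return A data.frame of class `model_comparison` with columns `model`,
#'   `geometry_symbol`, `best_parameter`, `residual_norm`, ordered best
#'   first; the individual fits are attached as attribute `fits`.
#' @examples
#' compare_models(yoyo_lambda_dataset(), 2.9e-10)
#' @export
compare_models <- function(ds, D) {
  stopifnot(inherits(ds, "rate_dataset"))
  if (nrow(ds$measurements) < 3L) stop("need at least 3 measurements",
                                       call. = FALSE)
  models <- Filter(function(m) !model_registry()[[m]]$time_dependent,
                   model_ids())
  fits <- lapply(models, function(m) fit_constant_geometry(ds, D, m))
  names(fits) <- models
  out <- data.frame(
    model = models,
    geometry_symbol = vapply(fits, `[[`, "", "geometry_symbol"),
    best_parameter = vapply(fits, `[[`, 0, "best_parameter"),
    residual_norm = vapply(fits, `[[`, 0, "residual_norm")
  )
  ord <- order(out$residual_norm, match(out$model, model_ids()))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> ranked by RMS log-residual\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
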