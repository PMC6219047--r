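# Replicate precision, linearity fits, inverse step estimation and the
# pump-malfunction decision.
#
# The pump is calibrated by fitting cube(volume length) = a * steps + b by
# ordinary least squares; inverting the line turns an image measurement into
# an estimate of the commanded steps, and a deviation beyond a configured
# bound flags pump malfunction.

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`, the replicate-precision statistic reported per step
#' level. (The instrument literature this mirrors occasionally labels the
#' column "ppm", but the values are percentages; this package labels the
#' unit honestly.)
#'
#' @param mean,sd Vectors of replicate means and sample standard deviations.
#' @return Numeric vector of CVs in percent.
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean <= 0, na.rm = TRUE)) abort("`mean` must be positive to form a CV.")
  100 * sd / mean
}

#' Per-step replicate statistics
#'
#' Summarises repeated measurements (reagent mass or volume length) at each
#' commanded step count: mean, sample standard deviation (n - 1 denominator)
#' and CV in percent.
#'
#' @param data A data frame of raw replicates in long form.
#' @param steps,value Column names (strings) holding the commanded pump steps
#'   and the measured value.
#' @return A tibble with one row per step level: `steps`, `n`, `mean`, `sd`,
#'   `cv_percent`, sorted by `steps`.
#' @examples
#' d <- data.frame(steps = rep(c(40, 80), each = 3), value = c(5.1, 5.3, 5.2, 11.4, 11.5, 11.6))
#' replicate_stats(d)
#' @export
replicate_stats <- function(data, steps = "steps", value = "value") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(steps, value)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found in `data`.", col))
  }
  s <- data[[steps]]; v <- data[[value]]
  if (any(is.na(s)) || any(s <= 0)) abort("`steps` must be positive with no missing values.")
  if (any(is.na(v)) || any(v <= 0)) abort("Measured values must be positive with no missing values.")
  out <- tibble(steps = s, value = v) |>
    dplyr::group_by(.data$steps) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$steps)
  if (any(out$n < 2L)) {
    bad <- out$steps[out$n < 2L]
    abort(sprintf(
      "Standard deviation needs >= 2 replicates; step level(s) %s have only one.",
      paste(bad, collapse = ", ")))
  }
  dplyr::mutate(out, cv_percent = cv_percent(.data$mean, .data$sd))
}

new_pump_calibration <- function(slope, intercept, r_squared, transform, n, fit = NULL) {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         transform = transform, n = n, fit = fit),
    class = "pump_calibration"
  )
}

#' Ordinary least-squares calibration line
#'
#' Fits `y = a x + b` with `x` the commanded pump steps and `y` either the
#' mean reagent mass (`transform = "mass"`) or the cubed mean volume length
#' (`transform = "cubed volume length"`; see [fit_cube_linear()], which
#' applies the cube for you). The fit is delegated to [stats::lm()].
#'
#' @param x Numeric vector of pump steps (>= 2 distinct values).
#' @param y Numeric response, same length.
#' @param transform Label recording what `y` is; `"cubed volume length"` is
#'   required for later step estimation.
#' @return A `pump_calibration` object with elements `slope`, `intercept`,
#'   `r_squared`, `transform`, `n` and the underlying `lm` fit. Has
#'   [tidy()], [glance()], [autoplot()] and `print()` methods.
#' @export
ols_fit <- function(x, y, transform = c("identity", "mass", "cubed volume length")) {
  transform <- match.arg(transform)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort("`x` and `y` must be numeric vectors of equal length.")
  }
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must not contain missing values.")
  if (length(unique(x)) < 2L) {
    abort("Degenerate design: at least 2 distinct `x` (step) values are required.")
  }
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  # R^2 from the residuals rather than summary(): an exactly collinear
  # calibration table (e.g. two step levels) is legitimate and should not warn
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  new_pump_calibration(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = r2,
    transform = transform,
    n = length(x),
    fit = fit
  )
}

#' Cube-linear volume-length calibration
#'
#' The tip is conical, so aspirated volume -- and therefore commanded steps --
#' is proportional to the cube of the measured volume length. This fits
#' `mean(volume length)^3 = a * steps + b` by OLS, the calibration that
#' [estimate_steps()] inverts.
#'
#' @param data Data frame with a step column and a volume-length column.
#'   Multiple rows per step level are averaged first (replicates).
#' @param steps,length Column names (strings).
#' @return A `pump_calibration` with `transform = "cubed volume length"`.
#' @export
fit_cube_linear <- function(data, steps = "steps", length = "length") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(steps, length)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found in `data`.", col))
  }
  means <- tibble(steps = data[[steps]], length = data[[length]]) |>
    dplyr::group_by(.data$steps) |>
    dplyr::summarise(length = mean(.data$length), .groups = "drop")
  ols_fit(means$steps, means$length^3, transform = "cubed volume length")
}

#' Estimate commanded pump steps from a measured volume length
#'
#' Inverts the cube-linear calibration: `s_hat = (L^3 - b) / a`. A negative
#' estimate (possible for lengths below the calibrated range) is returned
#' as-is with a warning, so the caller can treat it as an implausible-volume
#' signal rather than losing the information.
#'
#' @param length_px Measured volume length(s) in pixels.
#' @param model A `pump_calibration` with `transform = "cubed volume length"`.
#' @return Real-valued step estimate(s).
#' @export
estimate_steps <- function(length_px, model) {
  if (!inherits(model, "pump_calibration")) abort("`model` must be a pump_calibration.")
  if (!identical(model$transform, "cubed volume length")) {
    abort("Step estimation needs a calibration fitted on cubed volume lengths.")
  }
  if (model$slope == 0) abort("Calibration slope is zero; the line cannot be inverted.")
  if (!is.numeric(length_px) || any(is.na(length_px)) || any(length_px < 0)) {
    abort("`length_px` must be non-negative.")
  }
  s_hat <- (length_px^3 - model$intercept) / model$slope
  if (any(s_hat < 0)) {
    warn("Step estimate is negative: measured length lies below the calibrated range.")
  }
  s_hat
}

#' Deviation of step estimates from the commanded steps
#'
#' Root-mean-square deviation measured from the TRUE commanded steps, not
#' from the sample mean of the estimates (the mean error is assumed to
#' converge to zero with more replicates, so the commanded value is the
#' reference), and the same deviation as a percentage of the commanded steps.
#'
#' @param true_steps Commanded step count (positive scalar).
#' @param estimates One or more step estimates at that commanded level.
#' @return A one-row tibble: `true_steps`, `n`, `dev`, `rel_dev_percent`.
#' @export
deviation_stats <- function(true_steps, estimates) {
  if (!is.numeric(true_steps) || length(true_steps) != 1L || is.na(true_steps) || true_steps <= 0) {
    abort("`true_steps` must be a single positive number.")
  }
  if (!is.numeric(estimates) || length(estimates) < 1L || anyNA(estimates)) {
    abort("`estimates` must hold at least one non-missing value.")
  }
  dev <- sqrt(mean((estimates - true_steps)^2))
  tibble(true_steps = true_steps, n = length(estimates), dev = dev,
         rel_dev_percent = 100 * dev / true_steps)
}

#' Pump-malfunction check
#'
#' Estimates the pump steps from an image-measured volume length and fails
#' the check when the estimate deviates from the commanded steps beyond the
#' configured bound (strictly greater than the bound; an estimate exactly on
#' the bound passes). The bound can be absolute (steps) or relative (percent
#' of the commanded steps); the default 5% relative bound matches the
#' inaccuracy specification such dispensers are held to.
#'
#' @param commanded Commanded pump steps (positive scalar).
#' @param measured_length Volume length in pixels measured from the frame.
#' @param model A cube-linear `pump_calibration`.
#' @param bound_mode `"relative"` (percent) or `"absolute"` (steps).
#' @param bound_value Positive bound; percent when relative.
#' @return A one-row tibble: `commanded_steps`, `estimated_steps`,
#'   `deviation`, `relative_deviation_percent`, `bound_mode`, `bound_value`,
#'   `verdict` (`"pass"`/`"fail"`).
#' @export
check_pump <- function(commanded, measured_length, model,
                       bound_mode = c("relative", "absolute"), bound_value = 5) {
  bound_mode <- match.arg(bound_mode)
  if (!is.numeric(commanded) || length(commanded) != 1L || is.na(commanded) || commanded <= 0) {
    abort("`commanded` must be a single positive step count.")
  }
  if (!is.numeric(bound_value) || length(bound_value) != 1L || is.na(bound_value) || bound_value <= 0) {
    abort("`bound_value` must be a single positive number.")
  }
  s_hat <- estimate_steps(measured_length, model)
  dev <- s_hat - commanded
  rel <- 100 * abs(dev) / commanded
  exceeded <- if (bound_mode == "absolute") abs(dev) > bound_value else rel > bound_value
  tibble(
    commanded_steps = commanded,
    estimated_steps = s_hat,
    deviation = dev,
    relative_deviation_percent = rel,
    bound_mode = bound_mode,
    bound_value = bound_value,
    verdict = ifelse(exceeded, "fail", "pass")
  )
}

#' @export
print.pump_calibration <- function(x, ...) {
  cat("<pump_calibration>\n")
  cat(sprintf("  y (%s) = %.6g * steps + %.6g\n", x$transform, x$slope, x$intercept))
  cat(sprintf("  R-squared = %.3f over %d step levels\n", x$r_squared, x$n))
  invisible(x)
}

#' @rdname ols_fit
#' @param x A `pump_calibration`.
#' @param ... Unused.
#' @method tidy pump_calibration
#' @export
tidy.pump_calibration <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = c("(Intercept)", "steps"),
                  estimate = c(x$intercept, x$slope),
                  std.error = NA_real_, statistic = NA_real_, p.value = NA_real_))
  }
  co <- unname(summary(x$fit)$coefficients)
  tibble(term = c("(Intercept)", "steps"), estimate = co[, 1L],
         std.error = co[, 2L], statistic = co[, 3L], p.value = co[, 4L])
}

#' @rdname ols_fit
#' @method glance pump_calibration
#' @export
glance.pump_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         nobs = x$n, transform = x$transform)
}

#' @rdname ols_fit
#' @param object A `pump_calibration`.
#' @method autoplot pump_calibration
#' @export
autoplot.pump_calibration <- function(object, ...) {
  if (is.null(object$fit)) abort("autoplot needs the fitted model, not one restored from JSON.")
  d <- object$fit$model
  ylab <- switch(object$transform,
                 "cubed volume length" = expression("volume length"^3 ~ "(px"^3 * ")"),
                 "mass" = "mean reagent mass", "y")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "pump steps", y = ylab,
      title = sprintf("y = %.4g x + %.4g,  R² = %.3f",
                      object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Persist and restore a calibration
#'
#' The calibration is written as plain JSON (`slope`, `intercept`,
#' `r_squared`, `transform`, `n`, plus any pipeline settings supplied in
#' `extra`) so device firmware can consume it without R. A restored model
#' supports estimation and checking, but not `tidy()` standard errors or
#' `autoplot()` (the raw fit is not serialised).
#'
#' @param model A `pump_calibration`.
#' @param path JSON file path.
#' @param extra Optional named list stored alongside (e.g. threshold, ROI).
#' @return `path` (write) / a `pump_calibration` (read).
#' @export
write_calibration <- function(model, path, extra = NULL) {
  if (!inherits(model, "pump_calibration")) abort("`model` must be a pump_calibration.")
  payload <- list(slope = model$slope, intercept = model$intercept,
                  r_squared = model$r_squared, transform = model$transform, n = model$n)
  if (!is.null(extra)) payload <- c(payload, extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("Calibration file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("slope", "intercept", "r_squared", "transform", "n")) {
    if (is.null(p[[field]])) abort(sprintf("Calibration JSON is missing `%s`.", field))
  }
  new_pump_calibration(p$slope, p$intercept, p$r_squared, p$transform, as.integer(p$n))
}
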