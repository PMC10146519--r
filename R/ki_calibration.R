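#' Fit the piecewise retention-time to Kovats-index calibration
#'
#' On a temperature-programmed GC run the Rt-KI relationship is close to
#' linear early and late in the program but curved in between. The model
#' therefore interpolates linearly between calibrator peaks (compounds
#' identified against authentic standards on both platforms) for
#' `rt <= lower_max_rt` and `rt >= upper_min_rt`, and fits a least-squares
#' polynomial over the intervening region, using the mid-region calibrators
#' together with the two region-boundary calibrators. The polynomial must
#' pass within `boundary_tol` KI units of the boundary calibrators and the
#' full mapping must be monotone non-decreasing over the calibrator span;
#' either failure is an error.
#'
#' @param calibrators data.frame with numeric columns `rt` (minutes) and `ki`
#'   (index units), optional `name`; must be strictly increasing in both.
#' @param lower_max_rt,upper_min_rt region boundaries (minutes).
#' @param poly_degree degree of the mid-region polynomial.
#' @param boundary_tol allowed |polynomial - calibrator| at the boundary
#'   calibrators, KI units.
#' @return An object of class `ki_calibration`.
#' @export
fit_calibration <- function(calibrators, lower_max_rt = 13.59,
                            upper_min_rt = 17.37, poly_degree = 3,
                            boundary_tol = 1) {
  calibrators <- as.data.frame(calibrators)
  stopifnot(all(c("rt", "ki") %in% names(calibrators)))
  calibrators <- calibrators[order(calibrators$rt), , drop = FALSE]
  if (any(diff(calibrators$rt) <= 0) || any(diff(calibrators$ki) <= 0))
    stop("calibrators must be strictly increasing in both rt and ki")
  if (any(calibrators$rt <= 0)) stop("calibrator rt must be positive")
  lower <- calibrators[calibrators$rt <= lower_max_rt, , drop = FALSE]
  upper <- calibrators[calibrators$rt >= upper_min_rt, , drop = FALSE]
  mid <- calibrators[calibrators$rt > lower_max_rt &
                     calibrators$rt < upper_min_rt, , drop = FALSE]
  if (nrow(lower) < 2) stop("need >= 2 calibrators with rt <= ", lower_max_rt)
  if (nrow(upper) < 2) stop("need >= 2 calibrators with rt >= ", upper_min_rt)
  # the mid fit borrows the innermost calibrator of each linear region so the
  # three pieces share anchor points
  anchors <- rbind(lower[nrow(lower), ], mid, upper[1, ])
  if (nrow(anchors) < poly_degree + 1)
    stop("need >= ", poly_degree + 1,
         " calibrators spanning the mid region (including its boundary ",
         "calibrators); got ", nrow(anchors))
  fit <- stats::lm(ki ~ stats::poly(rt, degree = poly_degree, raw = TRUE),
                   data = anchors)
  coeffs <- unname(stats::coef(fit))
  at_bounds <- eval_poly(coeffs, c(anchors$rt[1], anchors$rt[nrow(anchors)]))
  dev <- abs(at_bounds - c(anchors$ki[1], anchors$ki[nrow(anchors)]))
  if (any(dev > boundary_tol))
    stop("mid-region polynomial misses a boundary calibrator by ",
         format(round(max(dev), 2)), " KI units (> ", boundary_tol,
         "); try a different poly_degree")
  model <- structure(list(calibrators = calibrators,
                          lower_region_max_rt = lower_max_rt,
                          upper_region_min_rt = upper_min_rt,
                          mid_poly_coeffs = coeffs,
                          poly_degree = poly_degree),
                     class = "ki_calibration")
  grid <- seq(min(calibrators$rt), max(calibrators$rt), length.out = 2001)
  vals <- impute_ki(model, grid, round = FALSE)
  if (any(diff(vals) < -1e-9))
    stop("fitted calibration is not monotone over the calibrator span; ",
         "check the calibrators or lower poly_degree")
  model
}

eval_poly <- function(coeffs, x) {
  drop(outer(x, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

#' @export
print.ki_calibration <- function(x, ...) {
  cat("<ki_calibration>\n  ", nrow(x$calibrators), " calibrators, rt ",
      min(x$calibrators$rt), "-", max(x$calibrators$rt), " min\n", sep = "")
  cat("  linear regions: rt <= ", x$lower_region_max_rt, " and rt >= ",
      x$upper_region_min_rt, "; mid polynomial degree ", x$poly_degree,
      "\n", sep = "")
  invisible(x)
}

# linear interpolation among the calibrators of one region, extending the end
# segments linearly for queries just beyond the outermost calibrator
interp_region <- function(region, rt) {
  x <- region$rt; y <- region$ki
  out <- stats::approx(x, y, xout = rt, rule = 2)$y
  lo <- rt < x[1]
  hi <- rt > x[length(x)]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (rt[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (rt[hi] - x[n])
  }
  out
}

#' Impute a Kovats index for a retention time
#'
#' Linear interpolation between flanking calibrators in the two linear
#' regions, polynomial evaluation in between. Queries must lie within the
#' calibrator span extended by 1 minute at each end, unless `extrapolate`
#' is set. Results are rounded to integer KI by default, as indices are
#' conventionally printed.
#'
#' @param model a `ki_calibration`.
#' @param rt numeric vector of retention times (minutes).
#' @param extrapolate allow queries beyond the span grace interval?
#' @param round round to integer KI?
#' @return Numeric vector of (imputed) Kovats indices.
#' @export
impute_ki <- function(model, rt, extrapolate = FALSE, round = TRUE) {
  cal <- model$calibrators
  span <- range(cal$rt)
  if (!extrapolate && any(rt < span[1] - 1 | rt > span[2] + 1))
    stop("rt outside the calibrated span [", span[1] - 1, ", ", span[2] + 1,
         "]; set extrapolate = TRUE to override")
  lower <- cal[cal$rt <= model$lower_region_max_rt, , drop = FALSE]
  upper <- cal[cal$rt >= model$upper_region_min_rt, , drop = FALSE]
  out <- numeric(length(rt))
  in_lower <- rt <= model$lower_region_max_rt
  in_upper <- rt >= model$upper_region_min_rt
  in_mid <- !in_lower & !in_upper
  if (any(in_lower)) out[in_lower] <- interp_region(lower, rt[in_lower])
  if (any(in_upper)) out[in_upper] <- interp_region(upper, rt[in_upper])
  if (any(in_mid)) out[in_mid] <- eval_poly(model$mid_poly_coeffs, rt[in_mid])
  if (round) base::round(out) else out
}

#' Residual report for a calibration against holdout pairs
#'
#' @param model a `ki_calibration`.
#' @param holdout data.frame with columns `rt` and `ki` (observed).
#' @return data.frame `(rt, ki_observed, ki_imputed, residual)` with the
#'   summary `max |residual|` in attribute `"max_abs_residual"`.
#' @export
calibration_report <- function(model, holdout) {
  holdout <- as.data.frame(holdout)
  imp <- impute_ki(model, holdout$rt)
  out <- data.frame(rt = holdout$rt, ki_observed = holdout$ki,
                    ki_imputed = imp, residual = imp - holdout$ki)
  attr(out, "max_abs_residual") <- if (nrow(out)) max(abs(out$residual)) else NA_real_
  out
}
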