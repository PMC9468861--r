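#' Fit the spectrometer roll-off to a mirror sweep
#'
#' Least-squares fit of the roll-off curve
#' `amplitude * sinc^2(xi) * exp(-xi^2 omega^2 / (2 ln 2))` to the peak
#' intensities of a reference-arm-only mirror sweep. The amplitude is fitted
#' jointly, so recovery is invariant to the sweep's intensity scale. The
#' optimizer is bounded Levenberg-Marquardt with a small multi-start grid
#' over omega (the starting omega comes from the log-ratio of the first and
#' last points, which inverts the Gaussian factor analytically).
#'
#' @param sweep a `mirror_sweep` of kind `"reference_arm_only"`, or any list
#'   with `depth_mm`, `intensity`, `max_depth_mm`.
#' @return object of class `rolloff_fit`: the fitted `model`
#'   (a [rolloff_model()]), `residual_norm` (RMS residual / peak intensity),
#'   `n_points`, plus the data.
#' @export
fit_rolloff <- function(sweep) {
  .check_sweep(sweep, "reference_arm_only")
  xi <- xi_depth(sweep$depth_mm, sweep$max_depth_mm)
  y <- sweep$intensity
  sinc2 <- ifelse(xi == 0, 1, (sin(xi) / xi)^2)
  # analytic start: the Gaussian factor between two depths gives omega^2
  g <- y / sinc2
  i1 <- which.max(xi > 0)
  i2 <- length(xi)
  ratio <- g[i1] / g[i2]
  w0 <- if (is.finite(ratio) && ratio > 1) {
    sqrt(2 * log(2) * log(ratio) / (xi[i2]^2 - xi[i1]^2))
  } else 0.5
  starts <- unique(pmax(c(w0, 0.5, 1, 2, 3), 1e-3))
  best <- NULL
  for (w in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * ifelse(xi == 0, 1, (sin(xi) / xi)^2) *
          exp(-xi^2 * omega^2 / (2 * log(2))),
        start = list(A = max(y), omega = w),
        lower = c(A = .Machine$double.eps, omega = 0),
        upper = c(A = Inf, omega = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("roll-off calibration did not converge from any start (",
         length(starts), " starts, ", length(y), " points)", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  model <- rolloff_model(omega = unname(cf["omega"]),
                         amplitude = unname(cf["A"]))
  structure(list(model = model,
                 residual_norm = sqrt(best$rss / length(y)) / max(y),
                 n_points = length(y),
                 depth_mm = sweep$depth_mm, intensity = y, xi = xi),
            class = "rolloff_fit")
}

#' Fit the confocal collection model to a mirror sweep
#'
#' Fits the Lorentzian `A / (1 + ((z - z_f)/(n z_r))^2)` to the peak
#' intensities of a fixed-reference mirror sweep, after dividing each
#' measurement by the roll-off `r(z)` when a roll-off model is supplied
#' (spectral-domain systems; omit for swept-source). The fit is performed in
#' linear intensity. The sweep is in air, so `n = 1`. Starts: the focus from
#' the argmax, the Rayleigh length from the half-maximum width.
#'
#' @param sweep a `mirror_sweep` of kind `"fixed_reference"`.
#' @param rolloff a fitted or known `rolloff_model`, a `rolloff_fit`, or
#'   `NULL` to skip the roll-off correction.
#' @return object of class `confocal_fit`: the fitted `model`
#'   (a [confocal_model()] with `n = 1`), `residual_norm`, `n_points`, data.
#' @export
fit_confocal <- function(sweep, rolloff = NULL) {
  .check_sweep(sweep, "fixed_reference")
  if (inherits(rolloff, "rolloff_fit")) rolloff <- rolloff$model
  z <- sweep$depth_mm
  y <- sweep$intensity
  if (all(y <= 0)) stop("all sweep intensities are zero", call. = FALSE)
  if (!is.null(rolloff)) {
    r <- rolloff_value(xi_depth(z, sweep$max_depth_mm), rolloff)
    y <- y / r
  }
  zf0 <- z[which.max(y)]
  half <- which(y >= max(y) / 2)
  zr0 <- max((z[max(half)] - z[min(half)]) / 2, diff(range(z)) / 20)
  starts <- list(c(zf0, zr0), c(zf0, zr0 / 2), c(zf0, zr0 * 2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A / (1 + ((z - zf) / zr)^2),
        start = list(A = max(y), zf = st[1], zr = st[2]),
        lower = c(A = .Machine$double.eps, zf = -Inf, zr = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("confocal calibration did not converge from any start", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  model <- confocal_model(focus_mm = unname(cf["zf"]),
                          rayleigh_mm = unname(cf["zr"]), n = 1,
                          amplitude = unname(cf["A"]))
  structure(list(model = model,
                 residual_norm = sqrt(best$rss / length(y)) / max(y),
                 n_points = length(y),
                 depth_mm = z, intensity = y),
            class = "confocal_fit")
}

.check_sweep <- function(sweep, kind) {
  stopifnot(is.list(sweep), !is.null(sweep$depth_mm), !is.null(sweep$intensity))
  if (!is.null(sweep$kind) && sweep$kind != kind) {
    stop("sweep kind '", sweep$kind, "' does not match the required '", kind,
         "'", call. = FALSE)
  }
  if (is.unsorted(sweep$depth_mm, strictly = TRUE)) {
    stop("sweep depths must be strictly increasing", call. = FALSE)
  }
  if (any(sweep$intensity < 0)) {
    stop("sweep intensities must be nonnegative", call. = FALSE)
  }
  if (is.null(sweep$max_depth_mm)) {
    stop("sweep lacks max_depth_mm (needed to normalize depth)", call. = FALSE)
  }
  invisible(sweep)
}

#' Calibrate a system profile from its mirror sweeps
#'
#' Convenience wrapper producing the calibration bundle the correction stage
#' consumes: fits the roll-off (only when the profile applies it) and then
#' the confocal model with the roll-off divided out.
#'
#' @param profile an `oct_profile`.
#' @param rolloff_sweep reference-arm-only `mirror_sweep`; ignored (may be
#'   `NULL`) when the profile neglects roll-off.
#' @param confocal_sweep fixed-reference `mirror_sweep`.
#' @return object of class `oct_calibration`: `rolloff` (`rolloff_model` or
#'   `NULL`), `confocal` (`confocal_model`), `residual_norms`, `profile_name`.
#' @export
calibrate_system <- function(profile, rolloff_sweep = NULL, confocal_sweep) {
  rfit <- NULL
  if (profile$apply_rolloff) {
    if (is.null(rolloff_sweep)) {
      stop("profile '", profile$name, "' applies roll-off: a reference-arm-only",
           " sweep is required", call. = FALSE)
    }
    rfit <- fit_rolloff(rolloff_sweep)
  }
  cfit <- fit_confocal(confocal_sweep, rolloff = rfit)
  structure(list(rolloff = if (is.null(rfit)) NULL else rfit$model,
                 confocal = cfit$model,
                 residual_norms = c(
                   rolloff = if (is.null(rfit)) NA_real_ else rfit$residual_norm,
                   confocal = cfit$residual_norm),
                 profile_name = profile$name),
            class = "oct_calibration")
}

#' Bundle known models as a calibration (no fitting)
#'
#' Useful when the true roll-off/confocal models are known, e.g. in
#' simulation studies.
#' @param confocal a `confocal_model`.
#' @param rolloff a `rolloff_model` or `NULL`.
#' @param profile_name optional provenance tag.
#' @return an `oct_calibration`.
#' @export
as_calibration <- function(confocal, rolloff = NULL, profile_name = NA_character_) {
  stopifnot(inherits(confocal, "confocal_model"),
            is.null(rolloff) || inherits(rolloff, "rolloff_model"))
  structure(list(rolloff = rolloff, confocal = confocal,
                 residual_norms = c(rolloff = NA_real_, confocal = NA_real_),
                 profile_name = profile_name),
            class = "oct_calibration")
}

#' @export
print.rolloff_fit <- function(x, ...) {
  cat(sprintf("Roll-off calibration: omega = %.4f, amplitude = %.4g (%d points, residual %.3g)\n",
              x$model$omega, x$model$amplitude, x$n_points, x$residual_norm))
  invisible(x)
}

#' @export
print.confocal_fit <- function(x, ...) {
  cat(sprintf("Confocal calibration: z_f = %.4f mm, z_r = %.4f mm, amplitude = %.4g (%d points, residual %.3g)\n",
              x$model$focus_mm, x$model$rayleigh_mm, x$model$amplitude,
              x$n_points, x$residual_norm))
  invisible(x)
}

#' @export
print.oct_calibration <- function(x, ...) {
  cat("OCT system calibration", if (!is.na(x$profile_name))
    paste0(" (", x$profile_name, ")"), "\n", sep = "")
  if (is.null(x$rolloff)) cat("  roll-off: neglected\n")
  else cat(sprintf("  roll-off: omega = %.4f\n", x$rolloff$omega))
  cat(sprintf("  confocal: z_f = %.4f mm, z_r = %.4f mm\n",
              x$confocal$focus_mm, x$confocal$rayleigh_mm))
  invisible(x)
}

#' @export
coef.rolloff_fit <- function(object, ...) {
  c(omega = object$model$omega, amplitude = object$model$amplitude)
}

#' @export
coef.confocal_fit <- function(object, ...) {
  c(focus_mm = object$model$focus_mm, rayleigh_mm = object$model$rayleigh_mm,
    amplitude = object$model$amplitude)
}

#' @export
predict.rolloff_fit <- function(object, depth_mm = object$depth_mm,
                                max_depth_mm = NULL, ...) {
  if (is.null(max_depth_mm)) {
    # xi was stored at fit time for the fitted depths
    if (identical(depth_mm, object$depth_mm)) {
      return(rolloff_value(object$xi, object$model))
    }
    stop("supply max_depth_mm to predict at new depths", call. = FALSE)
  }
  rolloff_value(xi_depth(depth_mm, max_depth_mm), object$model)
}

#' @export
predict.confocal_fit <- function(object, depth_mm = object$depth_mm, ...) {
  confocal_value(depth_mm, object$model)
}

#' @export
residuals.rolloff_fit <- function(object, ...) {
  object$intensity - rolloff_value(object$xi, object$model)
}

#' @export
residuals.confocal_fit <- function(object, ...) {
  object$intensity - confocal_value(object$depth_mm, object$model)
}

#' @export
plot.rolloff_fit <- function(x, ...) {
  graphics::plot(x$depth_mm, x$intensity, xlab = "depth [mm]",
                 ylab = "peak intensity [a.u.]",
                 main = "Roll-off calibration", ...)
  graphics::lines(x$depth_mm, rolloff_value(x$xi, x$model), col = 2)
  invisible(x)
}

#' @export
plot.confocal_fit <- function(x, ...) {
  graphics::plot(x$depth_mm, x$intensity, xlab = "depth [mm]",
                 ylab = "corrected peak intensity [a.u.]",
                 main = "Confocal calibration", ...)
  graphics::lines(x$depth_mm, confocal_value(x$depth_mm, x$model), col = 2)
  invisible(x)
}
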