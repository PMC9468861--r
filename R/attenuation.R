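#' Correct an A-scan for roll-off and confocal collection
#'
#' Divides the measured intensity by the roll-off gain `r(xi)` (when the
#' profile applies roll-off and the calibration provides a model) and by the
#' confocal gain `h(z)`, evaluated on the geometric depth axis with the
#' refraction-shifted focus (air to tissue, `n1 = 1`, `n2 = n_tissue`, at the
#' surface depth). What remains of a single-scattering signal is the pure
#' tissue decay `I0 exp(-2 mu (z - z_s))`.
#'
#' Pixels where either gain falls below `1e-6` of its maximum are flagged
#' invalid rather than amplified, as are pixels above the surface.
#'
#' @param ascan numeric intensity vector, or an `oct_ascan`.
#' @param profile an `oct_profile`.
#' @param calibration an `oct_calibration` (fitted or known models).
#' @param surface_pixel 1-based first tissue pixel (taken from an
#'   `oct_ascan` automatically).
#' @param n_tissue tissue refractive index.
#' @param depth_scaling see [geometric_depth_axis()].
#' @param gain_floor relative floor below which a gain invalidates a pixel.
#' @return object of class `corrected_ascan`: `corrected` (A^2(z)'),
#'   `depth_mm`, `surface_pixel`, `surface_depth_mm`, `valid` (logical per
#'   pixel), `rolloff_gain`, `confocal_gain`, `shifted_focus_mm`.
#' @export
correct_ascan <- function(ascan, profile, calibration, surface_pixel = NULL,
                          n_tissue = 1.36, depth_scaling = "divide",
                          gain_floor = 1e-6) {
  if (inherits(ascan, "oct_ascan")) {
    if (is.null(surface_pixel)) surface_pixel <- ascan$surface_pixel
    ascan <- ascan$intensity
  }
  stopifnot(is.numeric(ascan), inherits(calibration, "oct_calibration"))
  n_pixels <- length(ascan)
  if (is.null(surface_pixel) || surface_pixel < 1 || surface_pixel > n_pixels) {
    stop("surface_pixel missing or outside the A-scan", call. = FALSE)
  }
  pitch <- profile$axial_pixel_pitch_air_um
  nmap <- refractive_map(n_pixels, surface_pixel, n_tissue = n_tissue)
  z <- geometric_depth_axis(n_pixels, pitch, nmap, depth_scaling)
  depth_air <- (seq_len(n_pixels) - 1) * pitch / 1000
  z_s <- z[surface_pixel]
  sf <- shift_focus(calibration$confocal$focus_mm, z_s, n1 = 1, n2 = n_tissue,
                    numerical_aperture = profile$numerical_aperture)
  below <- seq_len(n_pixels) >= surface_pixel
  h <- rep(NA_real_, n_pixels)
  h[below] <- .tissue_confocal_gain(z[below], calibration$confocal,
                                    sf$shifted_focus_mm, n_tissue)
  r <- rep(1, n_pixels)
  if (isTRUE(profile$apply_rolloff) && !is.null(calibration$rolloff)) {
    r <- rolloff_value(xi_depth(depth_air, profile$max_imaging_depth_mm),
                       calibration$rolloff)
  }
  valid <- below &
    r >= gain_floor * max(r) &
    !is.na(h) & h >= gain_floor * max(h, na.rm = TRUE)
  corrected <- rep(NA_real_, n_pixels)
  corrected[valid] <- ascan[valid] / (r[valid] * h[valid])
  structure(list(corrected = corrected, depth_mm = z,
                 surface_pixel = as.integer(surface_pixel),
                 surface_depth_mm = z_s, valid = valid,
                 rolloff_gain = r, confocal_gain = h,
                 shifted_focus_mm = sf$shifted_focus_mm,
                 profile_name = profile$name),
            class = "corrected_ascan")
}

#' Estimate attenuation coefficient and backscattered intensity
#'
#' The single-scattering estimator: over a fit window starting
#' `fit_start_px` pixels below the surface and spanning `fit_length_um`
#' micrometers (counted in in-air pixels: 100 on the "sd" pitch, 50 on the
#' "ss" pitch), the log-transformed corrected intensity is regressed on
#' geometric depth by ordinary least squares,
#' \deqn{\ln A^2(z)' = \ln I_0 - 2 \mu (z - z_s),}
#' so the attenuation coefficient is `-slope / 2` (per mm of geometric
#' depth) and `I0` is the intercept referenced to the tissue surface.
#'
#' Nonpositive intensities in the window are excluded from the regression;
#' more than 20% exclusions (or invalid pixels in the window, or a window
#' running past the data) aborts the fit.
#'
#' @param corrected a `corrected_ascan` (from [correct_ascan()]).
#' @param profile the `oct_profile` (supplies the pixel pitch that converts
#'   `fit_length_um` to a pixel count).
#' @param fit_start_px window start below the surface, pixels.
#' @param fit_length_um window length, micrometers.
#' @param max_excluded_frac maximum tolerated fraction of excluded points.
#' @return object of class `oct_fit` with components `mu` (1/mm), `i0`
#'   (a.u., referenced to the surface), `r_squared`, `n_points`,
#'   `fit_start_pixel`, `fit_length_um`, `window` (pixel indices),
#'   `nonphysical` (TRUE when mu < 0), and the regression data.
#' @examples
#' p <- load_profile("ss")
#' cm <- confocal_model(0.9, 0.25)
#' a <- simulate_ascan(p, mu = 4.93, i0 = 0.4, surface_pixel = 11, cm)
#' cal <- as_calibration(cm)
#' fit <- fit_attenuation(correct_ascan(a, p, cal), p)
#' coef(fit)   # mu = 4.93, i0 = 0.4
#' @export
fit_attenuation <- function(corrected, profile, fit_start_px = 10,
                            fit_length_um = 300, max_excluded_frac = 0.2) {
  stopifnot(inherits(corrected, "corrected_ascan"))
  n_points <- fit_window_pixels(profile, fit_length_um)
  start <- corrected$surface_pixel + fit_start_px
  idx <- start:(start + n_points - 1L)
  if (max(idx) > length(corrected$corrected)) {
    stop("fit window runs past the end of the A-scan", call. = FALSE)
  }
  if (!all(corrected$valid[idx])) {
    stop("fit window contains invalid (flagged) pixels", call. = FALSE)
  }
  y_lin <- corrected$corrected[idx]
  keep <- y_lin > 0
  if (mean(!keep) > max_excluded_frac) {
    stop(sprintf("fit aborted: %.0f%% of window intensities are nonpositive",
                 100 * mean(!keep)), call. = FALSE)
  }
  x <- corrected$depth_mm[idx][keep] - corrected$surface_depth_mm
  y <- log(y_lin[keep])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  mu <- unname(-slope / 2)
  structure(list(mu = mu, i0 = unname(exp(intercept)),
                 r_squared = max(0, min(1, r2)),
                 n_points = n_points, n_used = sum(keep),
                 fit_start_pixel = as.integer(start),
                 fit_length_um = fit_length_um,
                 window = idx, nonphysical = mu < 0,
                 surface_depth_mm = corrected$surface_depth_mm,
                 data = list(depth_mm = x + corrected$surface_depth_mm,
                             log_intensity = y),
                 residuals_log = unname(fit$residuals),
                 profile_name = corrected$profile_name),
            class = "oct_fit")
}

#' @export
print.oct_fit <- function(x, ...) {
  cat(sprintf("Single-scattering attenuation fit (%s profile)\n",
              x$profile_name))
  cat(sprintf("  mu  = %.4g 1/mm    I0 = %.4g a.u.\n", x$mu, x$i0))
  cat(sprintf("  window: %d px (%g um) from pixel %d; R^2 = %.4f%s\n",
              x$n_points, x$fit_length_um, x$fit_start_pixel, x$r_squared,
              if (x$nonphysical) "  [nonphysical: mu < 0]" else ""))
  invisible(x)
}

#' @export
summary.oct_fit <- function(object, ...) {
  cat(sprintf("Attenuation coefficient mu: %.4f 1/mm\n", object$mu))
  cat(sprintf("Backscattered intensity I0: %.4g a.u. (at the tissue surface)\n",
              object$i0))
  cat(sprintf("Fit window: %d points over %g um starting at pixel %d (%d used)\n",
              object$n_points, object$fit_length_um, object$fit_start_pixel,
              object$n_used))
  cat(sprintf("R^2 of the log-linear fit: %.5f\n", object$r_squared))
  rms <- sqrt(mean(object$residuals_log^2))
  cat(sprintf("RMS log-residual: %.3g\n", rms))
  invisible(object)
}

#' @export
coef.oct_fit <- function(object, ...) {
  c(mu = object$mu, i0 = object$i0)
}

#' @export
predict.oct_fit <- function(object, depth_mm = object$data$depth_mm, ...) {
  object$i0 * exp(-2 * object$mu * (depth_mm - object$surface_depth_mm))
}

#' @export
residuals.oct_fit <- function(object, ...) {
  object$residuals_log
}

#' @export
plot.oct_fit <- function(x, ...) {
  graphics::plot(x$data$depth_mm, x$data$log_intensity,
                 xlab = "geometric depth [mm]",
                 ylab = "ln corrected intensity",
                 main = sprintf("log-linear fit: mu = %.3g 1/mm", x$mu), ...)
  graphics::abline(log(x$i0) + 2 * x$mu * x$surface_depth_mm, -2 * x$mu,
                   col = 2)
  invisible(x)
}

#' Fit every patch of a batch
#'
#' Per patch: average laterally ([average_patch()]), correct
#' ([correct_ascan()]) and fit ([fit_attenuation()]). Failures are recorded
#' per patch rather than aborting the batch. I0 is additionally exported
#' normalized to the batch maximum.
#'
#' @param patches list of `oct_patch`.
#' @param profile the `oct_profile`.
#' @param calibration an `oct_calibration`.
#' @param surface_offset_px the patches' offset below the surface (the
#'   corrected A-scan is reconstructed with its top at this offset).
#' @param ... passed to [fit_attenuation()].
#' @return data.frame keyed by patch id: provenance, label, `mu`, `i0`,
#'   `i0_normalized`, `r_squared`, `n_points`, `ok`, `error`, plus
#'   ground-truth columns where the patches carry truth.
#' @export
batch_fit <- function(patches, profile, calibration,
                      surface_offset_px = 10, ...) {
  man <- patch_manifest(patches)
  man$mu <- NA_real_; man$i0 <- NA_real_; man$r_squared <- NA_real_
  man$n_points <- NA_integer_
  man$ok <- FALSE; man$error <- NA_character_
  for (i in seq_along(patches)) {
    err <- tryCatch({
      fit <- .fit_patch(patches[[i]], profile, calibration,
                        surface_offset_px, ...)
      man$mu[i] <- fit$mu; man$i0[i] <- fit$i0
      man$r_squared[i] <- fit$r_squared
      man$n_points[i] <- fit$n_points
      man$ok[i] <- TRUE
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(err)) man$error[i] <- err
  }
  man$i0_normalized <- if (any(man$ok)) man$i0 / max(man$i0[man$ok]) else NA_real_
  man
}

# Rebuild an A-scan around the averaged patch at its true absolute rows
# (so the roll-off, which depends on absolute optical depth, is evaluated
# where the patch actually sat), with the surface at top_row - offset; the
# fit window then starts at the patch top.
.fit_patch <- function(patch, profile, calibration, surface_offset_px = 10,
                       fit_start_px = NULL, ...) {
  avg <- average_patch(patch)
  off <- if (inherits(patch, "oct_patch")) patch$surface_offset_px else surface_offset_px
  top <- if (inherits(patch, "oct_patch")) patch$top_row else off + 1L
  surface_pixel <- top - off
  stopifnot(surface_pixel >= 1L)
  full <- numeric(top - 1L + length(avg))
  full[top:(top - 1L + length(avg))] <- avg
  corr <- correct_ascan(full, profile, calibration,
                        surface_pixel = surface_pixel)
  if (is.null(fit_start_px)) fit_start_px <- off
  fit_attenuation(corr, profile, fit_start_px = fit_start_px,
                  fit_length_um = min(300, length(avg) *
                                        profile$axial_pixel_pitch_air_um), ...)
}
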