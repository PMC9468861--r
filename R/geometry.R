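#' Spectrometer roll-off model
#'
#' Depth-dependent sensitivity loss of a spectrometer-based OCT system:
#' \deqn{r(\xi) = A \,\mathrm{sinc}^2(\xi)\, \exp\!\left(-\frac{\xi^2 \omega^2}{2 \ln 2}\right)}
#' where \eqn{\xi} is the imaging depth normalized to the maximum imaging
#' depth (scaled by \eqn{\pi}, see [xi_depth()]) and \eqn{\omega} is the
#' ratio of the wavelength spacing between spectrometer pixels to the
#' spectral resolution of the spectrometer.
#'
#' @param omega spectral-resolution ratio, > 0 (or 0 for the pure-sinc limit).
#' @param amplitude intensity scale at zero depth, > 0.
#' @return an object of class `rolloff_model`.
#' @export
rolloff_model <- function(omega, amplitude = 1) {
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega), omega >= 0,
            is.numeric(amplitude), length(amplitude) == 1L, amplitude > 0)
  structure(list(omega = omega, amplitude = amplitude), class = "rolloff_model")
}

#' Evaluate the roll-off gain at a normalized depth
#'
#' Continuous at \eqn{\xi = 0} with value `amplitude` (the analytic
#' \eqn{\mathrm{sinc}} limit).
#'
#' @param xi normalized depth(s), >= 0 (dimensionless, typically in
#'   `[0, pi]`).
#' @param model a `rolloff_model`.
#' @return dimensionless gain, same length as `xi`.
#' @examples
#' rolloff_value(0, rolloff_model(2))      # 1
#' rolloff_value(0.5, rolloff_model(2))    # ~0.4469
#' @export
rolloff_value <- function(xi, model) {
  stopifnot(inherits(model, "rolloff_model"), all(xi >= 0))
  s <- ifelse(xi == 0, 1, sin(xi) / xi)
  model$amplitude * s^2 * exp(-xi^2 * model$omega^2 / (2 * log(2)))
}

#' Normalized depth coordinate for the roll-off model
#'
#' Maps an in-air optical depth to \eqn{\xi = \pi \, z / z_{max}}, the
#' convention under which the first sinc zero falls at the maximum imaging
#' depth. The constant only rescales the fitted \eqn{\omega}; it cancels in
#' the corrected signal.
#'
#' @param depth_mm in-air optical depth, mm.
#' @param max_depth_mm maximum imaging depth, mm.
#' @return dimensionless \eqn{\xi}.
#' @export
xi_depth <- function(depth_mm, max_depth_mm) {
  stopifnot(max_depth_mm > 0)
  pi * depth_mm / max_depth_mm
}

#' Confocal collection-efficiency model
#'
#' Lorentzian axial profile of the light collection efficiency of the
#' objective around the beam focus:
#' \deqn{h(z) = \frac{1}{1 + \left(\frac{z - z_f}{n z_r}\right)^2}}
#' with focus position \eqn{z_f}, Rayleigh length \eqn{z_r} and medium
#' refractive index \eqn{n}.
#'
#' @param focus_mm focus position \eqn{z_f} (mm, in-air coordinates).
#' @param rayleigh_mm Rayleigh length \eqn{z_r} (mm), > 0.
#' @param n refractive index of the imaged medium, >= 1.
#' @param amplitude peak collection efficiency (1 for a normalized model).
#' @return an object of class `confocal_model`.
#' @export
confocal_model <- function(focus_mm, rayleigh_mm, n = 1, amplitude = 1) {
  stopifnot(is.numeric(focus_mm), length(focus_mm) == 1L, is.finite(focus_mm),
            is.numeric(rayleigh_mm), length(rayleigh_mm) == 1L, rayleigh_mm > 0,
            n >= 1, amplitude > 0)
  structure(list(focus_mm = focus_mm, rayleigh_mm = rayleigh_mm, n = n,
                 amplitude = amplitude),
            class = "confocal_model")
}

#' Evaluate the confocal gain at a geometric depth
#'
#' Maximum `amplitude` at `z = focus`; symmetric about the focus; falls to
#' half maximum one scaled Rayleigh length (`n * z_r`) away.
#'
#' @param z_mm geometric depth(s), mm.
#' @param model a `confocal_model`.
#' @param focus_mm optional focus override (mm), e.g. the refraction-shifted
#'   focus from [shift_focus()]; defaults to the model's own focus.
#' @return dimensionless gain, same length as `z_mm`.
#' @export
confocal_value <- function(z_mm, model, focus_mm = model$focus_mm) {
  stopifnot(inherits(model, "confocal_model"))
  model$amplitude / (1 + ((z_mm - focus_mm) / (model$n * model$rayleigh_mm))^2)
}

#' Refraction-shifted focus position
#'
#' When the beam enters a medium of higher refractive index at the tissue
#' surface \eqn{z_s}, Snell's law bends the marginal ray and displaces the
#' focus. With the entrance angle \eqn{\alpha = \arcsin(NA / n_1)} and the
#' refracted angle \eqn{\beta = \arcsin(n_1 \sin\alpha / n_2)}, equating the
#' lateral ray offset \eqn{\Delta x} above and below the surface gives the
#' shifted focus
#' \deqn{z_f' = \frac{\tan\alpha}{\tan\beta} (z_f - z_s) + z_s.}
#'
#' A focus above the surface (`air_focus < surface`) is never displaced; the
#' geometry does not apply there and the function returns \eqn{z_f' = z_f}
#' with a warning.
#'
#' @param air_focus_mm focus position in air, \eqn{z_f} (mm).
#' @param surface_mm surface depth \eqn{z_s} (mm).
#' @param n1 refractive index of the incidence medium (air: 1).
#' @param n2 refractive index of the refraction medium (brain tissue: 1.36).
#' @param numerical_aperture system NA; must satisfy `NA < n1`.
#' @return list with `alpha_rad`, `beta_rad`, `lateral_offset_mm`
#'   (\eqn{\Delta x}), `shifted_focus_mm` (\eqn{z_f'}), and the inputs.
#' @examples
#' # 1 mm below the surface, air -> brain tissue, NA 0.051:
#' shift_focus(2, 1, 1, 1.36, 0.051)$shifted_focus_mm - 1  # ~1.3608
#' @export
shift_focus <- function(air_focus_mm, surface_mm, n1 = 1, n2 = 1.36,
                        numerical_aperture) {
  stopifnot(n1 >= 1, n2 >= 1, is.numeric(numerical_aperture),
            numerical_aperture > 0)
  if (numerical_aperture >= n1) {
    stop("numerical aperture must be smaller than the incidence index n1",
         call. = FALSE)
  }
  alpha <- asin(numerical_aperture / n1)
  beta <- asin(n1 * sin(alpha) / n2)
  if (air_focus_mm < surface_mm) {
    warning("focus lies above the tissue surface; no focus shift applied")
    zfp <- air_focus_mm
    dx <- 0
  } else {
    dx <- tan(alpha) * (air_focus_mm - surface_mm)
    zfp <- tan(alpha) / tan(beta) * (air_focus_mm - surface_mm) + surface_mm
  }
  list(alpha_rad = alpha, beta_rad = beta,
       lateral_offset_mm = dx, shifted_focus_mm = zfp,
       air_focus_mm = air_focus_mm, surface_mm = surface_mm,
       n1 = n1, n2 = n2, numerical_aperture = numerical_aperture)
}

#' Geometric depth axis of an A-scan
#'
#' OCT axial pixels sample optical path length; the geometric depth at pixel
#' \eqn{i} is the cumulative sum of the pitch divided by the local refractive
#' index, \eqn{z(i) = \sum_{j \le i} \Delta s / n(j)}, with \eqn{z = 0} at the
#' first pixel. The slope is \eqn{\Delta s} per pixel in air and
#' \eqn{\Delta s / 1.36} in brain tissue. `depth_scaling = "multiply"`
#' selects the alternative reading \eqn{\Delta s \cdot n(j)}.
#'
#' @param n_pixels number of axial pixels.
#' @param pitch_air_um axial pixel pitch in air, um.
#' @param n_map per-pixel refractive index, length `n_pixels`, all >= 1
#'   (see [refractive_map()]).
#' @param depth_scaling `"divide"` (geometric depth, default) or
#'   `"multiply"`.
#' @return depth per pixel in mm, strictly increasing, starting at 0.
#' @export
geometric_depth_axis <- function(n_pixels, pitch_air_um, n_map,
                                 depth_scaling = c("divide", "multiply")) {
  depth_scaling <- match.arg(depth_scaling)
  stopifnot(n_pixels >= 1, pitch_air_um > 0, length(n_map) == n_pixels)
  if (any(n_map < 1)) {
    stop("refractive indices below 1 are not physical", call. = FALSE)
  }
  step_um <- if (depth_scaling == "divide") pitch_air_um / n_map
             else pitch_air_um * n_map
  c(0, cumsum(step_um[-1])) / 1000
}
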