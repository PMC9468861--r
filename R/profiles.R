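#' OCT system profiles
#'
#' An `oct_profile` bundles the constants of one OCT configuration that every
#' downstream stage needs: wavelength, numerical aperture, pixel pitches,
#' point-spread-function resolutions, field of view, and whether the system
#' exhibits spectrometer roll-off (spectral-domain systems do; swept-source
#' systems do not).
#'
#' Two profiles are built in:
#' \describe{
#'   \item{`"ss"`}{a swept-source system at 1310 nm, NA 0.021, focal length
#'     54 mm, lateral/axial resolution 22/16 um in air, 6 x 6 mm field of
#'     view, 6 um axial pixel pitch in air, no roll-off.}
#'   \item{`"sd"`}{a spectral-domain system at 930 nm, NA 0.051, focal length
#'     36 mm, lateral/axial resolution 5.2/4.9 um in air, 2 x 5.2 mm field of
#'     view, 3 um axial pixel pitch in air, roll-off applied.}
#' }
#' The axial pixel pitches are fixed so that the standard 300 um fit window
#' spans 100 pixels ("sd") and 50 pixels ("ss").
#'
#' @param name_or_config either the name of a built-in profile (`"ss"`,
#'   `"sd"`), a path to a YAML config file, or a named list supplying every
#'   field of a custom profile.
#' @return an object of class `oct_profile`: a named list with fields
#'   `name`, `center_wavelength_nm`, `numerical_aperture`, `focal_length_mm`,
#'   `axial_pixel_pitch_air_um`, `lateral_pixel_pitch_um`,
#'   `axial_resolution_air_um`, `lateral_resolution_um`, `field_of_view_mm`
#'   (length 2), `apply_rolloff`, `max_imaging_depth_mm`.
#' @examples
#' p <- load_profile("ss")
#' p$center_wavelength_nm         # 1310
#' fit_window_pixels(p)           # 50
#' @export
load_profile <- function(name_or_config) {
  if (is.character(name_or_config) && length(name_or_config) == 1L) {
    if (name_or_config %in% names(.builtin_profiles)) {
      return(validate_profile(.builtin_profiles[[name_or_config]]))
    }
    if (file.exists(name_or_config)) {
      cfg <- yaml::read_yaml(name_or_config)
      return(load_profile(cfg))
    }
    stop("unknown profile name and no such config file: '", name_or_config,
         "' (built-ins: ", paste(names(.builtin_profiles), collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.list(name_or_config)) {
    stop("load_profile() expects a profile name, a config path, or a named list",
         call. = FALSE)
  }
  cfg <- name_or_config
  fields <- .profile_fields
  missing <- setdiff(fields, names(cfg))
  if (length(missing)) {
    stop("profile config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- structure(cfg[fields], class = "oct_profile")
  validate_profile(p)
}

.profile_fields <- c(
  "name", "center_wavelength_nm", "numerical_aperture", "focal_length_mm",
  "axial_pixel_pitch_air_um", "lateral_pixel_pitch_um",
  "axial_resolution_air_um", "lateral_resolution_um", "field_of_view_mm",
  "apply_rolloff", "max_imaging_depth_mm"
)

.builtin_profiles <- list(
  ss = structure(list(
    name = "ss",
    center_wavelength_nm = 1310,
    numerical_aperture = 0.021,
    focal_length_mm = 54,
    axial_pixel_pitch_air_um = 6,
    lateral_pixel_pitch_um = 22,
    axial_resolution_air_um = 16,
    lateral_resolution_um = 22,
    field_of_view_mm = c(6, 6),
    apply_rolloff = FALSE,
    max_imaging_depth_mm = 3.7
  ), class = "oct_profile"),
  sd = structure(list(
    name = "sd",
    center_wavelength_nm = 930,
    numerical_aperture = 0.051,
    focal_length_mm = 36,
    axial_pixel_pitch_air_um = 3,
    lateral_pixel_pitch_um = 5.2,
    axial_resolution_air_um = 4.9,
    lateral_resolution_um = 5.2,
    field_of_view_mm = c(2, 5.2),
    apply_rolloff = TRUE,
    max_imaging_depth_mm = 3.7
  ), class = "oct_profile")
)

validate_profile <- function(p) {
  stopifnot(inherits(p, "oct_profile"))
  num_pos <- c("center_wavelength_nm", "focal_length_mm",
               "axial_pixel_pitch_air_um", "lateral_pixel_pitch_um",
               "axial_resolution_air_um", "lateral_resolution_um",
               "max_imaging_depth_mm")
  for (f in num_pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("profile field '", f, "' must be a single positive number", call. = FALSE)
    }
  }
  na <- p$numerical_aperture
  if (!is.numeric(na) || length(na) != 1L || is.na(na) || na <= 0 || na >= 1) {
    stop("profile field 'numerical_aperture' must lie in (0, 1)", call. = FALSE)
  }
  fov <- p$field_of_view_mm
  if (!is.numeric(fov) || length(fov) != 2L || any(fov <= 0)) {
    stop("profile field 'field_of_view_mm' must be two positive numbers", call. = FALSE)
  }
  if (!is.logical(p$apply_rolloff) || length(p$apply_rolloff) != 1L ||
      is.na(p$apply_rolloff)) {
    stop("profile field 'apply_rolloff' must be TRUE or FALSE", call. = FALSE)
  }
  p$field_of_view_mm <- as.numeric(fov)
  p
}

#' @export
print.oct_profile <- function(x, ...) {
  cat("OCT system profile '", x$name, "'\n", sep = "")
  cat(sprintf("  wavelength    %g nm   NA %g   focal length %g mm\n",
              x$center_wavelength_nm, x$numerical_aperture, x$focal_length_mm))
  cat(sprintf("  resolution    %g um lateral / %g um axial (air)\n",
              x$lateral_resolution_um, x$axial_resolution_air_um))
  cat(sprintf("  pixel pitch   %g um lateral / %g um axial (air)\n",
              x$lateral_pixel_pitch_um, x$axial_pixel_pitch_air_um))
  cat(sprintf("  FOV           %g x %g mm   max depth %g mm   roll-off %s\n",
              x$field_of_view_mm[1], x$field_of_view_mm[2],
              x$max_imaging_depth_mm,
              if (x$apply_rolloff) "applied" else "neglected"))
  invisible(x)
}

#' Write / read a profile as a YAML config
#'
#' Round-trips exactly: `load_profile(write_profile(p, f))` has identical
#' field values.
#'
#' @param profile an `oct_profile`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  yaml::write_yaml(unclass(profile), path)
  invisible(path)
}

#' Number of pixels a fit window spans for a profile
#'
#' The fit-window length (default 300 um) is counted in in-air axial pixels,
#' matching the convention that 300 um corresponds to 100 pixels on the "sd"
#' profile and 50 pixels on the "ss" profile.
#'
#' @param profile an `oct_profile`.
#' @param fit_length_um window length in micrometers.
#' @return integer pixel count.
#' @export
fit_window_pixels <- function(profile, fit_length_um = 300) {
  as.integer(round(fit_length_um / profile$axial_pixel_pitch_air_um))
}

#' Patch geometry for a profile
#'
#' Patches are around 300 x 200 um^2: 50 x 50 pixels (axial x lateral) on the
#' "ss" profile and 100 x 50 on the "sd" profile.
#'
#' @param profile an `oct_profile`.
#' @return list with `height_px` (axial) and `width_px` (lateral).
#' @export
patch_geometry <- function(profile) {
  list(height_px = fit_window_pixels(profile, 300), width_px = 50L)
}

#' Per-pixel refractive index map along an A-scan
#'
#' Air (n = 1) above the surface pixel, tissue (default n = 1.36) at and
#' below it.
#'
#' @param n_pixels A-scan length.
#' @param surface_pixel first tissue pixel (1-based); `Inf` for all-air.
#' @param n_tissue tissue refractive index (>= 1).
#' @param n_air air refractive index (>= 1).
#' @return numeric vector of per-pixel indices.
#' @export
refractive_map <- function(n_pixels, surface_pixel, n_tissue = 1.36, n_air = 1) {
  stopifnot(n_pixels >= 1, n_tissue >= 1, n_air >= 1)
  n <- rep(n_air, n_pixels)
  if (is.finite(surface_pixel)) {
    if (surface_pixel < 1 || surface_pixel > n_pixels) {
      stop("surface_pixel outside the A-scan", call. = FALSE)
    }
    n[seq(from = surface_pixel, to = n_pixels)] <- n_tissue
  }
  n
}
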