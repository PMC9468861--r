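#' Tissue class specifications for the synthetic cohort generator
#'
#' One row per tissue class: the median attenuation coefficient and
#' backscattered intensity plus an inter-sample variation scale for each.
#' Defaults center every class on the reference medians of the chosen system
#' and set the spreads to half the reference interquartile range, so that a
#' generated cohort reproduces reference-like per-label distributions.
#' Regions drawn from a spec with zero spread carry exactly the median
#' values.
#'
#' @param system `"ss"` or `"sd"` (selects the reference medians).
#' @param spread_scale multiplier on the default spreads (0 gives
#'   deterministic medians).
#' @return data.frame with columns `label`, `mu_median`, `mu_spread`,
#'   `i0_median`, `i0_spread` (mu in 1/mm, i0 in a.u.).
#' @export
tissue_class_specs <- function(system = c("ss", "sd"), spread_scale = 1) {
  system <- match.arg(system)
  stopifnot(spread_scale >= 0)
  ref <- reference_optical_properties()
  ref <- ref[ref$system == system, ]
  data.frame(
    label = ref$label,
    mu_median = ref$mu,
    mu_spread = spread_scale * (ref$mu_q75 - ref$mu_q25) / 2,
    i0_median = ref$i0,
    i0_spread = spread_scale * (ref$i0_q75 - ref$i0_q25) / 2,
    stringsAsFactors = FALSE
  )
}

.noise_spec <- function(noise) {
  if (is.character(noise) && length(noise) == 1L) {
    noise <- list(type = noise)
  }
  stopifnot(is.list(noise))
  type <- noise$type %||% "none"
  if (!type %in% c("none", "speckle")) {
    stop("unknown noise type '", type, "' (use \"none\" or \"speckle\")",
         call. = FALSE)
  }
  list(type = type, background = noise$background %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expected (noise-free) A-scan under the single-scattering forward model:
# A^2(z) = r(xi) * h(z) * I0 * exp(-2 mu (z - z_s)) at and below the surface,
# evaluated on the geometric depth axis with the refraction-shifted focus.
.ascan_expectation <- function(profile, mu, i0, surface_pixel, confocal,
                               rolloff = NULL, n_pixels, n_tissue = 1.36,
                               depth_scaling = "divide") {
  stopifnot(mu >= 0, i0 > 0)
  if (surface_pixel < 1 || surface_pixel > n_pixels) {
    stop("surface_pixel outside the A-scan", call. = FALSE)
  }
  pitch <- profile$axial_pixel_pitch_air_um
  nmap <- refractive_map(n_pixels, surface_pixel, n_tissue = n_tissue)
  z <- geometric_depth_axis(n_pixels, pitch, nmap, depth_scaling)
  depth_air <- (seq_len(n_pixels) - 1) * pitch / 1000
  z_s <- z[surface_pixel]
  sf <- shift_focus(confocal$focus_mm, z_s, n1 = 1, n2 = n_tissue,
                    numerical_aperture = profile$numerical_aperture)
  below <- seq_len(n_pixels) >= surface_pixel
  h <- numeric(n_pixels)
  h[below] <- .tissue_confocal_gain(z[below], confocal, sf$shifted_focus_mm,
                                    n_tissue)
  r <- rep(1, n_pixels)
  if (!is.null(rolloff)) {
    r <- rolloff_value(xi_depth(depth_air, profile$max_imaging_depth_mm),
                       rolloff)
  }
  expect <- numeric(n_pixels)
  expect[below] <- r[below] * h[below] * i0 * exp(-2 * mu * (z[below] - z_s))
  list(expectation = expect, depth_mm = z, depth_air_mm = depth_air,
       surface_depth_mm = z_s, shifted_focus_mm = sf$shifted_focus_mm,
       rolloff_gain = r, confocal_gain = h)
}

# Confocal gain inside the tissue: Lorentzian about the refraction-shifted
# focus, width set by the Rayleigh length scaled with the tissue index.
.tissue_confocal_gain <- function(z_mm, confocal, shifted_focus_mm, n_tissue) {
  confocal$amplitude /
    (1 + ((z_mm - shifted_focus_mm) / (n_tissue * confocal$rayleigh_mm))^2)
}

#' Simulate a single A-scan under the single-scattering forward model
#'
#' The expected intensity at and below the tissue surface is
#' `r(xi) * h(z) * I0 * exp(-2 mu (z - z_s))`, with `r` the spectrometer
#' roll-off (omitted when `rolloff` is `NULL`), `h` the confocal collection
#' efficiency evaluated on the geometric depth axis with the
#' refraction-shifted focus, and depth measured geometrically (pixel pitch
#' divided by the local refractive index). Pixels above the surface hold
#' background only. With `noise = "none"` the returned intensities equal the
#' expectation exactly; with `noise = "speckle"` each pixel is drawn from an
#' exponential distribution with the (expectation + background) as its mean
#' — fully developed speckle.
#'
#' @param profile an `oct_profile`.
#' @param mu attenuation coefficient, 1/mm, >= 0.
#' @param i0 backscattered intensity at the surface, a.u., > 0.
#' @param surface_pixel 1-based index of the first tissue pixel.
#' @param confocal a `confocal_model` (air coordinates; the focus shift into
#'   the tissue is applied internally).
#' @param rolloff a `rolloff_model`, or `NULL` to neglect roll-off.
#' @param n_pixels A-scan length in pixels.
#' @param noise `"none"`, `"speckle"`, or a list
#'   `list(type =, background =)`; `background` is an additive mean
#'   intensity floor (a.u.).
#' @param seed optional integer seed (set before drawing noise).
#' @param n_tissue tissue refractive index.
#' @param depth_scaling see [geometric_depth_axis()].
#' @return list of class `oct_ascan`: `intensity`, `expectation`,
#'   `depth_mm`, `surface_pixel`, `surface_depth_mm`, `shifted_focus_mm`,
#'   `truth` (list with `mu`, `i0`).
#' @export
simulate_ascan <- function(profile, mu, i0, surface_pixel, confocal,
                           rolloff = NULL, n_pixels = 400, noise = "none",
                           seed = NULL, n_tissue = 1.36,
                           depth_scaling = "divide") {
  ns <- .noise_spec(noise)
  ex <- .ascan_expectation(profile, mu, i0, surface_pixel, confocal, rolloff,
                           n_pixels, n_tissue, depth_scaling)
  mean_int <- ex$expectation + ns$background
  if (!is.null(seed)) set.seed(seed)
  intensity <- switch(ns$type,
    none = mean_int,
    speckle = mean_int * stats::rexp(n_pixels, rate = 1)
  )
  structure(list(intensity = intensity, expectation = ex$expectation,
                 depth_mm = ex$depth_mm, surface_pixel = surface_pixel,
                 surface_depth_mm = ex$surface_depth_mm,
                 shifted_focus_mm = ex$shifted_focus_mm,
                 profile_name = profile$name,
                 truth = list(mu = mu, i0 = i0)),
            class = "oct_ascan")
}

# Draw a region parameter log-normally around its class median. `spread`
# is an additive scale (same units as `median`), mapped to a geometric
# standard deviation; spread 0 returns the median exactly.
.draw_lognormal <- function(median, spread) {
  sdlog <- log1p(spread / median)
  median * exp(stats::rnorm(1, 0, sdlog))
}

#' Simulate a labeled B-scan
#'
#' Assembles per-column A-scans from the single-scattering forward model into
#' a B-scan with a per-pixel label mask and a surface line. The layout is a
#' per-column label vector; each contiguous run of one label forms a region
#' whose (mu, i0) are drawn once, log-normally around the class medians, and
#' recorded as ground truth.
#'
#' @param profile an `oct_profile`.
#' @param class_layout character vector, one tissue label per column.
#' @param class_specs data.frame as from [tissue_class_specs()].
#' @param confocal,rolloff forward-model components (see [simulate_ascan()]).
#' @param surface_row surface pixel per column (scalar recycled; may be a
#'   vector for tilted surfaces).
#' @param n_pixels axial size of the image.
#' @param noise,seed,n_tissue see [simulate_ascan()].
#' @param patient_id,sample_id,bscan_id provenance identifiers.
#' @param param_scale optional named list `list(mu =, i0 =)` of
#'   multiplicative factors applied to the drawn region parameters (used for
#'   patient-level effects).
#' @return object of class `oct_bscan`: `image` (rows x cols), `mask`
#'   (character matrix, `NA` above the surface), `surface` (row per column),
#'   `ground_truth` (data.frame: region, label, col_start, col_end, mu, i0),
#'   provenance ids and the profile name.
#' @export
simulate_bscan <- function(profile, class_layout, class_specs, confocal,
                           rolloff = NULL, surface_row = 11, n_pixels = 400,
                           noise = "none", seed = NULL, n_tissue = 1.36,
                           patient_id = "P1", sample_id = "S1",
                           bscan_id = "B1", param_scale = NULL) {
  if (length(class_layout) == 0) stop("empty class layout", call. = FALSE)
  unknown <- setdiff(unique(class_layout), class_specs$label)
  if (length(unknown)) {
    stop("layout labels missing from class_specs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  width <- length(class_layout)
  surface <- as.integer(round(rep_len(surface_row, width)))
  if (any(surface < 1 | surface > n_pixels)) {
    stop("surface outside image", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  runs <- rle(class_layout)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gt <- data.frame(region = seq_along(runs$values), label = runs$values,
                   col_start = starts, col_end = ends,
                   mu = NA_real_, i0 = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(gt))) {
    sp <- class_specs[class_specs$label == gt$label[k], ]
    mu <- .draw_lognormal(sp$mu_median, sp$mu_spread)
    i0 <- .draw_lognormal(sp$i0_median, sp$i0_spread)
    if (!is.null(param_scale)) {
      mu <- mu * (param_scale$mu %||% 1)
      i0 <- i0 * (param_scale$i0 %||% 1)
    }
    gt$mu[k] <- mu
    gt$i0[k] <- i0
  }
  image <- matrix(0, nrow = n_pixels, ncol = width)
  mask <- matrix(NA_character_, nrow = n_pixels, ncol = width)
  for (k in seq_len(nrow(gt))) {
    for (col in gt$col_start[k]:gt$col_end[k]) {
      a <- simulate_ascan(profile, gt$mu[k], gt$i0[k], surface[col], confocal,
                          rolloff, n_pixels, noise, seed = NULL,
                          n_tissue = n_tissue)
      image[, col] <- a$intensity
      mask[surface[col]:n_pixels, col] <- gt$label[k]
    }
  }
  structure(list(image = image, mask = mask, surface = surface,
                 ground_truth = gt, profile_name = profile$name,
                 patient_id = patient_id, sample_id = sample_id,
                 bscan_id = bscan_id, n_tissue = n_tissue),
            class = "oct_bscan")
}

#' @export
print.oct_bscan <- function(x, ...) {
  cat(sprintf("OCT B-scan %s/%s/%s (%s profile): %d x %d px, %d region(s): %s\n",
              x$patient_id, x$sample_id, x$bscan_id, x$profile_name,
              nrow(x$image), ncol(x$image), nrow(x$ground_truth),
              paste(unique(x$ground_truth$label), collapse = ", ")))
  invisible(x)
}

#' Simulate a mirror-sweep calibration measurement
#'
#' Two sweep kinds mirror the two calibration procedures:
#' \describe{
#'   \item{`"reference_arm_only"`}{the mirror is moved through the imaging
#'     window by adjusting only the reference-arm length, so the beam focus
#'     never moves relative to the mirror: the peak intensities sample the
#'     roll-off `r(xi)` alone.}
#'   \item{`"fixed_reference"`}{the mirror is moved physically with reference
#'     length and focus fixed: the peak intensities sample the product
#'     `r(xi) * h(z)`; dividing out `r` is the caller's job (see
#'     [fit_confocal()]).}
#' }
#'
#' @param profile an `oct_profile` (supplies the maximum imaging depth that
#'   normalizes `xi`).
#' @param sweep_kind `"reference_arm_only"` or `"fixed_reference"`.
#' @param true_rolloff a `rolloff_model`, or `NULL` (no roll-off, e.g. a
#'   swept-source system).
#' @param true_confocal a `confocal_model` (air: the mirror sweep is in air,
#'   n = 1).
#' @param n_positions number of mirror positions, >= 4.
#' @param noise_sd relative (multiplicative Gaussian) noise on the peak
#'   intensities.
#' @param seed optional integer seed.
#' @param depth_range_mm range of mirror positions (defaults to 2% - 95% of
#'   the maximum imaging depth).
#' @return object of class `mirror_sweep`: `depth_mm`, `intensity`, `kind`,
#'   `max_depth_mm`, `profile_name`.
#' @export
simulate_mirror_sweep <- function(profile,
                                  sweep_kind = c("reference_arm_only",
                                                 "fixed_reference"),
                                  true_rolloff = NULL, true_confocal = NULL,
                                  n_positions = 50, noise_sd = 0, seed = NULL,
                                  depth_range_mm = NULL) {
  sweep_kind <- match.arg(sweep_kind)
  if (n_positions < 4) {
    stop("a mirror sweep needs at least 4 positions", call. = FALSE)
  }
  zmax <- profile$max_imaging_depth_mm
  if (is.null(depth_range_mm)) depth_range_mm <- c(0.02, 0.95) * zmax
  depth <- seq(depth_range_mm[1], depth_range_mm[2], length.out = n_positions)
  r <- if (is.null(true_rolloff)) rep(1, n_positions)
       else rolloff_value(xi_depth(depth, zmax), true_rolloff)
  intensity <- switch(sweep_kind,
    reference_arm_only = r,
    fixed_reference = {
      if (is.null(true_confocal)) {
        stop("fixed_reference sweep needs a confocal model", call. = FALSE)
      }
      r * confocal_value(depth, true_confocal)
    })
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    intensity <- intensity * (1 + stats::rnorm(n_positions, 0, noise_sd))
    intensity <- pmax(intensity, .Machine$double.eps)
  }
  structure(list(depth_mm = depth, intensity = intensity, kind = sweep_kind,
                 max_depth_mm = zmax, profile_name = profile$name),
            class = "mirror_sweep")
}

#' Generate a multi-patient synthetic cohort
#'
#' Builds the full input of a leave-one-patient-out study: `n_patients`
#' patients, each contributing `samples_per_patient` samples of
#' `bscans_per_sample` labeled B-scans. Per-patient class proportions are
#' drawn around `class_mix` (so folds are non-trivial) and a mild
#' patient-level multiplicative effect on (mu, i0) makes patches from one
#' patient correlated. Deterministic under `seed`.
#'
#' @param n_patients number of patients, >= 2.
#' @param samples_per_patient samples per patient.
#' @param class_mix named numeric vector of label proportions summing to 1.
#' @param profile an `oct_profile`.
#' @param seed integer seed (mandatory).
#' @param class_specs as [tissue_class_specs()]; defaults to the profile's
#'   system with full spread.
#' @param confocal,rolloff forward-model components; defaults: focus 0.9 mm /
#'   Rayleigh 0.3 mm, and for roll-off (when the profile applies it)
#'   omega 1.5.
#' @param bscans_per_sample B-scans per sample.
#' @param regions_per_bscan lateral regions per B-scan.
#' @param region_width_px columns per region.
#' @param n_pixels axial image size.
#' @param noise noise spec (default speckle with a small background floor).
#' @param patient_effect_sdlog log-scale SD of the patient-level effect.
#' @return object of class `oct_cohort`: `bscans` (list of `oct_bscan`),
#'   `patients` (data.frame), `profile_name`, `seed`, models used.
#' @export
generate_cohort <- function(n_patients, samples_per_patient, class_mix,
                            profile, seed, class_specs = NULL,
                            confocal = NULL, rolloff = NULL,
                            bscans_per_sample = 2, regions_per_bscan = 4,
                            region_width_px = 100, n_pixels = NULL,
                            noise = list(type = "speckle", background = 1e-5),
                            patient_effect_sdlog = 0.05) {
  if (n_patients < 2) {
    stop("leave-one-patient-out needs at least 2 patients", call. = FALSE)
  }
  if (abs(sum(class_mix) - 1) > 1e-6) {
    stop("class_mix proportions must sum to 1", call. = FALSE)
  }
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix)))) {
    stop("class_mix must be a named vector of label proportions", call. = FALSE)
  }
  if (is.null(class_specs)) {
    sys <- if (profile$name %in% c("ss", "sd")) profile$name else "ss"
    class_specs <- tissue_class_specs(sys)
  }
  unknown <- setdiff(names(class_mix), class_specs$label)
  if (length(unknown)) {
    stop("class_mix labels missing from class_specs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(confocal)) confocal <- confocal_model(0.9, 0.3)
  if (is.null(rolloff) && profile$apply_rolloff) rolloff <- rolloff_model(1.5)
  gp <- patch_geometry(profile)
  if (is.null(n_pixels)) n_pixels <- max(200L, 2L * gp$height_px + 40L)

  set.seed(seed)
  labels <- names(class_mix)
  patients <- data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
                         stringsAsFactors = FALSE)
  bscans <- list()
  for (p in seq_len(n_patients)) {
    # patient-specific label proportions: Dirichlet-like jitter around the mix
    g <- stats::rgamma(length(class_mix), shape = pmax(class_mix, 1e-6) * 20)
    props <- g / sum(g)
    scale_p <- list(mu = exp(stats::rnorm(1, 0, patient_effect_sdlog)),
                    i0 = exp(stats::rnorm(1, 0, patient_effect_sdlog)))
    for (s in seq_len(samples_per_patient)) {
      for (b in seq_len(bscans_per_sample)) {
        region_labels <- sample(labels, regions_per_bscan, replace = TRUE,
                                prob = props)
        # guarantee every mixed-in label appears somewhere in the cohort:
        # force the first sample of patient p to cycle through the labels
        if (s == 1 && b == 1) {
          region_labels[1] <- labels[((p - 1) %% length(labels)) + 1]
        }
        layout <- rep(region_labels, each = region_width_px)
        bs <- simulate_bscan(profile, layout, class_specs, confocal, rolloff,
                             surface_row = 11, n_pixels = n_pixels,
                             noise = noise,
                             patient_id = patients$patient_id[p],
                             sample_id = sprintf("%s_S%02d",
                                                 patients$patient_id[p], s),
                             bscan_id = sprintf("B%02d", b),
                             param_scale = scale_p)
        bscans[[length(bscans) + 1L]] <- bs
      }
    }
  }
  structure(list(bscans = bscans, patients = patients,
                 profile_name = profile$name, seed = seed,
                 class_specs = class_specs, confocal = confocal,
                 rolloff = rolloff),
            class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf("Synthetic OCT cohort: %d patients, %d B-scans (%s profile, seed %d)\n",
              nrow(x$patients), length(x$bscans), x$profile_name, x$seed))
  invisible(x)
}
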