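#' Detect the air/tissue surface in a B-scan
#'
#' Per column, the surface is the first row whose intensity exceeds a
#' background threshold. The threshold is the background mean plus
#' `k_sd` standard deviations, estimated from the top `bg_rows` rows of the
#' image; when the background is exactly constant (noise-free synthetic
#' images) a fallback of `1e-3 * max(image)` above the background mean is
#' used. The crossing is located on a boxcar-smoothed column profile and then
#' refined to the first raw-intensity crossing (so a noise-free flat surface
#' is recovered exactly), and the resulting surface line is median-filtered
#' across columns.
#'
#' @param bscan an `oct_bscan`, or a plain intensity matrix (rows = depth).
#' @param bg_rows rows used to estimate the background, from the image top.
#' @param k_sd threshold in background standard deviations.
#' @param smooth_width boxcar width (pixels) for the column profile; 1
#'   disables smoothing.
#' @param median_width across-column median filter width (odd; 1 disables).
#' @param max_missing_frac error when more than this fraction of columns has
#'   no crossing.
#' @return integer surface row per column (`NA` where no crossing).
#' @export
detect_surface <- function(bscan, bg_rows = 5, k_sd = 5, smooth_width = 3,
                           median_width = 5, max_missing_frac = 0.5) {
  img <- if (inherits(bscan, "oct_bscan")) bscan$image else bscan
  stopifnot(is.matrix(img), nrow(img) > bg_rows, ncol(img) >= 1)
  bg <- img[seq_len(bg_rows), , drop = FALSE]
  thr <- mean(bg) + k_sd * stats::sd(as.numeric(bg))
  if (!is.finite(thr) || stats::sd(as.numeric(bg)) == 0) {
    thr <- mean(bg) + 1e-3 * max(img)
  }
  n_rows <- nrow(img)
  half <- floor(smooth_width / 2)
  surface <- vapply(seq_len(ncol(img)), function(col) {
    prof <- img[, col]
    sm <- if (smooth_width > 1) {
      as.numeric(stats::filter(prof, rep(1 / smooth_width, smooth_width),
                               sides = 2))
    } else prof
    cross <- which(!is.na(sm) & sm > thr)
    if (!length(cross)) return(NA_integer_)
    i <- cross[1]
    # refine on the raw profile within the smoothing radius
    win <- max(1, i - half):min(n_rows, i + half)
    raw <- win[prof[win] > thr]
    as.integer(if (length(raw)) raw[1] else i)
  }, integer(1))
  missing <- mean(is.na(surface))
  if (missing > max_missing_frac) {
    stop(sprintf("surface detection failed: %.0f%% of columns have no crossing",
                 100 * missing), call. = FALSE)
  }
  if (median_width > 1 && sum(!is.na(surface)) >= median_width) {
    ok <- !is.na(surface)
    surface[ok] <- as.integer(stats::runmed(surface[ok], median_width))
  }
  surface
}

#' Extract homogeneous labeled patches from a B-scan
#'
#' Lateral tiling of fixed-size patches (profile-dependent: 50 x 50 px on
#' "ss", 100 x 50 px axial x lateral on "sd"), each overlapping the previous
#' by `overlap_px` pixels (stride = width - overlap) and starting
#' `surface_offset_px` pixels below the tissue surface. A candidate patch is
#' kept only when every pixel of its mask region carries one single label
#' (strict homogeneity; `homogeneity_frac` relaxes this to a minimum
#' majority fraction) and the patch lies fully inside the image.
#'
#' @param bscan an `oct_bscan` (with `mask` and `surface`; the surface may
#'   be re-detected with [detect_surface()]).
#' @param profile the `oct_profile` the B-scan was acquired with.
#' @param surface_offset_px patch top relative to the surface (pixels).
#' @param overlap_px lateral overlap between consecutive patches.
#' @param homogeneity_frac minimum fraction of mask pixels sharing the modal
#'   label (1 = strict).
#' @param surface override surface line (row per column).
#' @return list of `oct_patch` objects; each has `pixels`
#'   (height x width matrix), `label`, `patient_id`, `sample_id`,
#'   `bscan_id`, `column_start`, `top_row`, `surface_offset_px`, and (when
#'   the B-scan carries ground truth) `truth` with the region's (mu, i0).
#' @export
extract_patches <- function(bscan, profile, surface_offset_px = 10,
                            overlap_px = 10, homogeneity_frac = 1,
                            surface = NULL) {
  stopifnot(inherits(bscan, "oct_bscan"))
  if (is.null(surface)) surface <- bscan$surface
  if (is.null(surface)) stop("no surface line available", call. = FALSE)
  gp <- patch_geometry(profile)
  H <- gp$height_px
  W <- gp$width_px
  stride <- as.integer(W - overlap_px)
  stopifnot(stride >= 1)
  img <- bscan$image
  mask <- bscan$mask
  patches <- list()
  starts <- seq(1L, by = stride, length.out = max(0L, (ncol(img) - W) %/% stride + 1L))
  for (cs in starts) {
    cols <- cs:(cs + W - 1L)
    surf <- surface[cols]
    if (anyNA(surf)) next
    top <- as.integer(round(stats::median(surf)) + surface_offset_px)
    bottom <- top + H - 1L
    if (top < 1L || bottom > nrow(img)) next
    rows <- top:bottom
    lab <- mask[rows, cols]
    if (anyNA(lab)) next
    tab <- table(lab)
    modal <- names(tab)[which.max(tab)]
    if (max(tab) / length(lab) < homogeneity_frac) next
    if (homogeneity_frac >= 1 && length(tab) > 1L) next
    truth <- NULL
    if (!is.null(bscan$ground_truth)) {
      gt <- bscan$ground_truth
      hit <- gt$col_start <= cols[1] & gt$col_end >= cols[W] & gt$label == modal
      if (any(hit)) truth <- list(mu = gt$mu[which(hit)[1]],
                                  i0 = gt$i0[which(hit)[1]])
    }
    patches[[length(patches) + 1L]] <- structure(list(
      pixels = img[rows, cols, drop = FALSE],
      label = modal,
      patient_id = bscan$patient_id, sample_id = bscan$sample_id,
      bscan_id = bscan$bscan_id,
      column_start = as.integer(cs), top_row = top,
      surface_offset_px = surface_offset_px,
      profile_name = bscan$profile_name,
      truth = truth
    ), class = "oct_patch")
  }
  patches
}

#' Average a B-scan patch into one A-scan
#'
#' Arithmetic mean over the lateral dimension at each depth, in linear
#' intensity; the result has the patch height.
#'
#' @param patch an `oct_patch` or a matrix (rows = depth).
#' @return numeric vector of length `nrow(patch)`.
#' @export
average_patch <- function(patch) {
  px <- if (inherits(patch, "oct_patch")) patch$pixels else patch
  stopifnot(is.matrix(px))
  rowMeans(px)
}

#' Extract all patches of a cohort
#'
#' Applies [extract_patches()] to every B-scan of a synthetic cohort.
#'
#' @param cohort an `oct_cohort`.
#' @param profile the matching `oct_profile`.
#' @param ... passed to [extract_patches()].
#' @return flat list of `oct_patch`.
#' @export
cohort_patches <- function(cohort, profile, ...) {
  stopifnot(inherits(cohort, "oct_cohort"))
  out <- lapply(cohort$bscans, extract_patches, profile = profile, ...)
  do.call(c, out)
}

#' Manifest of a patch list
#'
#' @param patches list of `oct_patch`.
#' @return data.frame with one row per patch (id, provenance, label,
#'   geometry, and ground-truth mu/i0 where available).
#' @export
patch_manifest <- function(patches) {
  if (!length(patches)) {
    return(data.frame(patch_id = character(), patient_id = character(),
                      sample_id = character(), bscan_id = character(),
                      label = character(), column_start = integer(),
                      top_row = integer(), true_mu = numeric(),
                      true_i0 = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    patch_id = sprintf("patch%05d", seq_along(patches)),
    patient_id = vapply(patches, `[[`, "", "patient_id"),
    sample_id = vapply(patches, `[[`, "", "sample_id"),
    bscan_id = vapply(patches, `[[`, "", "bscan_id"),
    label = vapply(patches, `[[`, "", "label"),
    column_start = vapply(patches, `[[`, 0L, "column_start"),
    top_row = vapply(patches, `[[`, 0L, "top_row"),
    true_mu = vapply(patches, function(p) p$truth$mu %||% NA_real_, 0),
    true_i0 = vapply(patches, function(p) p$truth$i0 %||% NA_real_, 0),
    stringsAsFactors = FALSE
  )
}
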