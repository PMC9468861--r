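#' Reference optical properties of brain tissue classes
#'
#' Median attenuation coefficient (mu, per mm of geometric depth) and
#' normalized backscattered intensity (i0, arbitrary units) with 25th/75th
#' percentiles, for the five tissue classes used throughout the package —
#' healthy gray matter (GM0%), healthy white matter (WM0%) and white matter
#' at three tumor-infiltration grades (WM0-30%, WM30-60%, WM>60%) — as
#' determined ex vivo on each of the two system configurations ("sd": 930 nm
#' spectral-domain, "ss": 1310 nm swept-source). Attenuation in white matter
#' falls with increasing infiltration as myelin degrades; gray matter
#' resembles infiltrated white matter.
#'
#' These values parameterize the synthetic cohort generator
#' ([tissue_class_specs()]) and serve as inputs to the between-system
#' comparison ([compare_systems()]).
#'
#' @return a data.frame with columns `system`, `label`, `mu`, `mu_q25`,
#'   `mu_q75`, `i0`, `i0_q25`, `i0_q75`.
#' @examples
#' ref <- reference_optical_properties()
#' subset(ref, system == "ss", c(label, mu))
#' @export
reference_optical_properties <- function() {
  data.frame(
    system = rep(c("sd", "ss"), each = 5),
    label = rep(c("GM0%", "WM0%", "WM0-30%", "WM30-60%", "WM>60%"), 2),
    mu     = c(6.93, 12.58, 10.21, 6.95, 4.79,
               1.85, 4.93, 3.91, 2.05, 1.22),
    mu_q25 = c(5.18, 10.52, 5.72, 5.46, 3.32,
               1.21, 4.47, 1.70, 1.05, 0.72),
    mu_q75 = c(9.22, 15.55, 12.80, 10.41, 6.06,
               2.71, 5.41, 4.39, 3.67, 1.81),
    i0     = c(0.04, 0.08, 0.05, 0.04, 0.01,
               0.18, 0.40, 0.16, 0.13, 0.11),
    i0_q25 = c(0.02, 0.04, 0.02, 0.02, 0.01,
               0.13, 0.29, 0.12, 0.11, 0.08),
    i0_q75 = c(0.07, 0.15, 0.08, 0.06, 0.03,
               0.25, 0.49, 0.24, 0.17, 0.14),
    stringsAsFactors = FALSE
  )
}

#' Tissue labels recognized by the pipeline
#' @return character vector of the five class labels.
#' @export
tissue_labels <- function() {
  c("GM0%", "WM0%", "WM0-30%", "WM30-60%", "WM>60%")
}

#' Integer codes used when label masks are written to indexed TIFF
#'
#' 0 encodes background/air; 1..5 encode the five tissue classes in the
#' order of [tissue_labels()].
#' @return named integer vector (names are labels).
#' @export
label_codes <- function() {
  stats::setNames(seq_along(tissue_labels()), tissue_labels())
}
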