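# shared fixtures: a nontrivial confocal model, its calibration bundle, and
# a convenience noiseless round trip through correct + fit
fix_confocal <- function() confocal_model(focus_mm = 0.9, rayleigh_mm = 0.25)

fix_calibration <- function(rolloff = NULL) {
  as_calibration(fix_confocal(), rolloff)
}

# simulate one noiseless A-scan and recover (mu, i0) through the pipeline
roundtrip_fit <- function(profile, mu, i0, rolloff = NULL, surface_pixel = 11,
                          n_pixels = 450) {
  a <- simulate_ascan(profile, mu, i0, surface_pixel, fix_confocal(),
                      rolloff = rolloff, n_pixels = n_pixels)
  corr <- correct_ascan(a, profile, fix_calibration(rolloff))
  fit_attenuation(corr, profile)
}

# reference per-label medians as named vectors, one per system
ref_medians <- function(parameter = c("mu", "i0")) {
  parameter <- match.arg(parameter)
  ref <- reference_optical_properties()
  lapply(split(ref, ref$system), function(d) {
    stats::setNames(d[[parameter]], d$label)
  })
}
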