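test_that("the correction removes exactly what the forward model applied", {
  for (name in c("ss", "sd")) {
    p <- load_profile(name)
    ro <- if (p$apply_rolloff) rolloff_model(1.8) else NULL
    a <- simulate_ascan(p, 3.5, 0.2, 11, fix_confocal(), rolloff = ro,
                        n_pixels = 450)
    corr <- correct_ascan(a, p, fix_calibration(ro))
    below <- which(corr$valid)
    pure <- 0.2 * exp(-2 * 3.5 * (corr$depth_mm[below] - corr$surface_depth_mm))
    expect_equal(corr$corrected[below], pure, tolerance = 1e-9)
  }
})

test_that("deep pixels with vanishing gain are flagged, not amplified", {
  p <- load_profile("ss")
  # tiny Rayleigh length: the confocal gain collapses at depth
  cm <- confocal_model(0.1, 0.001)
  a <- simulate_ascan(p, 1, 0.3, 11, cm, n_pixels = 400)
  corr <- correct_ascan(a, p, as_calibration(cm))
  expect_true(any(!corr$valid[11:400]))
  expect_true(all(is.na(corr$corrected[!corr$valid])))
})

test_that("mu and I0 are recovered exactly from noiseless input", {
  p <- load_profile("ss")
  fit <- roundtrip_fit(p, 4.93, 0.40)
  expect_equal(fit$mu, 4.93, tolerance = 1e-6)
  expect_equal(fit$i0, 0.40, tolerance = 1e-6)
  expect_identical(fit$n_points, 50L)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_false(fit$nonphysical)
})

test_that("a constant corrected signal fits mu = 0", {
  p <- load_profile("ss")
  fit <- roundtrip_fit(p, 0, 0.25)
  expect_equal(fit$mu, 0, tolerance = 1e-10)
})

test_that("mu is linear in the generating slope and invariant to intensity scale", {
  p <- load_profile("sd")
  f1 <- roundtrip_fit(p, 2.5, 0.1)
  f2 <- roundtrip_fit(p, 5.0, 0.1)
  expect_equal(f2$mu / f1$mu, 2, tolerance = 1e-9)
  # global rescaling: mu unchanged, i0 scales
  a <- simulate_ascan(p, 2.5, 0.1, 11, fix_confocal(), n_pixels = 450)
  a$intensity <- a$intensity * 1000
  f3 <- fit_attenuation(correct_ascan(a, p, fix_calibration()), p)
  expect_equal(f3$mu, f1$mu, tolerance = 1e-9)
  expect_equal(f3$i0 / f1$i0, 1000, tolerance = 1e-9)
})

test_that("fit window errors are raised for short or flagged data", {
  p <- load_profile("ss")
  a <- simulate_ascan(p, 2, 0.3, 11, fix_confocal(), n_pixels = 40)
  corr <- correct_ascan(a, p, fix_calibration())
  expect_error(fit_attenuation(corr, p), "past the end")
  a2 <- simulate_ascan(p, 2, 0.3, 11, fix_confocal(), n_pixels = 450)
  corr2 <- correct_ascan(a2, p, fix_calibration())
  corr2$valid[30] <- FALSE
  expect_error(fit_attenuation(corr2, p), "invalid")
  # > 20% nonpositive intensities abort the fit
  corr3 <- correct_ascan(a2, p, fix_calibration())
  corr3$corrected[21:40] <- 0
  expect_error(fit_attenuation(corr3, p), "nonpositive")
})

test_that("oct_fit methods are coherent", {
  p <- load_profile("ss")
  fit <- roundtrip_fit(p, 3, 0.2)
  expect_named(coef(fit), c("mu", "i0"))
  expect_length(residuals(fit), fit$n_used)
  pred <- predict(fit)
  expect_equal(log(pred), fit$data$log_intensity - residuals(fit),
               tolerance = 1e-9)
  expect_output(print(fit), "mu")
  expect_output(summary(fit), "Attenuation coefficient")
})

test_that("round-trip recovery holds across the attenuation range and profiles", {
  mus <- c(0.5, 1.22, 2.05, 3.91, 4.93, 8, 12.58, 15)
  for (name in c("ss", "sd")) {
    p <- load_profile(name)
    ro <- if (p$apply_rolloff) rolloff_model(2.3) else NULL
    for (mu in mus) {
      fit <- roundtrip_fit(p, mu, 0.17, rolloff = ro)
      expect_lt(abs(fit$mu - mu) / max(mu, 1e-9), 1e-6)
      expect_lt(abs(fit$i0 - 0.17) / 0.17, 1e-6)
    }
  }
})

test_that("batch fitting isolates failures and normalizes I0 to the batch max", {
  p <- load_profile("ss")
  specs <- tissue_class_specs("ss", spread_scale = 0)
  bs <- simulate_bscan(p, rep(c("WM0%", "WM>60%"), each = 100), specs,
                       fix_confocal(), surface_row = 11, n_pixels = 200,
                       seed = 8)
  patches <- extract_patches(bs, p)
  expect_length(patches, 3)   # the straddling candidate is dropped
  # corrupt one patch so its window is entirely nonpositive
  patches[[3]]$pixels[] <- 0
  fits <- batch_fit(patches, p, fix_calibration())
  expect_identical(sum(!fits$ok), 1L)
  expect_false(fits$ok[3])
  expect_match(fits$error[3], "nonpositive")
  expect_equal(max(fits$i0_normalized[fits$ok]), 1.0)
  # two identical patches (same zero-spread region) fit identically
  expect_equal(fits$mu[1], fits$mu[2], tolerance = 1e-9)
})

test_that("under speckle the batched estimator is unbiased and monotone", {
  p <- load_profile("ss")
  cal <- fix_calibration()
  specs <- tissue_class_specs("ss", spread_scale = 0)
  grid <- c(1.22, 2.05, 3.91, 4.93)
  n_rep <- 60
  means <- vapply(grid, function(mu) {
    specs2 <- specs
    specs2$mu_median[specs2$label == "WM0%"] <- mu
    mus <- vapply(seq_len(n_rep), function(i) {
      bs <- simulate_bscan(p, rep("WM0%", 50), specs2, fix_confocal(),
                           surface_row = 11, n_pixels = 120,
                           noise = list(type = "speckle", background = 1e-6),
                           seed = 2000 + i)
      batch_fit(extract_patches(bs, p), p, cal)$mu[1]
    }, 0)
    mean(mus)
  }, 0)
  expect_true(all(abs(means - grid) / grid < 0.03))
  expect_true(all(diff(means) > 0))
})
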