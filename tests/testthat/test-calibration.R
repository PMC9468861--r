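test_that("roll-off calibration recovers the generating omega exactly", {
  p <- load_profile("sd")
  for (omega in c(0.7, 2.0, 3.0)) {
    sw <- simulate_mirror_sweep(p, "reference_arm_only", rolloff_model(omega),
                                fix_confocal(), 50)
    fit <- fit_rolloff(sw)
    expect_equal(fit$model$omega, omega, tolerance = 1e-3)
    expect_lt(fit$residual_norm, 1e-8)
  }
})

test_that("a near-constant sweep yields omega near zero", {
  p <- load_profile("sd")
  # sample only the shallow region where sinc^2 is ~1 and omega = 0
  sw <- simulate_mirror_sweep(p, "reference_arm_only", rolloff_model(0),
                              fix_confocal(), 20,
                              depth_range_mm = c(0.01, 0.12))
  fit <- fit_rolloff(sw)
  expect_lt(fit$model$omega, 0.05)
})

test_that("roll-off recovery tolerates 5% noise within 5%", {
  p <- load_profile("sd")
  for (rep in 1:3) {
    sw <- simulate_mirror_sweep(p, "reference_arm_only", rolloff_model(2),
                                fix_confocal(), 50, noise_sd = 0.05,
                                seed = 100 + rep)
    fit <- fit_rolloff(sw)
    expect_lt(abs(fit$model$omega - 2) / 2, 0.05)
  }
})

test_that("confocal calibration recovers focus and Rayleigh length exactly", {
  p <- load_profile("sd")
  ro <- rolloff_model(2)
  sw <- simulate_mirror_sweep(p, "fixed_reference", ro,
                              confocal_model(1.0, 0.2), 60)
  fit <- fit_confocal(sw, ro)
  expect_equal(fit$model$focus_mm, 1.0, tolerance = 1e-3)
  expect_equal(fit$model$rayleigh_mm, 0.2, tolerance = 1e-3)
  expect_lt(fit$residual_norm, 1e-8)
  # symmetric sweep: the fitted focus equals the argmax depth closely
  expect_equal(fit$model$focus_mm, sw$depth_mm[which.max(fit$intensity)],
               tolerance = 0.05)
})

test_that("parameter recovery is invariant to the sweep amplitude scale", {
  p <- load_profile("sd")
  sw <- simulate_mirror_sweep(p, "fixed_reference", NULL,
                              confocal_model(0.8, 0.3, amplitude = 1), 50)
  sw_scaled <- sw
  sw_scaled$intensity <- sw$intensity * 137
  f1 <- fit_confocal(sw)
  f2 <- fit_confocal(sw_scaled)
  expect_equal(f2$model$focus_mm, f1$model$focus_mm, tolerance = 1e-6)
  expect_equal(f2$model$rayleigh_mm, f1$model$rayleigh_mm, tolerance = 1e-6)
  expect_equal(f2$model$amplitude / f1$model$amplitude, 137, tolerance = 1e-6)
})

test_that("omitting the roll-off correction biases the fitted focus shallow", {
  p <- load_profile("sd")
  ro <- rolloff_model(2.5)
  truth <- confocal_model(1.5, 0.4)
  sw <- simulate_mirror_sweep(p, "fixed_reference", ro, truth, 60)
  with_corr <- fit_confocal(sw, ro)
  without <- fit_confocal(sw, NULL)
  expect_equal(with_corr$model$focus_mm, 1.5, tolerance = 1e-3)
  # the uncorrected roll-off pulls the apparent peak toward the surface
  expect_lt(without$model$focus_mm, with_corr$model$focus_mm - 0.01)
})

test_that("calibration validates its inputs", {
  p <- load_profile("sd")
  sw <- simulate_mirror_sweep(p, "fixed_reference", NULL, fix_confocal(), 30)
  expect_error(fit_rolloff(sw), "kind")
  bad <- sw
  bad$intensity <- rep(0, 30)
  expect_error(fit_confocal(bad), "zero")
  expect_error(calibrate_system(p, NULL, sw), "sweep is required")
  # swept-source profile: calibration carries no roll-off model
  ss <- load_profile("ss")
  cal <- calibrate_system(ss, NULL, sw)
  expect_null(cal$rolloff)
})

test_that("noisy confocal recovery stays within 5%", {
  p <- load_profile("sd")
  sw <- simulate_mirror_sweep(p, "fixed_reference", NULL,
                              confocal_model(1.0, 0.2), 50, noise_sd = 0.05,
                              seed = 77)
  fit <- fit_confocal(sw)
  expect_lt(abs(fit$model$focus_mm - 1.0), 0.05)
  expect_lt(abs(fit$model$rayleigh_mm - 0.2) / 0.2, 0.05)
})
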