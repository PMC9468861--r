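test_that("noiseless A-scans are exactly log-linear below the surface", {
  p <- load_profile("ss")
  # r and h held flat: huge Rayleigh length, no roll-off
  flat <- confocal_model(0.9, 1e6)
  a <- simulate_ascan(p, mu = 4.93, i0 = 0.4, surface_pixel = 5, flat,
                      n_pixels = 100)
  below <- 5:100
  ln <- log(a$intensity[below])
  z <- a$depth_mm[below]
  slope <- coef(lm(ln ~ z))[2]
  expect_equal(unname(slope), -2 * 4.93, tolerance = 1e-9)
  expect_equal(a$intensity[1:4], rep(0, 4))            # background above
})

test_that("zero attenuation gives constant intensity below the surface", {
  p <- load_profile("ss")
  flat <- confocal_model(0.9, 1e6)
  a <- simulate_ascan(p, mu = 0, i0 = 0.25, surface_pixel = 11, flat,
                      n_pixels = 60)
  expect_equal(a$intensity[11:60], rep(0.25, 50), tolerance = 1e-6)
})

test_that("simulation is deterministic under a seed", {
  p <- load_profile("ss")
  cm <- fix_confocal()
  a1 <- simulate_ascan(p, 2, 0.3, 11, cm, noise = "speckle", seed = 9)
  a2 <- simulate_ascan(p, 2, 0.3, 11, cm, noise = "speckle", seed = 9)
  expect_identical(a1$intensity, a2$intensity)
  expect_error(simulate_ascan(p, -1, 0.3, 11, cm), "mu")
  expect_error(simulate_ascan(p, 1, 0.3, 0, cm), "surface")
})

test_that("speckle preserves the expectation", {
  p <- load_profile("ss")
  cm <- fix_confocal()
  n_rep <- 10000
  set.seed(1234)
  ex <- simulate_ascan(p, 3, 0.5, 11, cm, n_pixels = 80)$expectation
  acc <- numeric(80)
  for (i in seq_len(n_rep)) {
    acc <- acc + simulate_ascan(p, 3, 0.5, 11, cm, n_pixels = 80,
                                noise = "speckle")$intensity
  }
  m <- acc / n_rep
  tissue <- 11:80
  d <- abs(m[tissue] - ex[tissue]) / ex[tissue]
  # relative deviations behave like 1/sqrt(N) speckle noise: the mean |dev|
  # of an exponential-mean estimator is ~0.8/sqrt(N)
  expect_lt(mean(d), 1.5 / sqrt(n_rep))
  expect_lt(max(d), 5 / sqrt(n_rep))
})

test_that("B-scans carry consistent image, mask, surface and ground truth", {
  p <- load_profile("ss")
  specs <- tissue_class_specs("ss", spread_scale = 0)
  layout <- rep(c("WM0%", "WM>60%"), each = 60)
  flat <- confocal_model(0.9, 1e6)   # h ~ 1: the decay is the tissue's alone
  bs <- simulate_bscan(p, layout, specs, flat, surface_row = 10,
                       n_pixels = 150, seed = 1)
  expect_identical(dim(bs$image), dim(bs$mask))
  expect_equal(bs$surface, rep(10L, 120))
  expect_identical(nrow(bs$ground_truth), 2L)
  # zero spread: regions decay at exactly -2 * class median
  for (k in 1:2) {
    col <- bs$ground_truth$col_start[k]
    ln <- log(bs$image[10:150, col])
    z <- geometric_depth_axis(150, 6, refractive_map(150, 10))[10:150]
    expect_equal(unname(coef(lm(ln ~ z))[2]),
                 -2 * specs$mu_median[specs$label == bs$ground_truth$label[k]],
                 tolerance = 1e-6)
  }
  # every region covered by ground truth
  expect_true(all(!is.na(bs$ground_truth$mu)))
  expect_error(simulate_bscan(p, character(0), specs, fix_confocal()), "empty")
  expect_error(simulate_bscan(p, c("WM0%", "unknown"), specs, fix_confocal()),
               "unknown")
  # reproducible ground truth under the same seed, with spread
  specs2 <- tissue_class_specs("ss")
  b1 <- simulate_bscan(p, layout, specs2, fix_confocal(), seed = 5)
  b2 <- simulate_bscan(p, layout, specs2, fix_confocal(), seed = 5)
  expect_identical(b1$ground_truth, b2$ground_truth)
})

test_that("mirror sweeps sample the intended gain products", {
  p <- load_profile("sd")
  ro <- rolloff_model(2)
  cm <- confocal_model(1.2, 0.3)
  s1 <- simulate_mirror_sweep(p, "reference_arm_only", ro, cm, 40)
  expect_equal(s1$intensity,
               rolloff_value(xi_depth(s1$depth_mm, p$max_imaging_depth_mm), ro))
  s2 <- simulate_mirror_sweep(p, "fixed_reference", ro, cm, 40)
  expect_equal(s2$intensity,
               rolloff_value(xi_depth(s2$depth_mm, p$max_imaging_depth_mm), ro) *
                 confocal_value(s2$depth_mm, cm))
  expect_error(simulate_mirror_sweep(p, "reference_arm_only", ro, cm, 3),
               "at least 4")
})

test_that("cohorts are seeded, validated, and cover the mixed-in labels", {
  p <- load_profile("ss")
  mix <- c("WM0%" = 0.5, "WM>60%" = 0.5)
  c1 <- generate_cohort(3, 2, mix, p, seed = 11)
  c2 <- generate_cohort(3, 2, mix, p, seed = 11)
  expect_identical(c1$bscans[[1]]$image, c2$bscans[[1]]$image)
  labs <- unique(unlist(lapply(c1$bscans, function(b) b$ground_truth$label)))
  expect_setequal(labs, names(mix))
  expect_identical(nrow(c1$patients), 3L)
  expect_error(generate_cohort(1, 2, mix, p, seed = 1), "at least 2")
  expect_error(generate_cohort(3, 2, c("WM0%" = 0.5, "WM>60%" = 0.4), p, 1),
               "sum to 1")
})
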