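make_flat_bscan <- function(surface_row = 10, width = 120, n_pixels = 150,
                            labels = "WM0%", seed = 1, noise = "none") {
  p <- load_profile("ss")
  specs <- tissue_class_specs("ss", spread_scale = 0)
  layout <- rep(labels, each = width %/% length(labels))
  simulate_bscan(p, layout, specs, fix_confocal(), surface_row = surface_row,
                 n_pixels = n_pixels, seed = seed, noise = noise)
}

test_that("a flat noiseless surface is detected exactly", {
  bs <- make_flat_bscan(surface_row = 10)
  expect_equal(detect_surface(bs), rep(10L, 120))
})

test_that("a tilted surface is detected within one pixel", {
  p <- load_profile("ss")
  specs <- tissue_class_specs("ss", spread_scale = 0)
  truth <- 10 + round(0.1 * (0:119))
  bs <- simulate_bscan(p, rep("WM0%", 120), specs, fix_confocal(),
                       surface_row = truth, n_pixels = 150, seed = 2)
  det <- detect_surface(bs)
  expect_true(all(abs(det - truth) <= 1))
})

test_that("an all-background image fails surface detection", {
  img <- matrix(0, 100, 50)
  expect_error(detect_surface(img), "failed")
})

test_that("patch tiling count follows the stride formula", {
  # width 500, patch 50, stride 40 -> 12 patches
  p <- load_profile("ss")
  specs <- tissue_class_specs("ss", spread_scale = 0)
  bs <- simulate_bscan(p, rep("WM0%", 500), specs, fix_confocal(),
                       surface_row = 10, n_pixels = 120, seed = 3)
  patches <- extract_patches(bs, p)
  expect_length(patches, 12)
  expect_true(all(vapply(patches, `[[`, "", "label") == "WM0%"))
  expect_equal(vapply(patches, `[[`, 0L, "column_start"),
               as.integer(seq(1, 441, by = 40)))
  # patch top sits 10 px below the surface
  expect_true(all(vapply(patches, `[[`, 0L, "top_row") == 20L))
})

test_that("no patch straddles a label boundary", {
  bs <- make_flat_bscan(width = 200, labels = c("WM0%", "WM>60%"))
  p <- load_profile("ss")
  patches <- extract_patches(bs, p)
  # starts 1, 41, 81, 121 fit laterally; 81 straddles column 100/101
  expect_length(patches, 3)
  for (pt in patches) {
    cols <- pt$column_start:(pt$column_start + 49)
    expect_length(unique(bs$mask[cbind(pt$top_row, cols)]), 1)
  }
})

test_that("patches that would run past the image bottom are dropped", {
  bs <- make_flat_bscan(surface_row = 100, n_pixels = 150)
  p <- load_profile("ss")
  expect_length(extract_patches(bs, p), 0)   # 100 + 10 + 50 > 150
})

test_that("patch extraction is deterministic", {
  bs <- make_flat_bscan(noise = "speckle", seed = 4)
  p <- load_profile("ss")
  p1 <- extract_patches(bs, p)
  p2 <- extract_patches(bs, p)
  expect_identical(p1, p2)
})

test_that("patch averaging is the lateral mean in linear intensity", {
  col <- exp(-0.1 * (1:50))
  patch <- matrix(col, 50, 50)
  expect_equal(average_patch(patch), col)
  expect_equal(average_patch(matrix(1, 50, 50)), rep(1, 50))
})

test_that("averaging 50 speckled columns shrinks the variance ~50-fold", {
  p <- load_profile("ss")
  specs <- tissue_class_specs("ss", spread_scale = 0)
  # many speckled replicates of the same 50-column patch
  devs2 <- c(); col_vars <- c()
  for (i in 1:40) {
    bs <- simulate_bscan(p, rep("WM0%", 50), specs, fix_confocal(),
                         surface_row = 10, n_pixels = 80, noise = "speckle",
                         seed = 500 + i)
    pt <- extract_patches(bs, p)[[1]]
    avg <- average_patch(pt)
    exp_ascan <- simulate_ascan(p, specs$mu_median[specs$label == "WM0%"],
                                specs$i0_median[specs$label == "WM0%"],
                                10, fix_confocal(), n_pixels = 80)$expectation
    rows <- pt$top_row:(pt$top_row + 49)
    devs2 <- c(devs2, (avg - exp_ascan[rows])^2)
    col_vars <- c(col_vars, apply(pt$pixels, 1, stats::var))
  }
  # Var(mean of 50 cols) should be ~ column variance / 50
  ratio <- mean(col_vars) / mean(devs2)
  expect_gt(ratio, 35)
  expect_lt(ratio, 70)
})
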