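test_that("CIELAB conversion matches the closed-form transform", {
  # white point maps to the a*b* origin, grays stay achromatic
  white <- rgb_to_lab(array(c(255, 255, 255), dim = c(1, 1, 3)))
  expect_equal(white[1, 1, 1], 100, tolerance = 1e-3)
  expect_lt(max(abs(white[1, 1, 2:3])), 0.2)
  gray <- rgb_to_lab(array(c(107, 107, 107), dim = c(1, 1, 3)))
  expect_lt(max(abs(gray[1, 1, 2:3])), 0.2)
  # sRGB green: negative a*, positive b*, values per the published closed forms
  green <- rgb_to_lab(array(c(0, 128, 0), dim = c(1, 1, 3)))
  expect_lt(green[1, 1, 2], 0)
  expect_gt(green[1, 1, 3], 0)
  for (rgb in list(c(0, 128, 0), c(58, 118, 48), c(150, 112, 80), c(12, 200, 240))) {
    got <- rgb_to_lab(array(rgb, dim = c(1, 1, 3)))[1, 1, ]
    expect_equal(unname(got), unname(oracle_rgb_to_lab(rgb)), tolerance = 0.5)
  }
})

test_that("mean-shift separates constant-color populations exactly", {
  # two exactly-constant colors, bandwidth below half their a*b* distance
  img <- array(0, dim = c(20, 20, 3))
  img[1:10, , ] <- rep(c(60, 120, 50), each = 200)
  img[11:20, , ] <- rep(c(150, 110, 80), each = 200)
  lab <- rgb_to_lab(img)
  d_ab <- sqrt(sum((lab[1, 1, 2:3] - lab[20, 20, 2:3])^2))
  ms <- mean_shift_ab(lab, bandwidth = d_ab / 4, seed = 1)
  expect_equal(nrow(ms$mode_centers), 2)
  expect_equal(sort(unique(as.vector(ms$labels))), c(0L, 1L))
  # constant image collapses to a single cluster
  flat <- rgb_to_lab(array(rep(c(90, 90, 90), each = 100), dim = c(10, 10, 3)))
  expect_message(ms1 <- mean_shift_ab(flat, seed = 1), "single cluster")
  expect_equal(nrow(ms1$mode_centers), 1)
  expect_error(mean_shift_ab(lab, bandwidth = -1), "bandwidth")
})

test_that("cluster modes land on the generator's true chromaticities", {
  sc <- generate_scene(test_scene_params(seed = 17))
  ms <- mean_shift_ab(rgb_to_lab(sc$rgb), subsample = 800, seed = 2)
  expect_gte(nrow(ms$mode_centers), 2)
  truth_ab <- rbind(sc$params$background_ab, sc$params$canopy_ab)  # bg is larger
  # noise SD in a*b* is a few units for 8-unit sRGB noise; modes must sit
  # within 2 SD of the true class chromaticities
  lab <- rgb_to_lab(sc$rgb)
  ab_sd <- stats::sd(lab[, , 2][sc$truth$true_mask])
  for (k in 1:2) {
    dists <- sqrt(rowSums(sweep(ms$mode_centers, 2, truth_ab[k, ])^2))
    expect_lt(min(dists), 2 * ab_sd)
  }
})

test_that("the greenness rule selects exactly the canopy cluster", {
  sc <- generate_scene(test_scene_params(seed = 23))
  ms <- mean_shift_ab(rgb_to_lab(sc$rgb), subsample = 800, seed = 3)
  mask <- select_plant_mask(ms)
  s <- mask_scores(mask, sc$truth$true_mask)
  expect_gte(s$precision, 0.95)
  expect_gte(s$recall, 0.95)
  # all-soil image (no green cluster) yields an empty mask with a warning
  soil <- array(rep(c(150, 110, 80), each = 400), dim = c(20, 20, 3))
  ms2 <- mean_shift_ab(rgb_to_lab(soil), seed = 1)
  expect_warning(m2 <- select_plant_mask(ms2), "empty mask")
  expect_false(any(m2))
  # explicit override takes the named labels verbatim
  m3 <- select_plant_mask(ms2, override_labels = 0L)
  expect_true(all(m3 == (ms2$labels == 0L)))
})

test_that("segmentation ignores lightness entirely", {
  sc <- generate_scene(test_scene_params(seed = 29))
  lab <- rgb_to_lab(sc$rgb)
  lab_shifted <- lab
  lab_shifted[, , 1] <- lab_shifted[, , 1] + 25
  ms1 <- mean_shift_ab(lab, subsample = 400, seed = 4)
  ms2 <- mean_shift_ab(lab_shifted, subsample = 400, seed = 4)
  expect_identical(ms1$labels, ms2$labels)
})

test_that("erosion matches its brute-force definition", {
  m <- matrix(TRUE, 5, 5)
  e <- erode_mask(m, 1, 1)
  expect_identical(e, oracle_erode(m, 1))
  expect_true(all(e[2:4, 2:4]))
  expect_equal(sum(e), 9)  # only the central 3x3 survives
  # empty mask and isolated pixel
  expect_false(any(erode_mask(matrix(FALSE, 4, 4), 1, 1)))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_false(any(erode_mask(single, 1, 1)))
  # random masks, radii and iterations against the oracle
  set.seed(99)
  for (r in 1:2) for (k in 1:5) {
    m <- matrix(stats::runif(15 * 12) < 0.7, 15, 12)
    got <- erode_mask(m, r, 1)
    expect_identical(got, oracle_erode(m, r))
    two <- erode_mask(m, r, 2)
    expect_identical(two, oracle_erode(oracle_erode(m, r), r))
    # anti-extensive and decreasing in iterations
    expect_true(all(got <= m))
    expect_true(all(two <= got))
  }
})
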