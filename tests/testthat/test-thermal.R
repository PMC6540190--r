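test_that("greybody correction obeys its physical limits and matches the root-solve oracle", {
  m <- matrix(c(25, 30, 35, 42), 2, 2)
  # emissive limit: eps = 1 is the identity for any reflected temperature
  expect_equal(greybody_correct(m, 1, 50), m)
  # fixed point: object indistinguishable from surroundings
  m20 <- matrix(20, 2, 2)
  expect_equal(greybody_correct(m20, 0.9, 20), m20, tolerance = 1e-9)
  # oracle: scalar root solve of the fourth-power balance
  expect_equal(greybody_correct(matrix(30), 0.98, 20)[1, 1],
               oracle_greybody(30, 0.98, 20), tolerance = 1e-6)
  for (app in c(22, 33.5, 41)) {
    expect_equal(greybody_correct(matrix(app), 0.95, 18)[1, 1],
                 oracle_greybody(app, 0.95, 18), tolerance = 1e-6)
  }
  expect_error(greybody_correct(m, 0, 20), "emissivity")
  expect_error(greybody_correct(m, 1.2, 20), "emissivity")
})

test_that("greybody correction is monotone, invertible, and vanishes as eps -> 1", {
  apparent <- matrix(seq(20, 45, length.out = 26), 1)
  corr <- greybody_correct(apparent, 0.98, 20)
  expect_true(all(diff(corr[1, ]) > 0))
  back <- apparent_from_object(corr, 0.98, 20)
  expect_lt(max(abs(back - apparent)), 1e-9)
  for (eps in c(0.9, 0.99, 0.999)) {
    dev <- max(abs(greybody_correct(apparent, eps, 20) - apparent))
    if (eps == 0.9) dev_prev <- dev else expect_lt(dev, dev_prev)
  }
  expect_lt(max(abs(greybody_correct(apparent, 0.9999, 20) - apparent)), 0.02)
})

test_that("pixel extraction respects the mask, order and shape contracts", {
  m <- matrix(1:12, 3, 4)  # distinct values
  mask <- matrix(FALSE, 3, 4); mask[1, 2] <- TRUE; mask[2, 1] <- TRUE; mask[3, 4] <- TRUE
  # row-major: (row 1, col 2)=4, (row 2, col 1)=2, (row 3, col 4)=12
  expect_equal(extract_canopy_pixels(m + 0, mask), c(4, 2, 12))
  const <- matrix(28, 5, 5)
  expect_true(all(extract_canopy_pixels(const, const > 0) == 28))
  mask_k <- matrix(stats::runif(25) < 0.4, 5, 5)
  if (any(mask_k)) expect_length(extract_canopy_pixels(const, mask_k), sum(mask_k))
  expect_error(extract_canopy_pixels(const, matrix(TRUE, 2, 2)), "shape")
  expect_error(extract_canopy_pixels(const, matrix(FALSE, 5, 5)), "no canopy pixels")
})

test_that("extraction under the truth mask returns the construction values exactly", {
  sc <- generate_scene(test_scene_params(seed = 13, temp_noise_sd = 0))
  px <- extract_canopy_pixels(sc$thermal, sc$truth$true_mask_thermal)
  expect_true(all(px == sc$truth$true_canopy_temp_c[1]))
})

test_that("histograms conserve counts and separate distinct populations", {
  set.seed(7)
  x <- stats::rnorm(100, 30, 1)
  h <- thermal_histogram(x, 0.5)
  expect_equal(sum(h$counts), 100)
  expect_true(all(diff(h$bin_edges_c) > 0))
  expect_equal(diff(range(diff(h$bin_edges_c))), 0, tolerance = 1e-12)
  hc <- thermal_histogram(rep(31.2, 50), 0.5)
  expect_equal(sum(hc$counts > 0), 1)
  expect_equal(max(hc$counts), 50)
  # control vs drought populations: modes about 5 degC apart
  set.seed(8)
  both <- c(stats::rnorm(5000, 28, 0.5), stats::rnorm(5000, 33, 0.5))
  hb <- thermal_histogram(both, 0.5)
  mids <- hb$bin_edges_c[-1] - 0.25
  top2 <- mids[order(hb$counts, decreasing = TRUE)[1:2]]
  expect_equal(abs(diff(top2)), 5, tolerance = 0.5)
  expect_error(thermal_histogram(x, 0), "bin_width")
})

test_that("canopy temperature summaries are the standard statistics", {
  expect_equal(canopy_temperature(c(30, 32))$mean, 31)
  s <- canopy_temperature(rep(27.5, 10))
  expect_equal(unlist(s[c("mean", "median", "p5", "p95")]), rep(27.5, 4),
               ignore_attr = TRUE)
  set.seed(10)
  big <- canopy_temperature(stats::rnorm(1e4, 33, 0.5))
  expect_lt(abs(big$mean - 33), 3 * 0.5 / sqrt(1e4))
  expect_lte(big$p5, big$median)
  expect_lte(big$median, big$p95)
  expect_error(canopy_temperature(numeric(0)), "empty")
})

test_that("delta-CT is the difference of treatment means with a replicate table", {
  expect_equal(delta_ct(c(30, 31), c(30, 31))$delta_ct_c, 0)
  d <- delta_ct(c(35, 35), c(30, 30))
  expect_equal(d$delta_ct_c, 5)
  expect_equal(d$table$delta_c, c(5, 5))
  expect_error(delta_ct(numeric(0), c(30)), "nonempty")
})

test_that("ground sampling distance follows the lens geometry", {
  gsd <- ground_sampling_distance(25, 320, 20)
  expect_equal(round(gsd * 100, 1), 2.8)  # 2.8 cm per pixel
  expect_equal(ground_sampling_distance(90, 2, 1), 1)
  expect_equal(ground_sampling_distance(25, 320, 40), 2 * gsd)
  expect_error(ground_sampling_distance(0, 320, 20), "fov")
  expect_error(ground_sampling_distance(25, 320, -1), "height")
})

test_that("thermal images validate their pixel ranges", {
  expect_warning(thermal_image(matrix(c(25, 300), 1, 2)), "plausible range")
  expect_error(thermal_image(matrix(c(25, NA), 1, 2)), "non-finite")
})
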