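test_that("scene generation is deterministic under a fixed seed", {
  p <- test_scene_params(seed = 11)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$rgb, s2$rgb)
  expect_identical(s1$thermal$temps_c, s2$thermal$temps_c)
  expect_identical(s1$truth$true_mask, s2$truth$true_mask)
})

test_that("noiseless construction puts exact temperatures under the truth mask", {
  p <- test_scene_params(seed = 3, temp_noise_sd = 0,
                         canopy_temp_c = 28, background_temp_c = 40)
  sc <- generate_scene(p)
  px <- extract_canopy_pixels(sc$thermal, sc$truth$true_mask_thermal)
  expect_true(all(px == 28))
  bg <- sc$thermal$temps_c[!sc$truth$true_mask_thermal]
  expect_true(all(bg == 40))
})

test_that("identity homography with equal sensor sizes makes both masks equal", {
  p <- scene_params(image_width_px = 96, image_height_px = 72,
                    thermal_width_px = 96, thermal_height_px = 72,
                    n_plants = 1, canopy_radius_px = 20,
                    true_homography = homography(diag(3)), rng_seed = 5)
  sc <- generate_scene(p)
  expect_identical(sc$truth$true_mask, sc$truth$true_mask_thermal)
})

test_that("degenerate homographies are rejected with an explanation", {
  H <- matrix(c(1, 2, 0, 2, 4, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # singular 2x2 block
  expect_error(test_scene_params(seed = 1, true_homography = H),
               "degenerate|singular")
})

test_that("warping the visible truth mask matches the thermal truth mask", {
  for (seed in c(2, 9, 31)) {
    sc <- generate_scene(test_scene_params(seed = seed))
    wm <- warp_mask(sc$truth$true_mask, sc$truth$true_homography,
                    dim(sc$thermal$temps_c))
    expect_gte(mask_scores(wm, sc$truth$true_mask_thermal)$jaccard, 0.95)
  }
})

test_that("a 4-genotype x 2-treatment x 5-replicate design yields 40 scenes and records", {
  ex <- generate_experiment(experiment_design(rng_seed = 2))
  expect_length(ex$scenes, 40)
  expect_equal(nrow(ex$records), 40)
  expect_equal(sort(unique(ex$records$treatment)), c("control", "drought"))
  expect_true(all(table(ex$records$genotype, ex$records$treatment) == 5))
})

test_that("with all noise SDs zero every replicate equals its cell mean", {
  ns <- default_noise_sds(); ns[] <- 0
  des <- experiment_design(noise_sds = ns, rng_seed = 4)
  ex <- generate_experiment(des, make_scenes = FALSE)
  r <- ex$records
  for (g in des$genotypes) for (tr in des$treatments) {
    sub <- r[r$genotype == g & r$treatment == tr, ]
    expect_equal(sub$CT_true, rep(des$ct_effects[g, tr], 5))
    expect_equal(sub$A, rep(des$physiology_effects$A[g, tr], 5))
    expect_equal(sub$GY, rep(des$physiology_effects$GY[g, tr], 5))
  }
})

test_that("a missing cell mean is reported by name", {
  eff <- default_ct_effects()
  eff["G2", "drought"] <- NA
  expect_error(experiment_design(ct_effects = eff), "G2.*drought")
})

test_that("delta-CT computed from generator truth recovers the programmed offset", {
  # programmed +5 degC drought offset with 0.2 degC replicate noise
  ns <- default_noise_sds(); ns["CT"] <- 0.2
  des <- experiment_design(ct_effects = default_ct_effects(drought_offsets_c = rep(5, 4)),
                           noise_sds = ns, rng_seed = 21)
  ex <- generate_experiment(des, make_scenes = FALSE)
  r <- ex$records
  for (g in des$genotypes) {
    d <- delta_ct(r$CT_true[r$genotype == g & r$treatment == "drought"],
                  r$CT_true[r$genotype == g & r$treatment == "control"])
    expect_lt(abs(d$delta_ct_c - 5), 3 * d$se)
  }
})

test_that("drought gas-exchange means above control are rejected", {
  eff <- default_physiology_effects(c("G1", "G2", "G3", "G4"))
  eff$A[, "drought"] <- 40  # above the control mean of 30
  expect_error(experiment_design(physiology_effects = eff), "gas exchange")
})

test_that("fixture sets round-trip exactly and reproduce byte-identical files", {
  des <- experiment_design(genotypes = c("G1", "G2"),
                           ct_effects = default_ct_effects(c("G1", "G2"),
                                                           drought_offsets_c = c(5, 3)),
                           physiology_effects = default_physiology_effects(c("G1", "G2")),
                           n_replicates = 2, rng_seed = 8)
  tmpl <- scene_params(image_width_px = 48, image_height_px = 36,
                       thermal_width_px = 24, thermal_height_px = 18,
                       n_plants = 1, canopy_radius_px = 7, temp_noise_sd = 0.3)
  ex <- generate_experiment(des, scene_template = tmpl)
  d1 <- withr::local_tempdir()
  mf <- write_fixture_set(d1, ex)
  expect_length(mf$scenes, length(ex$scenes))
  fx <- read_fixture_set(d1)
  expect_equal(length(fx$scenes), length(ex$scenes))
  expect_identical(fx$scenes[[1]]$rgb, ex$scenes[[1]]$rgb)
  expect_identical(fx$scenes[[2]]$true_mask, ex$scenes[[2]]$truth$true_mask)
  expect_lt(max(abs(fx$scenes[[1]]$thermal$temps_c - ex$scenes[[1]]$thermal$temps_c)), 1e-4)
  expect_equal(fx$records$CT_true, ex$records$CT_true)
  # regenerating with the same seed reproduces identical files
  d2 <- withr::local_tempdir()
  write_fixture_set(d2, generate_experiment(des, scene_template = tmpl))
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})
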