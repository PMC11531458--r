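test_that("degenerate phantoms hit the analytic endpoints of the density map", {
  # pure air lung: every lung voxel -1000 HU, zero tissue mass
  ph0 <- generate_phantom(phantom_spec(shape = c(16, 16, 16),
                                       base_tissue_fraction = 0, noise_sd = 0))
  lung_hu <- ph0$volume$data[ph0$truth$mask$data]
  expect_true(all(lung_hu == -1000))
  expect_equal(ph0$truth$true_tissue_mass, 0)
  expect_equal(ph0$truth$true_gas_volume,
               sum(ph0$truth$mask$data) * voxel_volume_ml(ph0$volume))

  # water-equivalent lung: 0 HU, mass = mask volume in g
  ph1 <- generate_phantom(phantom_spec(shape = c(16, 16, 16),
                                       base_tissue_fraction = 1, noise_sd = 0))
  expect_true(all(ph1$volume$data[ph1$truth$mask$data] == 0))
  expect_equal(ph1$truth$true_tissue_mass,
               sum(ph1$truth$mask$data) * voxel_volume_ml(ph1$volume))
  expect_equal(ph1$truth$true_gas_volume, 0)

  # fraction 0.3 maps exactly onto -700 HU, the lower edema-window bound
  ph3 <- generate_phantom(phantom_spec(shape = c(16, 16, 16),
                                       base_tissue_fraction = 0.3,
                                       noise_sd = 0))
  expect_true(all(ph3$volume$data[ph3$truth$mask$data] == -700))
  expect_equal(ph3$truth$true_tissue_mass,
               0.3 * sum(ph3$truth$mask$data) * voxel_volume_ml(ph3$volume))
})

test_that("phantom geometry: gradient, consolidations, contrast, spacing", {
  sp <- phantom_spec(shape = c(24, 24, 24), spacing = c(1.2, 0.8, 1.5),
                     base_tissue_fraction = 0.3, gradient_axis = 3,
                     gradient_amplitude = 0.4, noise_sd = 0, seed = 5)
  ph <- generate_phantom(sp)
  f <- ph$truth$tissue_fraction
  expect_true(all(f >= 0 & f <= 1))
  # gradient raises fraction monotonically along axis 3
  prof <- apply(f, 3, mean)
  expect_true(all(diff(prof) >= 0))
  expect_equal(ph$truth$true_tissue_mass,
               sum(f[ph$truth$mask$data]) * prod(sp$spacing) / 1000)

  # consolidation overrides the fraction inside its sphere
  spc <- phantom_spec(shape = c(24, 24, 24), base_tissue_fraction = 0.2,
                      consolidations = list(list(center = c(8, 12, 12),
                                                 radius_mm = 3,
                                                 tissue_fraction = 0.9)),
                      noise_sd = 0)
  phc <- generate_phantom(spc)
  expect_true(any(phc$truth$tissue_fraction == 0.9))
  expect_gt(phc$truth$true_tissue_mass, ph0_mass <- generate_phantom(
    phantom_spec(shape = c(24, 24, 24), base_tissue_fraction = 0.2,
                 noise_sd = 0))$truth$true_tissue_mass)

  # contrast blob voxels carry their HU exactly and are flagged
  spb <- phantom_spec(shape = c(24, 24, 24), base_tissue_fraction = 0.3,
                      contrast_blobs = list(list(center = c(8, 12, 12),
                                                 radius_mm = 2, hu = 400)),
                      noise_sd = 0)
  phb <- generate_phantom(spb)
  expect_gt(sum(phb$truth$contrast_mask), 0)
  expect_true(all(phb$volume$data[phb$truth$contrast_mask] == 400))

  # geometry errors
  expect_error(generate_phantom(phantom_spec(
    shape = c(16, 16, 16),
    contrast_blobs = list(list(center = c(1, 8, 8), radius_mm = 5,
                               hu = 300)))), "outside the grid")
  expect_error(phantom_spec(contrast_blobs = list(
    list(center = c(8, 8, 8), radius_mm = 2, hu = 150))), "exceed 200")
  expect_error(phantom_spec(consolidations = list(
    list(center = c(8, 8, 8), radius_mm = 2, tissue_fraction = 1.2))),
    "\\[0,1\\]")
})

test_that("phantom generation is seed-deterministic and seed-local", {
  sp <- phantom_spec(shape = c(16, 16, 16), noise_sd = 25, seed = 42)
  a <- generate_phantom(sp)
  set.seed(999)  # global RNG state must not leak in
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  # and the call must not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_phantom(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("with zero-mean noise the calculated weight is unbiased and its error shrinks with mask size", {
  errs_small <- errs_big <- numeric(30)
  for (i in 1:30) {
    ps <- generate_phantom(phantom_spec(shape = c(12, 12, 12),
                                        base_tissue_fraction = 0.3,
                                        noise_sd = 40, seed = i))
    pb <- generate_phantom(phantom_spec(shape = c(36, 36, 36),
                                        base_tissue_fraction = 0.3,
                                        noise_sd = 40, seed = i))
    qs <- quantify_lung(ps$volume, ps$truth$mask)
    qb <- quantify_lung(pb$volume, pb$truth$mask)
    # per-voxel mean error in g/ml units, comparable across mask sizes
    errs_small[i] <- (qs$calculated_lung_weight - ps$truth$true_tissue_mass) /
      (sum(ps$truth$mask$data) * voxel_volume_ml(ps$volume))
    errs_big[i] <- (qb$calculated_lung_weight - pb$truth$true_tissue_mass) /
      (sum(pb$truth$mask$data) * voxel_volume_ml(pb$volume))
  }
  # unbiased: mean error within 3 MC standard errors of zero
  expect_lt(abs(mean(errs_small)), 3 * sd(errs_small) / sqrt(30))
  expect_lt(abs(mean(errs_big)), 3 * sd(errs_big) / sqrt(30))
  # 1/sqrt(N) scaling: 27x more voxels -> ~5.2x smaller RMS error
  ratio <- sqrt(mean(errs_small^2)) / sqrt(mean(errs_big^2))
  expect_gt(ratio, 2.5)
})

test_that("synthetic cohorts honor their disagreement structure and invariants", {
  # degenerate noise: every difference equals the bias exactly
  co0 <- generate_cohort(cohort_spec(n = 20, disagreement_bias_ml = -104,
                                     disagreement_sd_ml = 0, seed = 3))
  expect_equal(co0$pe_tptd - co0$pe_ct, rep(-104, 20))

  # determinism
  sp <- cohort_spec(n = 50, seed = 17)
  expect_identical(generate_cohort(sp), generate_cohort(sp))

  # record invariants
  co <- generate_cohort(cohort_spec(n = 200, seed = 8))
  expect_true(all(co$height_m > 1.2 & co$height_m < 2.5))
  expect_true(all(co$weight_kg > 30))
  expect_true(all(co$evlwi_ml_per_kg >= 0))
  expect_true(all(co$sex %in% c("female", "male")))
  # EVLWI back-derivation: unclamped rows reproduce pe_tptd through the
  # thermodilution formula
  ok <- !co$evlwi_clamped
  t <- edema_from_tptd(co[ok, ])
  expect_equal(t$pe_tptd, co$pe_tptd[ok], tolerance = 1e-9)
})
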