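test_that("phantoms are seed-deterministic and leave the caller's RNG alone", {
  spec <- small_phantom_spec(pore_fraction = 0.5, noise_sd_hu = 25, seed = 3)
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  ph1 <- generate_phantom(spec)
  after <- rnorm(1)
  ph2 <- generate_phantom(spec)
  expect_identical(ph1$observed_volume$values, ph2$observed_volume$values)
  expect_identical(ph1$true_volume$values, ph2$true_volume$values)
  expect_equal(before, after)  # RNG state untouched by the generator

  ph3 <- generate_phantom(small_phantom_spec(pore_fraction = 0.5,
                                             noise_sd_hu = 25, seed = 4))
  expect_false(identical(ph1$observed_volume$values,
                         ph3$observed_volume$values))
})

test_that("a clean phantom realises its spec exactly", {
  spec <- small_phantom_spec(implant_true_hu = 1500)
  ph <- generate_phantom(spec)
  expect_identical(ph$observed_volume$values, ph$true_volume$values)
  s_oi <- region_statistics(ph$true_volume, ph$masks$OI)
  expect_equal(s_oi$mean_hu, 1500)
  expect_equal(s_oi$sd_hu, 0)
  s_cv <- region_statistics(ph$true_volume, ph$masks$CV)
  expect_equal(s_cv$mean_hu, 5.93)
  # the dense bone focus is the dedicated-volume maximum
  expect_equal(region_statistics(ph$true_volume, ph$masks$DV)$max_hu, 2024.67)
  # implant and corpus vitreum are disjoint
  expect_false(any(ph$masks$OI$selector & ph$masks$CV$selector))
})

test_that("noiseless distorted anchors obey the affine construction exactly", {
  spec <- small_phantom_spec(distortion_gain = 0.8, distortion_offset = 310)
  ph <- generate_phantom(spec)
  cv_obs <- region_statistics(ph$observed_volume, ph$masks$CV)$mean_hu
  expect_equal(cv_obs, 0.8 * 5.93 + 310)
  dv_obs <- region_statistics(ph$observed_volume, ph$masks$DV)$max_hu
  expect_equal(dv_obs, 0.8 * 2024.67 + 310)
})

test_that("porosity carves the requested fraction of implant voxels", {
  spec <- small_phantom_spec(pore_fraction = 0.8, seed = 12)
  ph <- generate_phantom(spec)
  vals <- ph$true_volume$values[ph$masks$OI$selector]
  expect_equal(sum(vals == spec$background_hu) / length(vals), 0.8,
               tolerance = 1e-3)
  # apparent (mean) density is depressed accordingly
  expect_equal(mean(vals),
               0.2 * spec$implant_true_hu + 0.8 * spec$background_hu,
               tolerance = 0.01)
})

test_that("oversized spheres are rejected", {
  expect_error(generate_phantom(phantom_spec(grid_shape = 32,
                                             implant_diameter_mm = 20)),
               "exceeds the grid")
})

test_that("synthetic cohorts are deterministic and invert the correction exactly", {
  spec <- cohort_spec(seed = 77)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_identical(coh1, coh2)
  expect_equal(nrow(coh1), 28L)
  expect_equal(as.integer(table(coh1$group)[c("HA", "AO")]), c(17L, 11L))

  # back-computation consistency: the pipeline's per-record correction
  # recovers the generator's true corrected densities exactly
  rec <- orbcal:::corrected_density(coh1)
  expect_equal(rec, coh1$true_corrected_hu, tolerance = 1e-12)
})

test_that("degenerate cohort specs collapse to their deterministic truth", {
  spec <- cohort_spec(n_per_group = c(g = 5L), baseline_hu = c(g = 500),
                      slope_hu_per_year = c(g = 0), residual_sd_hu = 0,
                      seed = 2)
  coh <- generate_cohort(spec)
  rec <- orbcal:::corrected_density(coh)
  expect_equal(rec, rep(500, 5), tolerance = 1e-12)

  lin <- cohort_spec(n_per_group = c(g = 3L), baseline_hu = c(g = 600),
                     slope_hu_per_year = c(g = -12), residual_sd_hu = 0,
                     seed = 6)
  fits <- density_trend(generate_cohort(lin), use = "recomputed")
  expect_equal(fits$all$r_squared, 1)
  expect_equal(fits$all$slope_hu_per_year, -12, tolerance = 1e-9)
})

test_that("cohort lifespans stay inside the specified range", {
  coh <- generate_cohort(cohort_spec(seed = 13))
  expect_true(all(coh$lifespan_days >= 79 & coh$lifespan_days <= 2636))
  expect_true(all(coh$dv_max_hu - coh$cv_mean_hu >= 500))
})
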