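test_that("three points on a great circle determine the sphere", {
  s <- sphere_from_three_points(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  expect_equal(s$center_mm, c(0, 0, 0))
  expect_equal(s$radius_mm, 1)
  expect_equal(s$diameter_mm, 2)

  # any permutation of the same points gives the identical sphere
  s2 <- sphere_from_three_points(c(0, 1, 0), c(1, 0, 0), c(-1, 0, 0))
  expect_equal(s2$center_mm, s$center_mm)
  expect_equal(s2$radius_mm, s$radius_mm)

  expect_error(sphere_from_three_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "degenerate")
  expect_error(sphere_from_three_points(c(1, 2, 3), c(1, 2, 3), c(0, 1, 0)),
               "degenerate")
})

test_that("three-point fitting is equivariant under rigid motions", {
  set.seed(21)
  r_true <- 9
  angles <- c(0.3, 2.1, 4.4)
  base <- lapply(angles, function(a) r_true * c(cos(a), sin(a), 0))
  for (rep in 1:20) {
    mo <- random_rigid_motion()
    pts <- lapply(base, function(p) apply_motion(mo, p))
    s <- sphere_from_three_points(pts[[1]], pts[[2]], pts[[3]])
    expect_equal(s$radius_mm, r_true, tolerance = 1e-9)
    expect_equal(s$diameter_mm, 18, tolerance = 1e-9)
    expect_equal(s$center_mm, apply_motion(mo, c(0, 0, 0)), tolerance = 1e-8)
  }
})

test_that("least-squares sphere fitting interpolates exact points", {
  ctr <- c(3, -2, 7); r <- 5
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  pts <- sweep(r * dirs, 2, ctr, `+`)
  f <- fit_sphere_least_squares(pts)
  expect_equal(f$center_mm, ctr, tolerance = 1e-12)
  expect_equal(f$radius_mm, r, tolerance = 1e-12)

  expect_error(fit_sphere_least_squares(matrix(1, 10, 3)), "degenerate")
  expect_error(fit_sphere_least_squares(pts[1:3, ]), "at least 4")
})

test_that("least-squares fit agrees with the three-point sphere on a great circle plus poles", {
  a <- c(2, 0, 0); b <- c(-2, 0, 0); c_ <- c(0, 2, 0)
  s3 <- sphere_from_three_points(a, b, c_)
  pts <- rbind(a, b, c_, c(0, -2, 0), c(0, 0, 2), c(0, 0, -2))
  f <- fit_sphere_least_squares(pts)
  expect_equal(f$center_mm, s3$center_mm, tolerance = 1e-12)
  expect_equal(f$radius_mm, s3$radius_mm, tolerance = 1e-12)
})

test_that("least-squares fitting recovers a noisy sphere radius", {
  set.seed(31)
  n <- 500; r <- 10; ctr <- c(1, 2, 3)
  u <- matrix(rnorm(3 * n), n)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(r * u, 2, ctr, `+`) + matrix(rnorm(3 * n, 0, 0.1), n)
  f <- fit_sphere_least_squares(pts)
  expect_lt(abs(f$radius_mm - r), 0.05)
  expect_lt(sqrt(sum((f$center_mm - ctr)^2)), 0.05)
})

test_that("factory-sphere classification conserves voxels and matches enumeration", {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec)
  vol <- ph$true_volume
  factory <- sphere(spec$implant_center_mm, spec$implant_diameter_mm / 4)
  cls <- classify_against_factory_sphere(vol, ph$masks$OI, factory)

  n_in <- sum(cls$inside$selector)
  n_out <- sum(cls$beyond$selector)
  expect_equal(n_in + n_out, sum(ph$masks$OI$selector))
  expect_false(any(cls$inside$selector & cls$beyond$selector))
  expect_equal(cls$inside$selector | cls$beyond$selector,
               ph$masks$OI$selector)

  # oracle: exhaustive voxel-center enumeration
  ctr <- voxel_centers(vol, ph$masks$OI)
  d <- sqrt(colSums((t(ctr) - factory$center_mm)^2))
  expect_equal(n_out, sum(d > factory$radius_mm))
  expect_equal(n_in, sum(d <= factory$radius_mm))

  # a mask entirely inside the factory sphere has an empty beyond set
  big <- sphere(spec$implant_center_mm, spec$implant_diameter_mm)
  expect_equal(sum(classify_against_factory_sphere(vol, ph$masks$OI,
                                                   big)$beyond$selector), 0L)
})

test_that("beyond-diameter voxels of a spiked phantom are confined to the spikes", {
  spec <- small_phantom_spec(spike_count = 4, spike_length_mm = 1.5, seed = 9)
  ph <- generate_phantom(spec)
  factory <- sphere(spec$implant_center_mm, spec$implant_diameter_mm / 2)
  cls <- classify_against_factory_sphere(ph$true_volume, ph$masks$OI, factory)
  beyond_idx <- which(cls$beyond$selector, arr.ind = TRUE)
  expect_gt(nrow(beyond_idx), 0L)
  spike_keys <- apply(ph$spike_voxels, 1, paste, collapse = ",")
  beyond_keys <- apply(beyond_idx, 1, paste, collapse = ",")
  expect_true(all(beyond_keys %in% spike_keys))
})

test_that("surface-shell diameter estimation is within a voxel on noiseless phantoms", {
  for (d in c(16, 18, 20)) {
    spec <- phantom_spec(grid_shape = c(168, 96, 96), spacing_mm = 0.25,
                         implant_diameter_mm = d, pore_fraction = 0,
                         noise_sd_hu = 0)
    ph <- generate_phantom(spec)
    est <- estimate_implant_diameter(ph$true_volume, ph$masks$OI)
    expect_lt(abs(est$diameter_mm - d), 0.25)
    expect_lt(sqrt(sum((est$center_mm - spec$implant_center_mm)^2)), 0.25)
  }
})
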