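test_that("mask volume converts voxel counts to mL", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:11, 2:11, 2:11] <- TRUE  # 1000 voxels
  expect_equal(mask_volume(tumor_mask(m, c(1, 1, 1))), 1.0)

  m1 <- array(FALSE, c(7, 7, 7)); m1[4, 4, 4] <- TRUE
  expect_equal(mask_volume(tumor_mask(m1, c(4, 4, 4))), 0.064)

  ph <- sphere_phantom(10)
  expect_equal(mask_volume(ph$truth), 4.18879, tolerance = 0.02)

  expect_error(tumor_mask(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("SUV statistics are the max and mean over the mask", {
  v <- array(1, c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5))
  m[2:4, 3, 3] <- TRUE
  v[2:4, 3, 3] <- c(2, 4, 6)
  s <- suv_stats(pet_volume(v), tumor_mask(m))
  expect_equal(s$suv_max, 6)
  expect_equal(s$suv_mean, 4)

  v[2:4, 3, 3] <- 5
  s2 <- suv_stats(pet_volume(v), tumor_mask(m))
  expect_equal(s2$suv_max, 5)
  expect_equal(s2$suv_mean, 5)
})

test_that("TLG is exactly MTV times SUVmean", {
  expect_identical(tlg(10, 5), 50)
  expect_identical(tlg(0.064, 2), 0.128)
  ph <- sphere_phantom(8, background = 1, fwhm = 2)
  f <- compute_features(ph$volume, ph$truth)
  expect_identical(f$tlg, f$mtv_ml * f$suv_mean)
  expect_lte(f$suv_max, 10)  # blur cannot exceed the plateau
  expect_gte(f$suv_max, f$suv_mean)
})

test_that("mesh surface area of a digitized sphere is accurate to 5%", {
  ph <- sphere_phantom(10)
  s <- surface_area(ph$truth)
  expect_equal(s, 4 * pi * 100, tolerance = 0.05)
})

test_that("voxel-face counting overestimates a sphere by about 50%", {
  ph <- sphere_phantom(10)
  s <- surface_area(ph$truth, method = "voxel_faces")
  expect_equal(s / (4 * pi * 100), 1.5, tolerance = 0.05)
})

test_that("single-voxel mask has the surface of its voxel cube", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  expect_equal(surface_area(tumor_mask(m), method = "voxel_faces"), 6)
  m2 <- tumor_mask(m, spacing = c(1, 2, 3))
  expect_equal(surface_area(m2, method = "voxel_faces"),
               2 * (2 + 3 + 6))
})

test_that("masks touching the grid boundary are rejected", {
  m <- array(FALSE, c(8, 8, 8)); m[1, 4, 4] <- TRUE; m[5, 5, 5] <- TRUE
  expect_error(surface_area(tumor_mask(m)), "boundary")
})

test_that("digitized-sphere asphericity converges within the stated bands", {
  asp <- vapply(c(10, 15, 20), function(r) {
    ph <- sphere_phantom(r)
    compute_features(ph$volume, ph$truth)$asp_percent
  }, 0)
  expect_lt(abs(asp[1]), 5)   # r = 10 voxels
  expect_lt(abs(asp[3]), 2)   # r = 20 voxels
  expect_true(all(diff(abs(asp)) <= 0))  # monotone improvement
  expect_true(all(asp >= -0.5))          # isoperimetric floor
})

test_that("asphericity is invariant under isotropic spacing scaling", {
  ph <- sphere_phantom(10)
  for (k in c(0.5, 3)) {
    m_scaled <- tumor_mask(ph$truth$data, spacing = ph$truth$spacing * k)
    a0 <- asphericity(surface_area(ph$truth), mask_volume(ph$truth) * 1000)
    ak <- asphericity(surface_area(m_scaled), mask_volume(m_scaled) * 1000)
    expect_equal(ak, a0, tolerance = 1e-9)
    expect_equal(surface_area(m_scaled), surface_area(ph$truth) * k^2,
                 tolerance = 1e-9)
    expect_equal(mask_volume(m_scaled), mask_volume(ph$truth) * k^3,
                 tolerance = 1e-12)
  }
})

test_that("voxel-pipeline asphericity tracks the analytic oracle", {
  # harmonic perturbation series: zero amplitude reproduces the sphere;
  # the voxel ASP increases with amplitude alongside the reference value
  amps <- c(0, 1.5, 3)
  res <- t(vapply(amps, function(a) {
    spec <- if (a == 0) shape_spec("sphere", radius = 10) else
      shape_spec("perturbed_sphere", radius = 10, degree = 2,
                 amplitudes = c(0, 0, a, 0, 0))
    ph <- make_phantom(spec, grid_spec(rep(36, 3)), acquisition_spec(10, 0))
    g <- reference_geometry(spec)
    c(vox = compute_features(ph$volume, ph$truth)$asp_percent,
      ref = asphericity(g$surface, g$volume))
  }, c(vox = 0, ref = 0)))
  expect_true(all(diff(res[, "vox"]) > 0))
  expect_true(all(diff(res[, "ref"]) > 0))
  expect_lt(max(abs(res[, "vox"] - res[, "ref"])), 1)  # pp, discretization
})

test_that("voxel-pipeline asphericity converges under grid refinement", {
  spec <- shape_spec("ellipsoid", semi_axes = c(20, 10, 10))
  g <- reference_geometry(spec)
  asp_ref <- asphericity(g$surface, g$volume)
  err <- vapply(c(1, 0.5), function(h) {
    ph <- make_phantom(spec, grid_spec(ceiling(c(52, 32, 32) / h),
                                       rep(h, 3)),
                       acquisition_spec(10, 0))
    abs(compute_features(ph$volume, ph$truth)$asp_percent - asp_ref)
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 1)
})
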