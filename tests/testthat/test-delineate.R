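test_that("two-valued images recover the ground truth exactly", {
  ph <- sphere_phantom(10, background = 0, tumor = 10)
  m <- delineate(ph$volume)
  expect_identical(m$data, ph$truth$data)
  expect_lte(attr(m, "iterations"), 2)
  expect_true(attr(m, "converged"))
})

test_that("converged threshold equals B + f(max - B) on plateau phantoms", {
  ph <- sphere_phantom(10, background = 2, tumor = 10)
  m <- delineate(ph$volume)
  expect_equal(attr(m, "threshold"), 2 + 0.41 * (10 - 2))
  expect_equal(attr(m, "background"), 2)
  expect_identical(m$data, ph$truth$data)

  p2 <- delineation_params(threshold_fraction = 0.6)
  m2 <- delineate(ph$volume, params = p2)
  expect_equal(attr(m2, "threshold"), 2 + 0.6 * (10 - 2))
})

test_that("delineation stays in the seeded lesion of a two-lesion volume", {
  v <- array(1, c(40, 20, 20))
  d <- dim(v)
  for (ctr in list(c(11, 10, 10), c(30, 10, 10))) {
    idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
    inside <- rowSums(sweep(idx, 2, ctr)^2) < 36
    v[array(inside, d)] <- 10
  }
  vol <- pet_volume(v)
  m <- delineate(vol, seed_point = c(11, 10, 10))
  expect_true(m$data[11, 10, 10])
  expect_false(any(m$data[25:40, , ]))
  m2 <- delineate(vol, seed_point = c(30, 10, 10))
  expect_false(any(m2$data[1:20, , ]))
})

test_that("background estimation averages the shell and flags empty shells", {
  ph <- sphere_phantom(8, background = 2, tumor = 10)
  expect_equal(estimate_background(ph$volume, ph$truth, 2, 4), 2)

  # noisy background: matches the direct mean over the brute-force shell
  phn <- sphere_phantom(4, background = 2, tumor = 10, noise = 0.3, seed = 5)
  b <- estimate_background(phn$volume, phn$truth, 2, 4)
  d <- dim(phn$volume$data)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  reg <- which(phn$truth$data)
  reg_idx <- idx[reg, , drop = FALSE]
  # distance of every voxel to the nearest region voxel center (small grid)
  mind <- apply(idx, 1, function(p) {
    sqrt(min(colSums((t(reg_idx) - p)^2)))
  })
  shell <- mind >= 2 & mind <= 4 & !phn$truth$data[cbind(idx)]
  expect_equal(b, mean(phn$volume$data[idx[shell, , drop = FALSE]]),
               tolerance = 1e-12)
  expect_equal(b, 2, tolerance = 4 * 0.3 / sqrt(sum(shell)))

  expect_error(estimate_background(ph$volume, ph$truth, 30, 31),
               "shell")
})

test_that("mask volume never grows when the threshold fraction increases", {
  ph <- sphere_phantom(10, background = 1.5, tumor = 10, fwhm = 2,
                       noise = 0.2, seed = 9)
  vols <- vapply(c(0.3, 0.41, 0.5, 0.6, 0.7), function(f) {
    sum(delineate(ph$volume,
                  params = delineation_params(threshold_fraction = f))$data)
  }, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("delineation is equivariant under intensity scaling", {
  ph <- sphere_phantom(9, background = 1.2, tumor = 8, fwhm = 2,
                       noise = 0.15, seed = 4)
  m1 <- delineate(ph$volume)
  for (k in c(0.25, 7)) {
    vk <- pet_volume(ph$volume$data * k, spacing = ph$volume$spacing)
    expect_identical(delineate(vk)$data, m1$data)
  }
})

test_that("blurred noiseless spheres recover MTV within 15%", {
  for (r in c(5, 8, 10)) {
    ph <- sphere_phantom(r, background = 1, tumor = 10, fwhm = 2)
    m <- delineate(ph$volume)
    expect_equal(mask_volume(m) * 1000, 4 / 3 * pi * r^3, tolerance = 0.15,
                 label = sprintf("MTV at r=%d", r))
  }
})

test_that("override masks are validated, trimmed and tagged", {
  ph <- sphere_phantom(8, background = 1, tumor = 10)
  m <- apply_override(ph$volume, ph$truth)
  expect_identical(m$data, ph$truth$data)
  expect_identical(m$provenance, "override")

  # two components: largest kept with a warning
  two <- ph$truth$data
  two[3, 3, 3] <- TRUE; two[3, 4, 3] <- TRUE; two[3, 3, 4] <- TRUE
  expect_warning(mt <- apply_override(ph$volume, two), "components")
  expect_identical(sum(mt$data), sum(ph$truth$data))

  # wrong grid rejected with both shapes reported
  wrong <- tumor_mask(array(TRUE, c(4, 4, 4)))
  expect_error(apply_override(ph$volume, wrong), "grid")
})

test_that("featureless volumes raise an informative error", {
  # near-constant volume: the initial region floods the whole grid and no
  # background shell exists
  v <- array(1, c(12, 12, 12))
  v[6, 6, 6] <- 1.0001
  expect_error(
    delineate(pet_volume(v), seed_point = c(2, 2, 2),
              params = delineation_params(init_fraction = 0.9)),
    "background|region"
  )
})
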