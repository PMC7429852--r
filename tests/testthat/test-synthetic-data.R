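test_that("phantom realizes the target bone volume fraction and is seeded", {
  sp <- phantom_spec(shape = c(64, 64, 64), target_bvtv = 0.3, noise_sd = 3,
                     seed = 7)
  ph <- generate_trabecular_phantom(sp)
  expect_gte(ph$bvtv, 0.28)
  expect_lte(ph$bvtv, 0.32)
  expect_equal(mean(ph$bone_mask), ph$bvtv)
  ph2 <- generate_trabecular_phantom(sp)
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_identical(ph$bone_mask, ph2$bone_mask)
  expect_error(phantom_spec(target_bvtv = 0), "target_bvtv")
  expect_error(phantom_spec(correlation_length = 1), "correlation_length")
})

test_that("phantom BV/TV converges to target with volume size", {
  err <- vapply(c(64, 160), function(n) {
    ph <- generate_trabecular_phantom(phantom_spec(shape = rep(n, 3), seed = 2))
    abs(ph$bvtv - 0.3)
  }, numeric(1))
  expect_lte(err[2], err[1] + 1e-6)
})

test_that("integer uniform translation is an exact array shift", {
  ph <- small_phantom()
  t <- c(2, -1, 3)
  dv <- apply_deformation(ph$volume, deformation_uniform(t), fill = 0)
  d <- dim(ph$volume$data)
  expect_equal(dv$data[(1 + t[1]):d[1], 1:(d[2] + t[2]), (1 + t[3]):d[3]],
               ph$volume$data[1:(d[1] - t[1]), (1 - t[2]):d[2], 1:(d[3] - t[3])])
  # identity
  dv0 <- apply_deformation(ph$volume, deformation_uniform(c(0, 0, 0)))
  expect_identical(dv0$data, ph$volume$data)
})

test_that("affine warp matches direct resampling within interpolation error", {
  v <- smooth_volume(c(64, 64, 64))
  A <- diag(c(0.98, 1, 1))
  ctr <- (dim(v$data) - 1) / 2
  defm <- deformation_affine(A, center = ctr)
  dv <- apply_deformation(v, defm, fill = 128)
  # check at interior voxels: g(x) should equal f(A^-1 (x - c) + c)
  set.seed(3)
  pts <- cbind(sample(16:47, 200, TRUE), sample(16:47, 200, TRUE),
               sample(16:47, 200, TRUE))
  X <- trabstrain:::inverse_map(defm, pts)
  fx <- trabstrain:::cpp_tricubic_sample(v$data, dim(v$data), X)
  gx <- dv$data[pts + 1]
  dyn <- diff(range(v$data))
  expect_lt(max(abs(fx - gx)), 0.01 * dyn)
  expect_error(deformation_affine(diag(c(-1, 1, 1))), "det")
})

test_that("localized concentration has the stated analytic volumetric strain", {
  defm <- deformation_localized(center = c(20, 20, 20), radius = 6, peak = 0.05)
  # at the center det(F) - 1 equals the peak
  expect_equal(true_volumetric_strain(defm, matrix(c(20, 20, 20), 1)), 0.05,
               tolerance = 1e-12)
  # numerical divergence check at an off-center point
  x0 <- c(23, 21, 19)
  h <- 1e-4
  J <- matrix(0, 3, 3)
  for (a in 1:3) {
    e <- rep(0, 3); e[a] <- h
    up <- true_displacement(defm, matrix(x0 + e, 1))
    um <- true_displacement(defm, matrix(x0 - e, 1))
    J[, a] <- (up - um) / (2 * h)
  }
  expect_equal(det(diag(3) + J) - 1,
               true_volumetric_strain(defm, matrix(x0, 1)),
               tolerance = 1e-6)
})

test_that("crack insertion marks exactly the modified voxels", {
  ph <- small_phantom()
  site <- drop(suggest_crack_sites(ph$bone_mask, n = 1, margin = 12,
                                   min_separation = 5))
  cs <- crack_spec(center = site, normal = c(1, 0, 0), thickness = 2,
                   extent = 10, gray = 90)
  out <- insert_cracks(ph$volume, list(cs), ph$bone_mask)
  changed <- out$volume$data != ph$volume$data
  expect_identical(out$crack_mask, changed)
  expect_true(all(out$volume$data[out$crack_mask] == 90))
  expect_true(all(ph$bone_mask[out$crack_mask]))  # slits only in bone
  # empty spec list leaves everything unchanged
  out0 <- insert_cracks(ph$volume, list(), ph$bone_mask)
  expect_identical(out0$volume$data, ph$volume$data)
  expect_false(any(out0$crack_mask))
  # seed in background errors
  bgv <- which(!ph$bone_mask, arr.ind = TRUE)[1, ] - 1
  expect_error(insert_cracks(ph$volume,
                             list(crack_spec(bgv, c(1, 0, 0))), ph$bone_mask),
               "not in bone")
})

test_that("load curve generator is bilinear without toe and noise", {
  c0 <- generate_load_curve(modulus = 100, yield_strain = 0.02, toe_strain = 0,
                            hardening_ratio = 0.1, noise_sd = 0)
  pre <- c0[c0$strain <= 0.02, ]
  expect_equal(pre$stress, 100 * pre$strain, tolerance = 1e-12)
  i <- which.min(abs(c0$strain - 0.01))
  expect_equal(c0$stress[i], 100 * c0$strain[i], tolerance = 1e-12)
  post <- c0[c0$strain > 0.02 & c0$strain <= 0.03, ]
  expect_equal(post$stress, 2 + 10 * (post$strain - 0.02), tolerance = 1e-9)
  # seeded noise reproducible
  c1 <- generate_load_curve(100, 0.02, noise_sd = 0.05, seed = 9)
  c2 <- generate_load_curve(100, 0.02, noise_sd = 0.05, seed = 9)
  expect_identical(c1$stress, c2$stress)
  expect_error(generate_load_curve(100, 0.002, toe_strain = 0.01), "exceed")
})

test_that("density phantoms have the prescribed mean grays", {
  g <- function(d) 50 + d / 10
  ps <- generate_density_phantoms(c(250, 750, 1250), g, noise_sd = 2, seed = 4)
  for (i in 1:3) {
    inside <- attr(ps[[i]], "inside")
    m <- mean(ps[[i]]$data[inside])
    se <- 2 / sqrt(sum(inside))
    expect_lt(abs(m - g(c(250, 750, 1250)[i])), 3 * se + 1e-9)
  }
  p0 <- generate_density_phantoms(c(250, 1250), g, noise_sd = 0)
  expect_equal(mean(p0[[1]]$data[attr(p0[[1]], "inside")]), 75)
  expect_error(generate_density_phantoms(c(500), g), "2 distinct")
})
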