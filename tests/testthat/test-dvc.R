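test_that("node grid geometry: margins, overlap, and failure modes", {
  roi <- roi_spec(c(0, 0, 0), c(100, 100, 100))
  g <- make_node_grid(roi, ns = 10, cw = 10, search_range = 5)
  expect_equal(g$overlap, 0.5)   # CW +/-10 with NS 10: 50% window overlap
  expect_equal(min(g$nodes_z), 15)
  expect_equal(diff(g$nodes_z)[1], 10)
  expect_equal(make_node_grid(roi, 10, 5, 0)$overlap, 0)
  expect_error(make_node_grid(roi_spec(c(0, 0, 0), c(30, 30, 30)), 10, 10, 5),
               "too small")
})

test_that("integer window correlation matches the exhaustive oracle", {
  v <- smooth_volume(c(40, 40, 40), seed = 12)
  s <- c(2, -1, 3)
  dv <- apply_deformation(v, deformation_uniform(s), fill = mean(v$data))
  node <- c(20, 19, 21)
  res <- correlate_window(v, dv, node, cw = 5, search_range = 5)
  expect_true(res$ok)
  expect_equal(res$u, as.integer(s))
  expect_gt(res$cc, 0.999)
  orc <- oracle_zncc_search(v$data, dv$data, node, cw = 5, sr = 5)
  expect_equal(res$u, as.integer(orc$u))
  expect_equal(res$cc, orc$cc, tolerance = 1e-12)
  # identical volumes: zero displacement, CC exactly 1
  r0 <- correlate_window(v, v, node, 5, 3)
  expect_equal(r0$u, c(0L, 0L, 0L))
  expect_equal(r0$cc, 1)
  # constant window fails
  cv <- image_volume(array(1, c(40, 40, 40)), 3.6)
  expect_false(correlate_window(cv, cv, node, 5, 3)$ok)
})

test_that("tie-breaking prefers the smallest displacement magnitude", {
  # periodic volume: every offset by the period correlates perfectly
  d <- c(24, 24, 24)
  base <- array(rep(c(10, 40, 90, 40), length.out = prod(d)), dim = d)
  v <- image_volume(base, 3.6)
  res <- correlate_window(v, v, c(12, 12, 12), cw = 4, search_range = 4)
  expect_equal(res$u, c(0L, 0L, 0L))
})

test_that("tri-quadratic sub-voxel peak matches the closed form", {
  grid <- expand.grid(z = -1:1, y = -1:1, x = -1:1)
  f <- function(z, y, x) 1 - 0.1 * (x - 0.3)^2 - 0.1 * (y + 0.2)^2 - 0.1 * z^2
  cube <- array(f(grid$z, grid$y, grid$x), dim = c(3, 3, 3))
  sp <- subpixel_triquadratic(cube)
  expect_true(sp$ok)
  expect_equal(sp$offset, c(0, -0.2, 0.3), tolerance = 1e-9)
  # symmetric cube peaks at the center
  g2 <- 1 - 0.05 * (grid$z^2 + grid$y^2 + grid$x^2)
  sp2 <- subpixel_triquadratic(array(g2, c(3, 3, 3)))
  expect_true(sp2$ok)
  expect_equal(sp2$offset, c(0, 0, 0), tolerance = 1e-12)
  # monotone toward a corner: no interior maximum
  g3 <- array(as.numeric(grid$z + grid$y + grid$x), c(3, 3, 3))
  expect_false(subpixel_triquadratic(g3)$ok)
  expect_false(subpixel_triquadratic(array(NA_real_, c(3, 3, 3)))$ok)
})

test_that("gradient refinement recovers sub-voxel translations", {
  v <- smooth_volume(c(40, 40, 40), seed = 13)
  t <- c(0.3, 0, 0)
  dv <- apply_deformation(v, deformation_uniform(t), fill = mean(v$data))
  node <- c(20, 20, 20)
  r <- correlate_window(v, dv, node, 7, 2)
  op <- subpixel_optimize(v, dv, node, 7, r$u)
  expect_lt(max(abs(op$u - t)), 0.05)
  # refinement never reduces the CC below the integer-search value
  expect_gte(op$cc, r$cc - 1e-6)
  # identical volumes: refinement stays at zero
  r0 <- correlate_window(v, v, node, 7, 2)
  op0 <- subpixel_optimize(v, v, node, 7, r0$u)
  expect_lt(max(abs(op0$u)), 1e-3)
})

test_that("run_dvc is shift-equivariant for integer shifts", {
  ph <- small_phantom()
  cfg <- dvc_config(cw = 7, ns = 7, search_range = 3, median_half_width = 0)
  for (k in list(c(1, 0, 0), c(2, -1, 3))) {
    dv <- apply_deformation(ph$volume, deformation_uniform(k), fill = 60)
    fld <- run_dvc(ph$volume, dv, ph$bone_mask, cfg)
    ok <- fld$status != "failed"
    expect_gt(sum(ok), 5)
    for (a in 1:3) expect_equal(unique(fld$u[, , , a][ok]), k[a])
    expect_true(all(fld$cc[ok] > 0.9999))
  }
})

test_that("swapping reference and deformed negates displacements", {
  ph <- small_phantom()
  defm <- deformation_affine(diag(c(0.995, 1, 1.005)),
                             center = (dim(ph$volume$data) - 1) / 2)
  dv <- apply_deformation(ph$volume, defm, fill = 60)
  cfg <- dvc_config(cw = 7, ns = 7, search_range = 2, median_half_width = 0)
  f1 <- run_dvc(ph$volume, dv, ph$bone_mask, cfg)
  f2 <- run_dvc(dv, ph$volume, ph$bone_mask, cfg)
  ok <- f1$status != "failed" & f2$status != "failed"
  expect_gt(sum(ok), 5)
  for (a in 1:3) {
    diffs <- f1$u[, , , a][ok] + f2$u[, , , a][ok]
    expect_lt(sqrt(mean(diffs^2)), 0.1)
  }
})
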