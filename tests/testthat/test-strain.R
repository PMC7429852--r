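# Build a displacement_field directly from an analytic function of the
# node coordinates, bypassing image correlation.
analytic_field <- function(ufun, gshape = c(5, 5, 5), ns = 10, cc = 1) {
  roi <- roi_spec(c(0, 0, 0), (gshape - 1) * ns + 2 * 11 + ns)
  grid <- make_node_grid(roi, ns, cw = 10, search_range = 1)
  g <- grid$shape
  u <- array(NA_real_, dim = c(g, 3))
  nodes <- as.matrix(expand.grid(z = grid$nodes_z, y = grid$nodes_y,
                                 x = grid$nodes_x))
  uu <- ufun(nodes)
  for (a in 1:3) u[, , , a] <- array(uu[, a], g)
  structure(list(grid = grid, u = u, cc = array(cc, g),
                 status = array("ok", g), voxel_size = 3.6),
            class = "displacement_field")
}

test_that("Green strain is exact for affine displacement fields", {
  A <- matrix(c(1.02, 0.01, 0, 0, 0.99, 0.005, 0, 0, 1.01), 3, 3, byrow = TRUE)
  fld <- analytic_field(function(X) X %*% t(A - diag(3)))
  sf <- green_strain(fld)
  E_true <- 0.5 * (t(A) %*% A - diag(3))
  expect_lt(max(abs(sf$E[, , , 1] - E_true[1, 1])), 1e-10)
  expect_lt(max(abs(sf$E[, , , 2] - E_true[2, 2])), 1e-10)
  expect_lt(max(abs(sf$E[, , , 3] - E_true[3, 3])), 1e-10)
  expect_lt(max(abs(sf$E[, , , 4] - E_true[1, 2])), 1e-10)
  expect_lt(max(abs(sf$E[, , , 5] - E_true[1, 3])), 1e-10)
  expect_lt(max(abs(sf$E[, , , 6] - E_true[2, 3])), 1e-10)
  expect_lt(max(abs(sf$volumetric - (det(A) - 1))), 1e-10)
})

test_that("rigid translation and rotation give zero Green strain", {
  fld <- analytic_field(function(X) matrix(c(4.2, -1.3, 0.7), nrow(X), 3,
                                           byrow = TRUE))
  sf <- green_strain(fld)
  expect_lt(max(abs(sf$E)), 1e-12)
  expect_lt(max(abs(sf$volumetric)), 1e-12)
  # finite rotation: objectivity distinguishes Green from small strain
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  fldr <- analytic_field(function(X) X %*% t(R - diag(3)))
  sfr <- green_strain(fldr)
  expect_lt(max(abs(sfr$E)), 1e-10)
  expect_lt(max(abs(sfr$volumetric)), 1e-10)
})

test_that("textbook strain states come out componentwise", {
  # 2% uniaxial stretch along x
  fld <- analytic_field(function(X) cbind(0 * X[, 1], 0 * X[, 2], 0.02 * X[, 3]))
  sf <- green_strain(fld)
  expect_equal(unique(round(as.vector(sf$E[, , , 3]), 12)), 0.0202)
  expect_lt(max(abs(sf$E[, , , c(1, 2, 4, 5, 6)])), 1e-12)
  # simple shear u_x = 0.1 Y: E12(x,y) = 0.05, E22(y) = 0.005
  flds <- analytic_field(function(X) cbind(0 * X[, 1], 0 * X[, 2], 0.1 * X[, 2]))
  sfs <- green_strain(flds)
  expect_equal(unique(round(as.vector(sfs$E[, , , 6]), 12)), 0.05)
  expect_equal(unique(round(as.vector(sfs$E[, , , 2]), 12)), 0.005)
  expect_lt(max(abs(sfs$E[, , , c(1, 3, 4, 5)])), 1e-12)
})

test_that("volumetric strain follows det(F) - 1", {
  fld <- analytic_field(function(X) 0.01 * X)  # isotropic 1% expansion
  sf <- green_strain(fld)
  expect_equal(unique(round(as.vector(sf$volumetric), 9)), 0.030301)
  fldc <- analytic_field(function(X) cbind(-0.01 * X[, 1], 0 * X[, 2], 0 * X[, 3]))
  expect_equal(unique(round(as.vector(volumetric_strain(green_strain(fldc))), 12)),
               -0.01)
  expect_gt(min(sf$volumetric, na.rm = TRUE), -1)
})

test_that("stepwise volumetric strain composes multiplicatively", {
  A1 <- diag(c(0.99, 1, 1)); A2 <- diag(c(1, 0.985, 1.002))
  f1 <- analytic_field(function(X) X %*% t(A1 - diag(3)))
  f2 <- analytic_field(function(X) X %*% t(A2 - diag(3)))
  v1 <- unique(round(as.vector(green_strain(f1)$volumetric), 12))
  v2 <- unique(round(as.vector(green_strain(f2)$volumetric), 12))
  expect_equal((1 + v1) * (1 + v2) - 1, det(A2 %*% A1) - 1, tolerance = 1e-10)
})

test_that("displacement outlier filtering follows the double-median rule", {
  fld <- analytic_field(function(X) matrix(1, nrow(X), 3), gshape = c(4, 4, 4))
  f0 <- filter_displacement_field(fld)
  expect_equal(f0$u, fld$u)  # constant field unchanged
  # one node at 10 voxels amid median 1: replaced by the median
  flo <- fld
  flo$u[2, 2, 2, 1] <- 10
  ff <- filter_displacement_field(flo)
  expect_equal(ff$u[2, 2, 2, 1], 1)
  expect_equal(ff$status[2, 2, 2], "filtered")
  # checkerboard +/-0.05 noise around zero survives the absolute floor
  chk <- analytic_field(function(X) {
    s <- (-1)^rowSums((X - 11) / 10)
    cbind(0.05 * s, 0.05 * s, 0.05 * s)
  }, gshape = c(4, 4, 4))
  fc <- filter_displacement_field(chk)
  expect_lte(max(abs(fc$u), na.rm = TRUE), 0.05 + 1e-12)
  expect_false(any(fc$status == "failed"))
})

test_that("correlation gating invalidates incident elements", {
  fld <- analytic_field(function(X) 0.001 * X, gshape = c(4, 4, 4))
  sf0 <- mask_by_correlation(green_strain(fld), 0.95)
  expect_true(all(sf0$valid))   # all CC = 1: nothing removed
  fld$cc[2, 2, 2] <- 0.5
  sf <- mask_by_correlation(green_strain(fld), 0.95)
  expect_equal(sum(!sf$valid), 8)  # the 8 elements incident to that node
  expect_true(all(is.na(sf$volumetric[!sf$valid])))
})
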