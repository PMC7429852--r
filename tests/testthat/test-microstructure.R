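test_that("bone mask applies the 8-bit operating range inclusively", {
  v <- image_volume(array(c(114, 115, 200, 255), c(1, 2, 2)), 3.6)
  m <- bone_mask(v)
  expect_equal(as.vector(m), c(FALSE, TRUE, TRUE, TRUE))
  expect_true(all(bone_mask(v, c(0, 255))))
  expect_error(bone_mask(image_volume(array(0, c(2, 2, 2)), 3.6)), "empty")
})

test_that("BV/TV is the bone voxel fraction", {
  m <- array(c(TRUE, FALSE), c(4, 4, 4))
  expect_equal(bvtv(m), 0.5)
  expect_equal(bvtv(array(FALSE, c(2, 2, 2))), 0)
  region <- array(TRUE, c(4, 4, 4))
  expect_equal(bvtv(m, m), 1)
  expect_equal(bvtv(m, region), 0.5)
})

test_that("local thickness of canonical shapes", {
  # laterally extended slab, 10 voxels thick: interior reads 10 * voxel_size
  slab <- array(FALSE, c(14, 40, 40))
  slab[3:12, , ] <- TRUE
  th <- local_thickness(slab, voxel_size = 2, method = "exact")
  interior <- th$map[7:8, 15:25, 15:25]
  expect_true(all(interior == 20))
  expect_true(all(is.na(th$map[!slab])))
  # digital ball of radius 6: central thickness ~ 2 r within one voxel
  d <- c(17, 17, 17)
  ctr <- c(9, 9, 9)
  g <- as.matrix(expand.grid(1:17, 1:17, 1:17))
  ball <- array(colSums((t(g) - ctr)^2) <= 36, d)
  thb <- local_thickness(ball, voxel_size = 1, method = "exact")
  expect_lt(abs(thb$map[9, 9, 9] - 12), 1)
  expect_error(local_thickness(array(FALSE, c(3, 3, 3))), "empty")
  expect_error(local_thickness(array(TRUE, c(3, 3, 3))), "background")
})

test_that("sphere-marking thickness equals the brute-force oracle", {
  shapes <- list(c(12, 12, 12), c(16, 10, 8), c(20, 20, 20))
  for (i in seq_along(shapes)) {
    set.seed(30 + i)
    d <- shapes[[i]]
    raw <- array(rnorm(prod(d)), d)
    sm <- array(trabstrain:::cpp_gauss_smooth3(raw, d, 1.5), d)
    mask <- sm >= quantile(sm, 0.6)
    if (!any(mask) || all(mask)) next
    th <- local_thickness(mask, voxel_size = 1, method = "exact")
    orc <- oracle_local_thickness(mask)
    expect_equal(th$map[mask], orc[mask], tolerance = 1e-12)
    # redundant-sphere pruning is an approximation that can only
    # underestimate, on average by less than a voxel
    thf <- local_thickness(mask, voxel_size = 1, method = "fast")
    expect_true(all(thf$map[mask] <= orc[mask] + 1e-9))
    expect_lt(mean(orc[mask] - thf$map[mask]), 1)
  }
})

test_that("TMD calibration fits the gray-density line", {
  mk <- function(g) {
    v <- image_volume(array(g, c(4, 4, 4)), 3.6)
    attr(v, "inside") <- array(TRUE, c(4, 4, 4))
    v
  }
  cal <- calibrate_tmd(list(mk(50), mk(100), mk(150)), c(250, 750, 1250))
  expect_equal(cal$slope, 10, tolerance = 1e-10)
  expect_equal(cal$intercept, -250, tolerance = 1e-8)
  expect_equal(cal$residual, 0, tolerance = 1e-8)
  # two points: the exact interpolating line
  cal2 <- calibrate_tmd(list(mk(60), mk(180)), c(300, 1500))
  expect_equal(cal2$slope * 60 + cal2$intercept, 300, tolerance = 1e-9)
  expect_error(calibrate_tmd(list(mk(100), mk(100)), c(250, 750)), "identical")
  # noisy phantom means from the generator feed the fit
  ps <- generate_density_phantoms(c(250, 750, 1250), noise_sd = 1, seed = 2)
  calp <- calibrate_tmd(ps, c(250, 750, 1250))
  expect_equal(calp$slope, 10, tolerance = 0.05)
})

test_that("TMD maps transform gray affinely on bone voxels only", {
  cal <- trabstrain:::new_tmd_calibration(10, -250)
  v <- image_volume(array(100, c(3, 3, 3)), 3.6)
  mask <- array(TRUE, c(3, 3, 3)); mask[1, 1, 1] <- FALSE
  m <- tmd_map(v, cal, mask)
  expect_equal(m[2, 2, 2], 750)
  expect_true(is.na(m[1, 1, 1]))
  id <- trabstrain:::new_tmd_calibration(1, 0)
  expect_equal(tmd_map(v, id, mask)[mask], v$data[mask])
  # default calibration reproduces the printed anchors
  dc <- default_tmd_calibration()
  expect_equal(dc$slope * 115 + dc$intercept, 833, tolerance = 1e-9)
  expect_equal(dc$slope * 255 + dc$intercept, 1746, tolerance = 1e-9)
  # monotone in gray
  expect_gt(dc$slope, 0)
})
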