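# Minimal strain_field stub on a regular element grid for interpolation tests
stub_strain_field <- function(vals, valid = NULL, ns = 10) {
  e <- dim(vals)
  if (is.null(valid)) valid <- array(TRUE, e)
  vals[!valid] <- NA_real_
  centers <- lapply(1:3, function(a) (seq_len(e[a]) - 1) * ns + 15)
  structure(list(E = NULL, F = NULL, volumetric = vals, valid = valid,
                 cc = array(1, e), centers = setNames(centers, c("z", "y", "x")),
                 ns = ns, voxel_size = 3.6),
            class = "strain_field")
}

test_that("voxel interpolation reproduces constant and linear element fields", {
  sf <- stub_strain_field(array(0.01, c(4, 4, 4)))
  m <- interpolate_strain_to_voxels(sf, c(60, 60, 60))
  inner <- m[16:45, 16:45, 16:45]
  expect_true(all(abs(inner - 0.01) < 1e-12))
  # outside the element hull: missing
  expect_true(all(is.na(m[1:14, , ])))
  # linear ramp along x reproduced exactly
  ramp <- array(rep(seq(0, 0.03, length.out = 4), each = 16), c(4, 4, 4))
  sfr <- stub_strain_field(ramp)
  mr <- interpolate_strain_to_voxels(sfr, c(60, 60, 60))
  xs <- 16:45
  expected <- 0.03 * (xs - 1 - 15) / 30
  expect_equal(mr[20, 20, xs], expected, tolerance = 1e-10)
  # an invalid element blanks its interior voxels
  valid <- array(TRUE, c(4, 4, 4)); valid[2, 2, 2] <- FALSE
  sfi <- stub_strain_field(array(0.01, c(4, 4, 4)), valid)
  mi <- interpolate_strain_to_voxels(sfi, c(60, 60, 60))
  expect_true(all(is.na(mi[25:35, 25:35, 25:35])))
  expect_false(anyNA(mi[16:20, 16:20, 40:45]))
})

test_that("signed cumulation with absolute maps and missing propagation", {
  d <- c(4, 4, 4)
  plus <- array(0.01, d); minus <- array(-0.01, d)
  cs <- accumulate_strain(list(plus, minus))
  expect_true(all(abs(cs$cumulative[[2]]) < 1e-15))
  expect_true(all(cs$absolute[[2]] == 0))
  cs2 <- accumulate_strain(list(minus, array(-0.02, d)))
  expect_true(all(abs(cs2$absolute[[2]] - 0.03) < 1e-15))
  # voxel missing at step 2 of 3 stays missing afterwards
  m2 <- plus; m2[1, 1, 1] <- NA
  cs3 <- accumulate_strain(list(plus, m2, plus))
  expect_false(anyNA(cs3$cumulative[[1]]))
  expect_true(is.na(cs3$cumulative[[2]][1, 1, 1]))
  expect_true(is.na(cs3$cumulative[[3]][1, 1, 1]))
  expect_equal(cs3$absolute[[2]], abs(cs3$cumulative[[2]]))
  expect_error(accumulate_strain(list(plus, array(0, c(3, 3, 3)))), "misaligned")
})

test_that("normalization to the yield point preserves endpoints", {
  out <- normalize_to_yield(c(0.01, 0.05), n_grid = 11)
  expect_equal(out$value[1], 0.01)
  expect_equal(out$value[11], 0.05)
  expect_equal(out$value[6], 0.03)  # midpoint of a linear series
  five <- normalize_to_yield(c(1, 2, 4, 8, 16), n_grid = 9)
  expect_equal(five$value[1], 1)
  expect_equal(five$value[9], 16)
  expect_error(normalize_to_yield(0.01), ">= 2 steps")
})

test_that("region summaries compute means per region and swap symmetrically", {
  d <- c(4, 4, 4)
  amap <- array(0.002, d)
  crack <- array(FALSE, d); crack[1:2, 1, 1] <- TRUE
  amap[1, 1, 1] <- 0.04; amap[2, 1, 1] <- 0.05
  bone <- array(TRUE, d)
  rm1 <- structure(list(crack_region = crack, non_crack_region = bone & !crack,
                        radius = 0), class = "region_mask")
  s <- summarize_regions(amap, rm1)
  expect_equal(s$mean[s$region == "crack"], 0.045)
  expect_equal(s$mean[s$region == "non_crack"], 0.002)
  expect_equal(s$n[s$region == "crack"], 2)
  # swapping labels swaps the summaries
  rm2 <- structure(list(crack_region = rm1$non_crack_region,
                        non_crack_region = rm1$crack_region, radius = 0),
                   class = "region_mask")
  s2 <- summarize_regions(amap, rm2)
  expect_equal(s2$mean[s2$region == "crack"], s$mean[s$region == "non_crack"])
  rm_empty <- structure(list(crack_region = array(FALSE, d),
                             non_crack_region = bone, radius = 0),
                        class = "region_mask")
  expect_error(summarize_regions(amap, rm_empty), "empty")
})

test_that("strain histograms are frequency-normalized and size-invariant", {
  d <- c(8, 8, 8)
  amap <- array(0.012, d)
  region <- array(TRUE, d)
  h <- strain_histogram(amap, region)
  expect_equal(sum(h$frequency), 1)
  expect_equal(h$frequency[h$lower == 0.010], 1)
  # same distribution at two region sizes gives the same frequencies
  set.seed(9)
  vals <- sample(c(0.004, 0.011, 0.019), prod(d), TRUE, prob = c(0.5, 0.3, 0.2))
  big <- array(vals, d)
  small <- big[1:4, 1:4, 1:4]
  hb <- strain_histogram(big, array(TRUE, d))
  hs <- strain_histogram(array(small, c(4, 4, 4)), array(TRUE, c(4, 4, 4)))
  expect_equal(sum(hb$frequency), 1)
  expect_equal(sum(hs$frequency), 1)
  expect_lt(max(abs(hb$frequency - hs$frequency)), 0.15)
  expect_error(strain_histogram(amap, array(FALSE, d)), "empty")
})

test_that("paired signed-rank test matches the exact enumeration oracle", {
  # n = 6, all differences positive: exact two-sided p = 2/2^6
  crack <- c(0.041, 0.052, 0.038, 0.060, 0.045, 0.049)
  non <- c(0.002, 0.003, 0.002, 0.004, 0.001, 0.003)
  r <- paired_wilcoxon(crack, non)
  expect_equal(r$p_value, 0.03125)
  expect_equal(r$p_value, oracle_signed_rank_p(crack - non))
  expect_true(r$conf_int[1] <= r$mean_difference &&
              r$mean_difference <= r$conf_int[2])
  # balanced equal-magnitude differences: p = 1
  a <- c(1, 2, 3, 4, 5, 6); b <- a + c(1, -1, 1, -1, 1, -1)
  expect_equal(paired_wilcoxon(a, b)$p_value, 1)
  # all-zero differences: p = 1 by convention
  expect_equal(paired_wilcoxon(a, a)$p_value, 1)
  # mixed-sign case agrees with enumeration
  d <- c(0.5, -0.2, 0.8, 1.1, -0.1, 0.3, 0.9)
  r2 <- paired_wilcoxon(d, rep(0, 7))
  expect_equal(r2$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  expect_error(paired_wilcoxon(1:3, 4:6), ">= 5")
})
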