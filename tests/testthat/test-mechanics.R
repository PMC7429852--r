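test_that("stress-strain conversion uses nominal area and compliance", {
  lc <- data.frame(displacement = c(0, 0.063), force = c(0, 100))
  ss <- to_stress_strain(lc, diameter = 7.1, height = 6.3, compliance = 0)
  expect_equal(ss$curve$stress[2], 100 / (pi * 3.55^2), tolerance = 1e-9)
  expect_equal(ss$curve$stress[2], 2.526, tolerance = 1e-3)
  expect_equal(ss$curve$strain[2], 0.01, tolerance = 1e-12)
  # compliance c reduces strain by c F / height
  ssc <- to_stress_strain(lc, 7.1, 6.3, compliance = 1e-4)
  expect_equal(ss$curve$strain[2] - ssc$curve$strain[2], 1e-4 * 100 / 6.3)
  expect_error(to_stress_strain(lc, 0, 6.3), "geometry")
})

test_that("apparent modulus comes from the linear region, pauses excluded", {
  c0 <- generate_load_curve(100, 0.02, hardening_ratio = 0.1, toe_strain = 0,
                            noise_sd = 0, n_points = 600)
  ss <- trabstrain:::as_stress_strain(c0)
  E <- apparent_modulus(ss)
  expect_equal(as.numeric(E), 100, tolerance = 1e-3)
  # inject relaxation drops (constant strain, dropping stress)
  drop1 <- data.frame(strain = rep(0.010, 5), stress = seq(1.0, 0.9, length.out = 5))
  drop2 <- data.frame(strain = rep(0.015, 5), stress = seq(1.5, 1.35, length.out = 5))
  withp <- rbind(c0[c0$strain <= 0.010, ], drop1,
                 c0[c0$strain > 0.010 & c0$strain <= 0.015, ], drop2,
                 c0[c0$strain > 0.015, ])
  Ep <- apparent_modulus(trabstrain:::as_stress_strain(withp))
  expect_equal(as.numeric(Ep), 100, tolerance = 5e-3)
  # pure toe with no rising linear branch errors
  flat <- data.frame(strain = seq(0, 0.01, length.out = 50),
                     stress = rep(0, 50))
  expect_error(apparent_modulus(trabstrain:::as_stress_strain(flat)))
})

test_that("toe correction recovers the zero-stress intercept", {
  # sigma = 100 (eps - 0.002) beyond a quadratic toe
  c1 <- generate_load_curve(100, 0.022, hardening_ratio = 0.05,
                            toe_strain = 0.004, noise_sd = 0, n_points = 800)
  tc <- toe_correct(trabstrain:::as_stress_strain(c1))
  expect_lt(abs(tc$toe_offset - 0.002), 1e-4)
  expect_equal(tc$modulus, 100, tolerance = 1e-2)
  # exactly linear curve through the origin: offset 0
  lin <- data.frame(strain = seq(0, 0.02, length.out = 100),
                    stress = 100 * seq(0, 0.02, length.out = 100))
  tc0 <- toe_correct(trabstrain:::as_stress_strain(lin))
  expect_equal(tc0$toe_offset, 0, tolerance = 1e-10)
})

test_that("0.2% offset yield solves the worked bilinear intersection", {
  # E = 100 MPa, post-yield slope 10 MPa from (0.02, 2 MPa):
  # 100 (e - 0.002) = 2 + 10 (e - 0.02)  =>  e = 0.02222, sigma = 2.0222
  eps <- seq(0, 0.05, length.out = 2001)
  sig <- ifelse(eps <= 0.02, 100 * eps, 2 + 10 * (eps - 0.02))
  ss <- trabstrain:::as_stress_strain(data.frame(strain = eps, stress = sig))
  y <- yield_offset(ss, modulus = 100)
  expect_equal(y$yield_stress, 2.022, tolerance = 1e-3)
  expect_equal(y$yield_strain_pct, 2.222, tolerance = 1e-3)
  # perfectly linear to failure: no intersection
  lin <- trabstrain:::as_stress_strain(
    data.frame(strain = eps, stress = 100 * eps))
  expect_error(yield_offset(lin, 100), "no intersection")
})

test_that("ultimate point and toughness integrate the curve", {
  # linear to (0.02, 2 MPa): toughness is the triangle area 0.02 MJ/m^3
  eps <- seq(0, 0.02, length.out = 400)
  rising <- trabstrain:::as_stress_strain(
    data.frame(strain = eps, stress = 100 * eps))
  u <- ultimate_toughness(rising)
  expect_equal(u$toughness_mj_m3, 0.02, tolerance = 1e-6)
  expect_true(u$censored)  # no interior maximum
  # plateau after a peak: ultimate at the maximum
  eps2 <- seq(0, 0.04, length.out = 400)
  sig2 <- pmin(100 * eps2, 2) - pmax(0, eps2 - 0.03) * 20
  peaked <- trabstrain:::as_stress_strain(
    data.frame(strain = eps2, stress = sig2))
  u2 <- ultimate_toughness(peaked)
  expect_equal(u2$ultimate_stress, 2)
  expect_false(u2$censored)
})

test_that("full summary recovers generating parameters of synthetic curves", {
  truth <- list(modulus = 250, yield_strain = 0.021, toe = 0.003)
  c0 <- generate_load_curve(truth$modulus, truth$yield_strain,
                            hardening_ratio = 0.05, toe_strain = truth$toe,
                            noise_sd = 0, n_points = 1500)
  ms <- mechanical_summary(trabstrain:::as_stress_strain(c0))
  expect_equal(ms$apparent_modulus_mpa, truth$modulus, tolerance = 0.01)
  expect_lt(abs(ms$toe_offset_strain - truth$toe / 2), 1e-4)
  # ultimate stress from the generator's peak
  s_y <- truth$modulus * (truth$yield_strain - truth$toe) +
         truth$modulus * truth$toe / 2
  s_u <- s_y + 0.05 * truth$modulus * 0.01
  expect_equal(ms$ultimate_stress_mpa, s_u, tolerance = 0.01)
  expect_true(ms$ultimate_stress_mpa >= ms$yield_stress_mpa)
  expect_true(ms$yield_strain_pct < ms$ultimate_strain_pct)
  # with mild noise the recovery stays within 5%
  cn <- generate_load_curve(truth$modulus, truth$yield_strain,
                            hardening_ratio = 0.05, toe_strain = truth$toe,
                            noise_sd = s_u / 40, n_points = 1500, seed = 3)
  msn <- mechanical_summary(trabstrain:::as_stress_strain(cn))
  expect_lt(abs(msn$apparent_modulus_mpa - truth$modulus) / truth$modulus, 0.05)
  expect_lt(abs(msn$ultimate_stress_mpa - s_u) / s_u, 0.05)
})
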