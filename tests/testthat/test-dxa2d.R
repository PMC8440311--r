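test_that("global modulus calibration follows the stress-over-strain form", {
  cal <- calibrate_e0(f = 1200, u = 0.1, l_eff = 16, a_eff_min = 50)
  expect_equal(cal$e0, 3840)
  # doubling the displacement halves the modulus
  expect_equal(calibrate_e0(1200, 0.2, 16, 50)$e0, 1920)
  # invariant holds exactly
  expect_equal(cal$e0, (cal$f / cal$a_eff_min) / (cal$u / cal$l_eff))
  expect_error(calibrate_e0(1200, 0, 16, 50), "positive")

  # round trip: simulated bar displacement recovers the generating modulus
  e_true <- 2750; a <- 40; l <- 16; f <- 900
  u_sim <- f * l / (a * e_true)
  expect_equal(calibrate_e0(f, u_sim, l, a)$e0, e_true, tolerance = 1e-12)
})

test_that("gray-to-modulus mapping is linear and mean-preserving", {
  m_uni <- gray_to_modulus(areal_map(matrix(80, 4, 4)), e0 = 3029)
  expect_equal(as.numeric(m_uni), rep(3029, 16))

  g <- matrix(c(rep(100, 8), rep(200, 8)), 4, 4)
  m2 <- gray_to_modulus(areal_map(g), e0 = 3000)
  expect_setequal(round(unique(as.numeric(m2)), 9), c(2000, 4000))
  expect_equal(mean(m2), 3000, tolerance = 1e-12)

  # dim band sits below e0, complement above
  gb <- matrix(150, 6, 10); gb[, 7:8] <- 75
  mb <- gray_to_modulus(areal_map(gb), e0 = 3000)
  idx <- attr(mb, "pixel_index")
  rows <- arrayInd(idx, dim(gb))[, 2]
  expect_true(all(mb[rows %in% 7:8] < 3000))
  expect_true(all(mb[!rows %in% 7:8] > 3000))

  expect_error(gray_to_modulus(areal_map(matrix(0, 2, 2)), 100), "zero")
})

test_that("model thickness preserves the nominal cross-section", {
  map <- areal_map(matrix(1, 28, 40), 0.5)   # 14 mm wide
  expect_equal(model_thickness(153.94, map), 153.94 / 14, tolerance = 1e-12)
  # W = d and a_n = pi d^2 / 4 gives t = pi d / 4
  d <- 14
  expect_equal(model_thickness(pi * d^2 / 4, map), pi * d / 4,
               tolerance = 1e-12)
  # halved pixel spacing at fixed physical extent leaves t unchanged
  map2 <- areal_map(matrix(1, 56, 80), 0.25)
  expect_equal(model_thickness(153.94, map2), model_thickness(153.94, map))
})

test_that("SIB summarises the strain field and its row profile correctly", {
  # uniform plane-strain state: flat profile, SIB = |eps| * 1e4
  res <- solve_column_2d(e0 = 3000, nu = 0.3, sigma = 10, nx = 4, nz = 8)
  s <- sib(res)
  expect_equal(s$sib, 30.33, tolerance = 1e-3)
  expect_equal(nrow(s$row_profile), 8)
  expect_lt(diff(range(s$row_profile$sib)), 1e-6 * s$sib)
  # row heights follow the bottom-up convention
  expect_equal(s$row_profile$z_norm, ((1:8) - 0.5) / 8)
  # global SIB bounds the row profile (max of means <= max of raw values)
  expect_true(all(s$row_profile$sib <= s$sib + 1e-12))

  # linearity in the applied force
  res2 <- solve_column_2d(e0 = 3000, nu = 0.3, sigma = 20, nx = 4, nz = 8)
  expect_equal(sib(res2)$sib, 2 * s$sib, tolerance = 1e-9)

  # a uniform field scaled to the printed pre-fatigue peak gives its SIB
  expect_equal(abs(-2.543e-3) * 1e4, 25.43)
})

test_that("a soft band is the weakest row of the 2D model", {
  g <- matrix(200, 16, 20)
  g[, 15:16] <- 100                       # band at ~75% height
  mesh <- pixels_to_quad(areal_map(g, 0.5), e0 = 3000, thickness = 5)
  res <- fe_solve(mesh, material_model(nu = 0.3),
                  load_case(500, constraint = "clamp",
                            distribution = "platen"))
  s <- sib(res)
  expect_true(s$weakest_row %in% 15:16)
  expect_gte(s$weakest_height, 0.70)
  expect_lte(s$weakest_height, 0.80)
})

test_that("row profile is flat away from the clamped row for homogeneous maps", {
  mesh <- pixels_to_quad(fix_uniform_map(10, 16, 120, 0.5), e0 = 3000,
                         thickness = 4)
  res <- fe_solve(mesh, material_model(nu = 0.3),
                  load_case(300, constraint = "clamp",
                            distribution = "platen"))
  prof <- sib(res)$row_profile
  interior <- prof$sib[3:(nrow(prof) - 2)]
  expect_lt((max(interior) - min(interior)) / mean(interior), 0.05)
})
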