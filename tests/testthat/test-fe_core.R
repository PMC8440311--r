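test_that("homogeneous plane-strain column reproduces the closed form", {
  # sigma = 10 MPa, E = 3000 MPa, nu = 0.3, roller base, free sides:
  # eps_axial = -sigma (1 - nu^2) / E everywhere
  res <- solve_column_2d(e0 = 3000, nu = 0.3, sigma = 10)
  expected <- -10 * (1 - 0.3^2) / 3000
  expect_equal(range(res$eps_ip[, , 2]), rep(expected, 2),
               tolerance = 1e-9)
  expect_equal(range(res$eps_p_min), rep(expected, 2), tolerance = 1e-9)
  # and the SIB of this state is 30.33
  expect_equal(sib(res)$sib, -expected * 1e4, tolerance = 1e-9)
})

test_that("homogeneous hexahedral block reproduces uniaxial Hooke's law", {
  bin <- fix_block(3, 3, 6)
  mesh <- voxels_to_hex(bin)
  sigma <- 10; e <- 3000
  res <- fe_solve(mesh, material_model(e = e, nu = 0.3),
                  load_case(sigma * 9, constraint = "roller",
                            distribution = "consistent"))
  expect_equal(range(res$eps_ip[, , 3]), rep(-sigma / e, 2),
               tolerance = 1e-9)
  expect_equal(range(res$eps_p_min), rep(-sigma / e, 2), tolerance = 1e-9)
  # transverse expansion nu * sigma / E
  expect_equal(range(res$eps_ip[, , 1]), rep(0.3 * sigma / e, 2),
               tolerance = 1e-9)
})

test_that("iterative and dense solutions agree on small irregular meshes", {
  set.seed(14)
  a <- array(runif(3 * 3 * 5) < 0.85, c(3, 3, 5))
  a[, , 1] <- TRUE; a[, , 5] <- TRUE
  mesh <- voxels_to_hex(binary_volume(a, 1))
  expect_lte(3 * nrow(mesh$nodes), 500)
  mt <- material_model(e = 2000, nu = 0.3)
  lc <- load_case(100, constraint = "clamp")
  u_pcg <- fe_solve(mesh, mt, lc, method = "pcg", tol = 1e-12)$u
  u_dense <- fe_solve(mesh, mt, lc, method = "dense")$u
  expect_lt(max(abs(u_pcg - u_dense)) / max(abs(u_dense)), 1e-8)

  # 2D as well
  set.seed(15)
  g <- matrix(ifelse(runif(6 * 8) < 0.9, 100, 0), 6, 8)
  g[, 1] <- 100; g[, 8] <- 100
  qm <- pixels_to_quad(areal_map(g, 0.5), e0 = 3000, thickness = 5)
  expect_lte(2 * nrow(qm$nodes), 500)
  up <- fe_solve(qm, material_model(nu = 0.3), lc, method = "pcg",
                 tol = 1e-12)$u
  ud <- fe_solve(qm, material_model(nu = 0.3), lc, method = "dense")$u
  expect_lt(max(abs(up - ud)) / max(abs(ud)), 1e-8)
})

test_that("minimum principal strain matches the eigenvalue oracle", {
  expect_equal(principal_min(diag(c(-0.002, 0.001, 0))), -0.002)
  # pure shear: eigenvalues +/- gamma/2
  sh <- matrix(0, 3, 3); sh[1, 2] <- sh[2, 1] <- 0.001
  expect_equal(principal_min(sh), -0.001, tolerance = 1e-12)

  set.seed(99)
  for (i in 1:100) {
    m <- matrix(rnorm(9), 3, 3) * 1e-3
    m <- (m + t(m)) / 2
    expect_equal(principal_min(m), oracle_min_eig(m), tolerance = 1e-10)
  }
  expect_error(principal_min(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
})

test_that("solver is linear in the load and balances reactions", {
  set.seed(23)
  a <- array(runif(4 * 4 * 6) < 0.8, c(4, 4, 6))
  a[, , 1] <- TRUE; a[, , 6] <- TRUE
  mesh <- voxels_to_hex(binary_volume(a, 0.5))
  mt <- material_model(e = 3000, nu = 0.3)
  r1 <- fe_solve(mesh, mt, load_case(100))
  r3 <- fe_solve(mesh, mt, load_case(300))
  expect_equal(3 * r1$u, r3$u, tolerance = 1e-7)
  expect_equal(3 * r1$eps_p_min, r3$eps_p_min, tolerance = 1e-7)
  # bottom reaction balances the applied force
  expect_lt(abs(abs(r1$reaction_sum) - 100) / 100, 1e-6)

  # clamped bottom concentrates strain relative to rollers (homogeneous)
  bm <- voxels_to_hex(fix_block(4, 4, 6, spacing = 0.5))
  pc <- fe_solve(bm, mt, load_case(100, constraint = "clamp",
                                   distribution = "consistent"))
  pr <- fe_solve(bm, mt, load_case(100, constraint = "roller",
                                   distribution = "consistent"))
  expect_gte(pc$peak$abs_value, pr$peak$abs_value)
})

test_that("model stiffness follows the bar formula and scales with E", {
  # homogeneous block with the pre-fatigue modulus: k = E A / L
  e_pre <- 3029
  bin <- fix_block(4, 4, 8, spacing = 0.5)
  mesh <- voxels_to_hex(bin)
  res <- fe_solve(mesh, material_model(e = e_pre, nu = 0.3),
                  load_case(500, constraint = "roller",
                            distribution = "consistent"))
  a_sec <- (4 * 0.5)^2; len <- 8 * 0.5
  expect_equal(model_stiffness(res), e_pre * a_sec / len, tolerance = 1e-9)

  res2 <- fe_solve(mesh, material_model(e = 2 * e_pre, nu = 0.3),
                   load_case(500, constraint = "roller",
                             distribution = "consistent"))
  expect_equal(model_stiffness(res2), 2 * model_stiffness(res),
               tolerance = 1e-9)
})

test_that("refinement leaves homogeneous stiffness unchanged and releases strain energy under clamping", {
  # uniform refinement of the same physical column (2D): the clamped model
  # softens monotonically (strain energy grows) as the constraint layer is
  # resolved
  g1 <- matrix(100, 4, 8)
  m1 <- pixels_to_quad(areal_map(g1, 0.5), e0 = 3000, thickness = 2)
  g2 <- matrix(100, 8, 16)
  m2 <- pixels_to_quad(areal_map(g2, 0.25), e0 = 3000, thickness = 2)
  lc <- load_case(40, constraint = "clamp", distribution = "platen")
  k1 <- fe_solve(m1, material_model(nu = 0.3), lc)$stiffness
  k2 <- fe_solve(m2, material_model(nu = 0.3), lc)$stiffness
  expect_lte(k2, k1 * (1 + 1e-9))
  expect_lt(abs(k2 - k1) / k1, 0.02)

  # away from constraint layers the discretization is already converged:
  # roller ends give the exact bar stiffness at both resolutions
  lr <- load_case(40, constraint = "roller", distribution = "consistent")
  kr1 <- fe_solve(m1, material_model(nu = 0.3), lr)$stiffness
  kr2 <- fe_solve(m2, material_model(nu = 0.3), lr)$stiffness
  expect_lt(abs(kr2 - kr1) / kr1, 0.005)
})
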