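test_that("voxel-to-hex conversion counts elements and nodes correctly", {
  # 2x2x2 full block: 8 cubes sharing a 3x3x3 corner grid
  m <- voxels_to_hex(fix_block(2, 2, 2))
  expect_equal(nrow(m$elements), 8)
  expect_equal(nrow(m$nodes), 27)
  expect_true(all(apply(m$elements, 1, function(e) length(unique(e)) == 8)))

  # single voxel: unit cube with perfect quality
  s <- voxels_to_hex(binary_volume(array(TRUE, c(1, 1, 1)), 0.0256))
  expect_equal(nrow(s$elements), 1)
  expect_equal(nrow(s$nodes), 8)
  q <- mesh_quality(s)
  expect_equal(q$aspect_ratio, 1)
  expect_equal(q$max_corner_angle, 90)
  expect_equal(q$min_scaled_jacobian, 1)

  # node dedup: fewer than 8m nodes whenever elements share faces
  expect_lt(nrow(m$nodes), 8 * nrow(m$elements))

  expect_error(voxels_to_hex(binary_volume(array(FALSE, c(2, 2, 2)), 1)),
               "empty")
})

test_that("coarsening applies the majority vote (block-vote oracle)", {
  set.seed(21)
  a <- array(runif(12^3) < 0.5, c(12, 12, 12))
  bin <- binary_volume(a, 1)
  m <- voxels_to_hex(bin, coarsen = 2)
  voted <- oracle_block_vote(a, 2)
  lab <- oracle_flood_label(voted, 6)
  keep_count <- max(tabulate(lab[lab > 0]))
  expect_equal(nrow(m$elements), keep_count)
  expect_equal(m$elem_size, 2)

  # coarsen = 1 element count equals the largest face-connected bone set
  m1 <- voxels_to_hex(bin, coarsen = 1)
  lab1 <- oracle_flood_label(a, 6)
  expect_equal(nrow(m1$elements), max(tabulate(lab1[lab1 > 0])))
})

test_that("pixel-to-quad meshing assigns mean-preserving moduli", {
  map <- areal_map(matrix(1, 3, 3), 0.5)
  m <- pixels_to_quad(map, e0 = 3029, thickness = 11)
  expect_equal(nrow(m$elements), 9)
  expect_equal(nrow(m$nodes), 16)
  expect_equal(m$elem_modulus, rep(3029, 9))

  # detached pixel is dropped by the largest-component rule
  g <- matrix(0, 5, 5)
  g[1:3, 1:3] <- 100
  g[5, 5] <- 80
  m2 <- pixels_to_quad(areal_map(g, 0.5), e0 = 1000, thickness = 1)
  expect_equal(nrow(m2$elements), 9)
  # mean modulus equals the calibrated global modulus exactly
  expect_equal(mean(m2$elem_modulus), 1000, tolerance = 1e-12)

  expect_error(pixels_to_quad(areal_map(matrix(0, 3, 3)), 100, 1), "zero")
})

test_that("quality metrics match direct evaluation on distorted elements", {
  # 2:1 stretched brick
  m <- voxels_to_hex(fix_block(1, 1, 1))
  m$nodes[, 3] <- m$nodes[, 3] * 2
  q <- mesh_quality(m)
  expect_equal(q$aspect_ratio, 2)
  expect_equal(q$max_corner_angle, 90)
  expect_equal(q$min_scaled_jacobian, 1)   # right angles survive stretching

  # jittered cube: scaled Jacobian against corner determinants via det()
  set.seed(8)
  mj <- voxels_to_hex(fix_block(1, 1, 1))
  mj$nodes <- mj$nodes + matrix(runif(24, -0.1, 0.1), 8, 3)
  qj <- mesh_quality(mj)
  adj <- list(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
              c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))
  sj <- sapply(1:8, function(ci) {
    es <- sapply(adj[[ci]], function(a2)
      mj$nodes[mj$elements[1, a2], ] - mj$nodes[mj$elements[1, ci], ])
    det(es) / prod(sqrt(colSums(es^2)))
  })
  expect_equal(qj$min_scaled_jacobian, min(sj), tolerance = 1e-12)

  # voxel meshes always satisfy the image-based meshing thresholds
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 24), seed = 4))
  qp <- mesh_quality(voxels_to_hex(ph))
  expect_lte(qp$aspect_ratio, 3)
  expect_lt(qp$max_corner_angle, 160)
  expect_gt(qp$min_scaled_jacobian, 0.7)
})
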