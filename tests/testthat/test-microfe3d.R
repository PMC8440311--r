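test_that("percentage changes reproduce the printed damage-progression deltas", {
  # peak strain deltas vs pre-fatigue
  expect_equal(pct_change(2.543e-3, 4.387e-3), 72.5128, tolerance = 1e-6)
  expect_equal(pct_change(2.543e-3, 4.387e-3, rounded = TRUE), 73)
  expect_equal(pct_change(2.543e-3, 5.388e-3, rounded = TRUE), 112)
  # stiffness validation delta (experimental value as reference)
  expect_equal(pct_change(5219, 4367, rounded = TRUE), 16)
  expect_equal(pct_change(4, 4), 0)
  expect_error(pct_change(0, 1), "zero")
  # the convention is reference-first: swapping the operands does not give
  # the printed numbers
  expect_false(pct_change(4.387e-3, 2.543e-3, rounded = TRUE) == 73)
})

test_that("condition series is linear in the modulus and validates ordering", {
  bin <- fix_block(3, 3, 6, spacing = 0.5)
  mesh <- voxels_to_hex(bin)
  sr <- run_series(list(mesh, mesh), e_values = c(3000, 1500),
                   load = load_case(100), n_cycles = c(0, 1000))
  pk <- sr$metrics$peak_abs_eps_min
  expect_equal(pk[2], 2 * pk[1], tolerance = 1e-9)
  expect_equal(sr$metrics$pct_change_vs_pre, c(0, 100), tolerance = 1e-6)
  expect_error(run_series(list(mesh, mesh), c(1, 2), n_cycles = c(5, 1)),
               "ordered")
  expect_error(run_series(list(mesh), 1, n_cycles = 1,
                          labels = c("a")), NA)
})

test_that("critical slice tracks the constructed weak region", {
  # homogeneous clamped block: the constraint concentration puts the peak
  # next to the clamped face
  bin <- fix_block(4, 4, 8, spacing = 0.5)
  mesh <- voxels_to_hex(bin)
  res <- fe_solve(mesh, material_model(e = 2000, nu = 0.3),
                  load_case(200, constraint = "clamp",
                            distribution = "platen"))
  cs <- critical_slice(res)
  expect_true(cs$slice %in% c(1, 8))
  expect_equal(dim(cs$slice_map), c(4, 4))

  # notched block: slice with reduced section carries the peak
  a <- array(TRUE, c(6, 6, 10))
  a[, 4:6, 6] <- FALSE                      # halve slice 6
  resn <- fe_solve(voxels_to_hex(binary_volume(a, 0.5)),
                   material_model(e = 2000, nu = 0.3),
                   load_case(200, constraint = "roller",
                             distribution = "consistent"))
  expect_equal(critical_slice(resn)$slice, 6)

  # two notches of unequal severity: the weaker one wins
  b <- array(TRUE, c(6, 6, 12))
  b[, 5:6, 4] <- FALSE                      # mild notch
  b[, 3:6, 9] <- FALSE                      # severe notch
  resb <- fe_solve(voxels_to_hex(binary_volume(b, 0.5)),
                   material_model(e = 2000, nu = 0.3),
                   load_case(200, constraint = "roller",
                             distribution = "consistent"))
  expect_equal(critical_slice(resb)$slice, 9)
})

test_that("progressively eroded weak bands strictly increase the peak strain", {
  spec <- phantom_spec(shape = c(32, 32, 32), weak_band = c(0.6, 0.1, 0.2),
                       seed = 6)
  series <- make_damage_series(spec, reductions = c(0.2, 0.4, 0.6))
  meshes <- lapply(series, voxels_to_hex, coarsen = 1)
  sr <- run_series(meshes, e_values = rep(3000, 3),
                   load = load_case(100, distribution = "platen"),
                   n_cycles = c(0, 1000, 2000),
                   labels = c("pre-fatigue", "interrupted_1", "post-fatigue"))
  pk <- sr$metrics$peak_abs_eps_min
  expect_true(all(diff(pk) > 0))
})
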