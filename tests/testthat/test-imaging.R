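test_that("Gaussian blur matches the dense convolution oracle and conserves mass", {
  set.seed(42)
  # single impulse: kernel response, sum preserved
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 1
  v <- gray_volume(a, 1)
  b <- gaussian_blur(v, 1.5)
  expect_equal(sum(b$data), 1, tolerance = 1e-12)
  expect_equal(b$data, oracle_gaussian_blur(a, 1.5), tolerance = 1e-12)
  expect_gt(b$data[5, 5, 5], max(b$data) - 1e-15)   # centered on the impulse

  # impulse pair: superposition, against the same oracle
  a2 <- array(0, c(9, 9, 9)); a2[3, 4, 5] <- 1; a2[7, 6, 2] <- 1
  b2 <- gaussian_blur(gray_volume(a2, 1), 1.5)
  expect_equal(b2$data, oracle_gaussian_blur(a2, 1.5), tolerance = 1e-12)

  # flat field is exactly invariant; sigma = 0 is the identity
  flat <- gray_volume(array(3.7, c(5, 6, 4)), 0.5)
  expect_equal(gaussian_blur(flat, 2)$data, flat$data, tolerance = 1e-12)
  expect_identical(gaussian_blur(flat, 0), flat)

  # linearity
  x <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  y <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  lhs <- gaussian_blur(gray_volume(2 * x + 3 * y, 1), 1.2)$data
  rhs <- 2 * gaussian_blur(gray_volume(x, 1), 1.2)$data +
    3 * gaussian_blur(gray_volume(y, 1), 1.2)$data
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(gaussian_blur(v, NA), "sigma")
  expect_error(gaussian_blur(v, -1), "sigma")
})

test_that("Otsu threshold minimizes intra-class variance (exhaustive scan)", {
  # two-level image: cut falls strictly between the levels
  a <- array(0, c(4, 4, 4)); a[1:2, , ] <- 255
  o <- otsu_threshold(gray_volume(a, 1))
  expect_gt(o$threshold, 0)
  expect_lt(o$threshold, 255)
  expect_identical(o$bin$data, a > 128)

  # trimodal and random images agree with the brute-force 256-scan
  imgs <- list(
    array(rep(c(0, 100, 255), each = 9), c(3, 3, 3)),
    with(list(), {set.seed(3); array(sample(0:255, 4^3, TRUE), c(4, 4, 4))}),
    with(list(), {set.seed(9); array(c(rnorm(40, 50, 10),
                                       rnorm(24, 200, 10)), c(4, 4, 4))}))
  for (img in imgs) {
    o <- otsu_threshold(gray_volume(img, 1))
    lo <- min(img); hi <- max(img)
    g8 <- round(255 * (img - lo) / (hi - lo))
    sc <- oracle_otsu_scan(g8)
    expect_true(o$threshold %in% sc$minimizers ||
                  o$threshold == floor(mean(sc$minimizers)))
    # the chosen threshold attains the scan's minimum variance
    k <- o$threshold
    intra_k <- {
      cls <- g8 <= k
      n <- length(g8)
      v0 <- if (any(cls)) var(g8[cls]) * (sum(cls) - 1) / sum(cls) else 0
      v1 <- if (any(!cls)) var(g8[!cls]) * (sum(!cls) - 1) / sum(!cls) else 0
      (sum(cls) * v0 + sum(!cls) * v1) / n
    }
    expect_equal(intra_k, sc$min_intra, tolerance = 1e-9)
  }

  expect_error(otsu_threshold(gray_volume(array(5, c(3, 3, 3)), 1)),
               "constant")
})

test_that("Otsu segmentation recovers a known phantom volume fraction", {
  set.seed(11)
  d <- c(24, 24, 24)
  truth <- array(runif(prod(d)) < 0.35, d)    # generating fraction
  img <- ifelse(truth, rnorm(prod(d), 200, 10), rnorm(prod(d), 50, 10))
  dim(img) <- d
  o <- otsu_threshold(gray_volume(img, 1))
  expect_lt(abs(mean(o$bin$data) - mean(truth)), 0.01)

  # per-slice mode runs and stays close to the global segmentation
  ops <- otsu_threshold(gray_volume(img, 1), per_slice = TRUE)
  expect_length(ops$threshold, d[3])
  expect_lt(mean(ops$bin$data != o$bin$data), 0.02)
})

test_that("largest_component keeps the dominant component with deterministic ties", {
  a <- array(FALSE, c(8, 8, 8))
  a[2:4, 2:4, 2:4] <- TRUE          # 27-voxel block
  a[7, 7, 7] <- TRUE                # floating speck
  lc <- largest_component(binary_volume(a, 1))
  expect_equal(sum(lc$data), 27)
  expect_false(lc$data[7, 7, 7])

  # equal-size tie: the component reached first in scan order wins
  b <- array(FALSE, c(8, 4, 4))
  b[1:2, 1:2, 1:2] <- TRUE
  b[6:7, 1:2, 1:2] <- TRUE
  t1 <- largest_component(binary_volume(b, 1))
  expect_true(t1$data[1, 1, 1])
  expect_false(t1$data[6, 1, 1])

  # idempotence
  expect_identical(largest_component(lc)$data, lc$data)

  expect_error(largest_component(binary_volume(array(FALSE, c(2, 2, 2)), 1)),
               "empty")
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(5)
  a <- array(runif(10^3) < 0.2, c(10, 10, 10))   # speckle
  a[4:6, 4:6, ] <- TRUE                           # solid rod
  bin <- binary_volume(a, 1)
  for (conn in c(6, 26)) {
    lab <- label_components(bin, conn)
    ora <- oracle_flood_label(a, conn)
    # same partition: label images identical up to renaming
    expect_equal(max(lab), max(ora))
    expect_true(all(tapply(ora[a], lab[a], function(x) length(unique(x))) == 1))
    # and largest_component retains the rod
    lc <- largest_component(bin, conn)
    expect_true(all(lc$data[4:6, 4:6, ]))
    expect_equal(sum(lc$data), max(tabulate(ora[ora > 0])))
  }
})
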