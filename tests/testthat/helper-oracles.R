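# Independent oracles used to check the package's fast implementations.
# These are deliberately naive (loops, dense algebra) and share no code with
# the implementation paths they verify.

# Direct dense 3D convolution with a separable Gaussian kernel and
# scipy-style reflected borders.
oracle_gaussian_blur <- function(a, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(a)
  reflect <- function(i, n) {
    while (any(i < 1L) || any(i > n)) {
      i[i < 1L] <- 1L - i[i < 1L]
      i[i > n] <- 2L * n + 1L - i[i > n]
    }
    i
  }
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (s in seq_len(d[3])) {
    acc <- 0
    for (ti in seq_along(k)) for (tj in seq_along(k)) for (ts in seq_along(k)) {
      ii <- reflect(i + ti - r - 1L, d[1])
      jj <- reflect(j + tj - r - 1L, d[2])
      ss <- reflect(s + ts - r - 1L, d[3])
      acc <- acc + k[ti] * k[tj] * k[ts] * a[ii, jj, ss]
    }
    out[i, j, s] <- acc
  }
  out
}

# Exhaustive 256-candidate intra-class-variance scan on 8-bit data.
# Returns the set of minimizing thresholds and the minimal variance.
oracle_otsu_scan <- function(g) {
  counts <- tabulate(as.integer(g) + 1L, nbins = 256L)
  n <- sum(counts)
  lev <- 0:255
  intra <- rep(Inf, 256)
  for (k in 0:255) {
    c0 <- counts[lev <= k]
    c1 <- counts[lev > k]
    n0 <- sum(c0); n1 <- sum(c1)
    if (n0 == 0 || n1 == 0) next
    l0 <- lev[lev <= k]; l1 <- lev[lev > k]
    m0 <- sum(c0 * l0) / n0; m1 <- sum(c1 * l1) / n1
    v0 <- sum(c0 * (l0 - m0)^2) / n0
    v1 <- sum(c1 * (l1 - m1)^2) / n1
    intra[k + 1] <- (n0 * v0 + n1 * v1) / n
  }
  best <- which(intra <= min(intra) + 1e-12) - 1L
  list(minimizers = best, min_intra = min(intra))
}

# Queue-based flood-fill labeling of a 3D logical array.
oracle_flood_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ai <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        w <- ai + offs[o, ]
        if (any(w < 1L) || any(w > d)) next
        wi <- w[1] + d[1] * ((w[2] - 1L) + d[2] * (w[3] - 1L))
        if (mask[wi] && lab[wi] == 0L) {
          lab[wi] <- cur
          queue <- c(queue, wi)
        }
      }
    }
  }
  lab
}

# Majority-vote block downsampling by explicit per-block loops
# (ties count as bone).
oracle_block_vote <- function(a, f) {
  d <- dim(a)
  d2 <- ceiling(d / f)
  out <- array(FALSE, d2)
  for (i in seq_len(d2[1])) for (j in seq_len(d2[2])) for (s in seq_len(d2[3])) {
    ri <- ((i - 1) * f + 1):min(i * f, d[1])
    rj <- ((j - 1) * f + 1):min(j * f, d[2])
    rs <- ((s - 1) * f + 1):min(s * f, d[3])
    blk <- a[ri, rj, rs]
    out[i, j, s] <- sum(blk) * 2 >= length(blk)
  }
  out
}

# Smallest eigenvalue via base::eigen (the cross-check for the closed-form
# principal-strain path).
oracle_min_eig <- function(m) min(eigen(m, symmetric = TRUE,
                                        only.values = TRUE)$values)

# Hand-computed t prediction interval of a log10-log10 regression
# (independent of predict.lm).
oracle_pred_interval <- function(x, y, x0, level = 0.95) {
  n <- length(x)
  xb <- mean(x)
  sxx <- sum((x - xb)^2)
  bhat <- sum((x - xb) * (y - mean(y))) / sxx
  ahat <- mean(y) - bhat * xb
  res <- y - (ahat + bhat * x)
  s <- sqrt(sum(res^2) / (n - 2))
  tq <- qt((1 + level) / 2, n - 2)
  se <- s * sqrt(1 + 1 / n + (x0 - xb)^2 / sxx)
  yhat <- ahat + bhat * x0
  cbind(fit = yhat, lwr = yhat - tq * se, upr = yhat + tq * se)
}

# --- small fixtures ------------------------------------------------------

# Full cuboid volume (all bone).
fix_block <- function(nx = 3, ny = 3, nz = 6, spacing = 1) {
  binary_volume(array(TRUE, c(nx, ny, nz)), spacing)
}

# Two horizontal plates bridged by a single strut; `horizontal = TRUE`
# orients the strut across the load axis.
fix_rod_phantom <- function(horizontal = TRUE, n = 12, spacing = 0.1) {
  a <- array(FALSE, c(n, n, 10))
  a[, , 1:2] <- TRUE
  a[, , 9:10] <- TRUE
  if (horizontal) {
    a[, 6:7, 3:8] <- TRUE            # beam along x, full width
  } else {
    a[6:7, 6:7, 3:8] <- TRUE         # vertical strut
  }
  binary_volume(a, spacing)
}

# Uniform rectangular areal map.
fix_uniform_map <- function(ncol_px = 4, nrow_px = 8, gray = 100,
                            spacing = 0.5) {
  areal_map(matrix(gray, ncol_px, nrow_px), spacing)
}

# Quick uniform-stress plane-strain solve used by several tests.
solve_column_2d <- function(e0 = 3000, nu = 0.3, sigma = 10, nx = 4,
                            nz = 8, h = 0.5, thickness = 2) {
  mesh <- pixels_to_quad(fix_uniform_map(nx, nz, spacing = h), e0 = e0,
                         thickness = thickness)
  f <- sigma * nx * h * thickness
  fe_solve(mesh, material_model(nu = nu),
           load_case(f, constraint = "roller", distribution = "consistent"))
}
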