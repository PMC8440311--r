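#' Phantom specification
#'
#' Parameters of the seeded trabecular phantom generator: a Gaussian random
#' field with a stated correlation length (the strut scale), thresholded per
#' slice so the realized BV/TV profile tracks a target profile, optionally
#' depressed inside a localized weak band. The footprint is the cylinder
#' inscribed in the transverse grid, emulating a cored cylindrical specimen
#' at micro-CT resolution.
#'
#' @param shape voxel dimensions (default 64 x 64 x 64).
#' @param spacing voxel edge (mm); default 0.0256 (micro-CT-like).
#' @param target_bvtv target bone volume fraction in (0, 1); default 0.30,
#'   a typical vertebral trabecular value.
#' @param correlation_length strut scale (mm): the standard deviation of
#'   the Gaussian smoothing that shapes the random field. Default 0.03,
#'   chosen so the structural wavelength-to-diameter ratio of the
#'   desk-scale phantom matches a real trabecular core (~1/20) rather than
#'   the absolute strut width; see the package vignette.
#' @param weak_band `NULL`, or `c(center_z_norm, half_width_norm,
#'   bvtv_reduction)`: inside the band the target BV/TV is multiplied by
#'   `1 - bvtv_reduction`.
#' @param axial_elongation ratio of the axial to the transverse correlation
#'   length (default 2): vertebral trabecular architecture is transversely
#'   isotropic, with plates and rods preferentially aligned with the
#'   (axial) habitual load direction.
#' @param seed integer; the phantom is a pure function of (spec, seed).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = 0.0256,
                         target_bvtv = 0.30, correlation_length = 0.03,
                         weak_band = NULL, axial_elongation = 2,
                         seed = 1) {
  if (target_bvtv <= 0 || target_bvtv >= 1)
    stop_param("`target_bvtv` must be in (0, 1)")
  if (!is.null(weak_band)) {
    if (length(weak_band) != 3 || weak_band[1] < 0 || weak_band[1] > 1 ||
        weak_band[2] < 0 || weak_band[3] < 0 || weak_band[3] > 1)
      stop_param("`weak_band` must be c(center in [0,1], half width >= 0, ",
                 "reduction in [0,1])")
  }
  if (axial_elongation <= 0) stop_param("`axial_elongation` must be > 0")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 target_bvtv = target_bvtv,
                 correlation_length = correlation_length,
                 weak_band = weak_band, axial_elongation = axial_elongation,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Target BV/TV per slice implied by the spec (the generator ground truth).
phantom_target_profile <- function(spec) {
  nz <- spec$shape[3]
  z <- (seq_len(nz) - 0.5) / nz
  t <- rep(spec$target_bvtv, nz)
  if (!is.null(spec$weak_band)) {
    inband <- abs(z - spec$weak_band[1]) <= spec$weak_band[2]
    t[inband] <- t[inband] * (1 - spec$weak_band[3])
  }
  t
}

#' Generate a trabecular phantom
#'
#' White noise is smoothed by a Gaussian kernel with standard deviation
#' `correlation_length / spacing` voxels, then each axial slice is
#' thresholded at the quantile that realizes the target BV/TV of that slice
#' (inside the cylindrical footprint); finally the largest 26-connected
#' component is kept. The generating per-slice profile is attached as
#' ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A [binary_volume()] with attributes `target_profile` (per-slice
#'   BV/TV the generator aimed at) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sigma_vox <- spec$correlation_length / spec$spacing
  elong <- spec$axial_elongation %||% 1
  field <- with_seed(spec$seed, array(rnorm(prod(d)), d))
  kxy <- gauss_kernel_1d(sigma_vox)
  kz <- gauss_kernel_1d(sigma_vox * elong)
  field <- convolve_axis_reflect(field, kxy, 1L)
  field <- convolve_axis_reflect(field, kxy, 2L)
  field <- convolve_axis_reflect(field, kz, 3L)

  rad <- min(d[1], d[2]) / 2
  u <- seq_len(d[1]) - 0.5 - d[1] / 2
  v <- seq_len(d[2]) - 0.5 - d[2] / 2
  inside <- outer(u^2, v^2, "+") <= rad^2

  target <- phantom_target_profile(spec)
  # iterate the per-slice quantile threshold so the REALIZED profile (after
  # largest-component cleanup) meets the target, compensating the mass lost
  # with the disconnected specks
  aim <- target
  for (pass in 1:3) {
    mask <- array(FALSE, d)
    for (s in seq_len(d[3])) {
      vals <- field[, , s][inside]
      thr <- quantile(vals, 1 - min(aim[s], 0.999), names = FALSE, type = 7)
      mask[, , s] <- field[, , s] > thr & inside
    }
    bin <- largest_component(binary_volume(mask, spec$spacing), 26)
    realized <- vapply(seq_len(d[3]), function(s)
      mean(bin$data[, , s][inside]), numeric(1))
    gap <- target - realized
    if (max(abs(gap)) < 0.002) break
    aim <- pmax(pmin(aim + gap, 0.999), 0.001)
  }
  realized_total <- mean(realized)
  if (realized_total < 0.5 * spec$target_bvtv)
    stop_param(sprintf(
      "infeasible phantom: realized BV/TV %.3f < half the target %.3f after cleanup",
      realized_total, spec$target_bvtv))
  attr(bin, "target_profile") <- target
  attr(bin, "spec") <- spec
  bin
}

#' Project a segmented volume to a DXA-like areal map
#'
#' Bone path length (mm) summed along one transverse axis, block-averaged to
#' the requested pixel size and linearly rescaled to 8-bit. Before the
#' rescale the map conserves bone mass: its sum times the pixel area equals
#' the bone volume (up to partial edge blocks). The raw path-length map is
#' kept as attribute `pathlen_mm`.
#'
#' @param bin a [binary_volume()].
#' @param pixel_mm output pixel size (mm); must be >= the voxel spacing
#'   (0.5 mm is the DXA-like value).
#' @param axis projection (ray) axis: `"x"` or `"y"` (default `"y"`).
#' @param mask_partial emulate the scanner's specimen segmentation with the
#'   customary region-of-interest erosion: pixels whose transverse extent
#'   is not fully inside the specimen's circular silhouette (the inscribed
#'   cylinder of the grid), plus an erosion margin of `rim_erode_px`
#'   pixels, are set to background (0) — partial-volume rim pixels carry
#'   spuriously low areal density. Default `TRUE`; the raw path-length
#'   attribute is not masked.
#' @param rim_erode_px erosion margin in pixels (default 1).
#' @param psf_sigma_px optional detector point-spread blur (Gaussian, in
#'   pixels) applied to the binned path-length map before the 8-bit
#'   rescale; 0 (default) is the pure geometric projection.
#' @return An [areal_map()] with first index transverse, second axial.
#' @export
project_dxa <- function(bin, pixel_mm = 0.5, axis = c("y", "x"),
                        mask_partial = TRUE, psf_sigma_px = 0,
                        rim_erode_px = 1) {
  stopifnot(inherits(bin, "binary_volume"))
  axis <- match.arg(axis)
  if (pixel_mm < bin$spacing - 1e-12)
    stop_param("`pixel_mm` must be >= the voxel spacing")
  keepax <- if (axis == "y") 1L else 2L
  pl <- apply(bin$data, c(keepax, 3L), sum) * bin$spacing   # path length, mm
  f <- max(1L, as.integer(round(pixel_mm / bin$spacing)))
  pl <- block_mean_2d(pl, f)
  pl_raw <- pl
  if (psf_sigma_px > 0) {
    a3 <- array(pl, c(dim(pl), 1L))
    k <- gauss_kernel_1d(psf_sigma_px)
    for (axis_i in 1:2) a3 <- convolve_axis_reflect(a3, k, axis_i)
    pl <- a3[, , 1]
  }
  if (mask_partial) {
    # keep pixels whose full transverse extent lies inside the silhouette,
    # eroded by the margin (units: voxels)
    d <- dim(bin$data)
    rad <- min(d[1], d[2]) / 2 - rim_erode_px * f
    ctr <- d[keepax] / 2
    px_lo <- (seq_len(nrow(pl)) - 1) * f        # pixel transverse extent
    px_hi <- pmin(seq_len(nrow(pl)) * f, d[keepax])
    keep <- abs(px_lo - ctr) <= rad & abs(px_hi - ctr) <= rad
    pl[!keep, ] <- 0
  }
  g <- if (max(pl) > min(pl))
    round(255 * (pl - min(pl)) / (max(pl) - min(pl)))
  else pl * 0
  out <- areal_map(g, spacing = bin$spacing * f)
  attr(out, "pathlen_mm") <- pl_raw
  out
}

# Block mean of a matrix over f x f tiles (partial edge tiles averaged over
# their actual size).
block_mean_2d <- function(m, f) {
  if (f == 1L) return(m)
  d <- dim(m)
  d2 <- ceiling(d / f)
  out <- matrix(0, d2[1], d2[2])
  for (i in seq_len(d2[1])) for (j in seq_len(d2[2])) {
    ri <- ((i - 1) * f + 1):min(i * f, d[1])
    rj <- ((j - 1) * f + 1):min(j * f, d[2])
    out[i, j] <- mean(m[ri, rj])
  }
  out
}

#' Generate a synthetic fatigue dataset
#'
#' Samples fatigue lives log-uniformly over `n_range`, places SIB values on
#' the power law `sib = a * N_f^b` with lognormal multiplicative scatter
#' `10^eps, eps ~ N(0, sigma_log)`, and flags records whose sampled life
#' reaches the cycle ceiling as runouts (recorded at the ceiling). The
#' defaults emulate a 21-specimen campaign with a ceiling of 8e5 cycles.
#'
#' @param a law coefficient (> 0); default 450.
#' @param b law exponent; default -0.25 (SIB decreases with life).
#' @param n number of specimens (>= 3); default 21.
#' @param sigma_log scatter in log10 units; default 0.15.
#' @param ceiling runout ceiling in cycles; default 8e5.
#' @param n_range life sampling range (cycles); default c(1e3, 1.2e6).
#' @param seed RNG seed.
#' @return A [fatigue_records()] data frame.
#' @export
make_fatigue_dataset <- function(a = 450, b = -0.25, n = 21,
                                 sigma_log = 0.15, ceiling = 8e5,
                                 n_range = c(1e3, 1.2e6), seed = 1) {
  if (a <= 0) stop_param("`a` must be positive")
  if (n < 3) stop_param("need at least 3 specimens")
  with_seed(seed, {
    nf <- 10^runif(n, log10(n_range[1]), log10(n_range[2]))
    s <- a * nf^b * 10^rnorm(n, 0, sigma_log)
    ro <- nf >= ceiling
    nf[ro] <- ceiling
    fatigue_records(s, nf, ro)
  })
}

#' Generate a damage-condition phantom series
#'
#' The same underlying random field re-thresholded with a progressively
#' deeper weak band: one phantom per requested band reduction, emulating a
#' specimen re-scanned at successive fatigue interruptions as its failure
#' band erodes.
#'
#' @param spec a [phantom_spec()] whose `weak_band` gives the band center
#'   and half width.
#' @param reductions increasing BV/TV reductions, one per condition.
#' @return List of [binary_volume()]s.
#' @export
make_damage_series <- function(spec, reductions = c(0.2, 0.35, 0.5, 0.65)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$weak_band)) stop_param("spec must define a weak band")
  lapply(reductions, function(r) {
    s <- spec
    s$weak_band[3] <- r
    make_phantom(s)
  })
}
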