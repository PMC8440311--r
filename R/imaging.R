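#' Gaussian blur of an image volume
#'
#' Separable Gaussian smoothing used to attenuate reconstruction noise before
#' segmentation. The standard deviation is expressed in voxels (the imaging
#' protocol this mirrors uses sigma = 1.5). Boundaries are handled by
#' reflection, so a flat field is preserved exactly and total intensity is
#' conserved up to boundary truncation.
#'
#' @param vol a [gray_volume()].
#' @param sigma standard deviation of the Gaussian kernel, in voxels; >= 0.
#'   `sigma = 0` returns the input unchanged.
#' @return A [gray_volume()] of the same shape and spacing.
#' @export
gaussian_blur <- function(vol, sigma = 1.5) {
  stopifnot(inherits(vol, "gray_volume"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) stop_param("`sigma` must be a finite scalar >= 0")
  if (sigma == 0) return(vol)
  k <- gauss_kernel_1d(sigma)
  out <- vol$data
  for (axis in 1:3) out <- convolve_axis_reflect(out, k, axis)
  gray_volume(out, vol$spacing, vol$origin)
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along one axis of a 3D array, reflecting indices at the
# borders (edge voxel duplicated, scipy-style "reflect").
convolve_axis_reflect <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  out <- array(0, d)
  for (t in seq_along(k)) {
    off <- t - r - 1L
    idx <- seq_len(n) + off
    # fold repeatedly for kernels wider than the axis
    repeat {
      bad_lo <- idx < 1L
      bad_hi <- idx > n
      if (!any(bad_lo) && !any(bad_hi)) break
      idx[bad_lo] <- 1L - idx[bad_lo]
      idx[bad_hi] <- 2L * n + 1L - idx[bad_hi]
    }
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + k[t] * shifted
  }
  out
}

#' Otsu segmentation of a grayscale volume
#'
#' Rescales the volume linearly to 8-bit (0-255), builds the 256-bin
#' histogram, and selects the threshold that minimizes the intra-class
#' variance (equivalently, maximizes the between-class variance). Voxels
#' strictly above the threshold are classified as bone. When several
#' thresholds are exactly optimal (e.g. a two-level image) the midpoint of
#' the optimal range is taken, so the cut falls between the classes.
#'
#' @param vol a [gray_volume()] with at least two distinct intensities.
#' @param per_slice logical; if `TRUE`, threshold each axial (z) slice
#'   independently instead of globally. Default `FALSE` (global).
#' @return A list with `threshold` (8-bit level; a vector per slice when
#'   `per_slice`), `threshold_raw` (same cut on the original intensity
#'   scale), and `bin`, a [binary_volume()].
#' @export
otsu_threshold <- function(vol, per_slice = FALSE) {
  stopifnot(inherits(vol, "gray_volume"))
  x <- vol$data
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop_param("constant image: histogram is degenerate")
  g <- as.integer(round(255 * (x - lo) / (hi - lo)))
  dim(g) <- dim(x)
  if (!per_slice) {
    k <- otsu_level(as.vector(g))
    mask <- g > k
  } else {
    nz <- dim(g)[3]
    k <- integer(nz)
    mask <- array(FALSE, dim(g))
    for (s in seq_len(nz)) {
      gs <- g[, , s]
      if (min(gs) == max(gs)) {
        k[s] <- NA_integer_
        mask[, , s] <- FALSE
      } else {
        k[s] <- otsu_level(as.vector(gs))
        mask[, , s] <- gs > k[s]
      }
    }
  }
  list(threshold = k,
       threshold_raw = lo + k * (hi - lo) / 255,
       bin = binary_volume(mask, vol$spacing, vol$origin))
}

# Optimal 8-bit Otsu level by vectorized scan of all 256 candidates.
# Candidate k puts levels <= k in the background class.
otsu_level <- function(g) {
  p <- tabulate(g + 1L, nbins = 256L) / length(g)
  lev <- 0:255
  w0 <- cumsum(p)
  s1 <- cumsum(p * lev)
  s2 <- cumsum(p * lev^2)
  w1 <- 1 - w0
  mu0 <- ifelse(w0 > 0, s1 / w0, 0)
  mu1 <- ifelse(w1 > 0, (s1[256] - s1) / w1, 0)
  v0 <- ifelse(w0 > 0, s2 / w0 - mu0^2, 0)
  v1 <- ifelse(w1 > 0, (s2[256] - s2) / w1 - mu1^2, 0)
  intra <- w0 * v0 + w1 * v1
  intra[w0 <= 0 | w1 <= 0] <- Inf        # both classes must be non-empty
  best <- which(intra <= min(intra) + 1e-12) - 1L
  as.integer(floor(mean(best)))
}

#' Label connected components of a binary volume
#'
#' @param bin a [binary_volume()].
#' @param connectivity 6 (face neighbours) or 26 (faces, edges, corners).
#' @return Integer 3D array of component labels (0 = background), numbered in
#'   order of first occurrence in column-major order.
#' @export
label_components <- function(bin, connectivity = 26) {
  stopifnot(inherits(bin, "binary_volume"))
  lab <- label_components_cpp(as.logical(bin$data), dim(bin$data),
                              as.integer(connectivity))
  dim(lab) <- dim(bin$data)
  lab
}

#' Keep only the largest connected bone component
#'
#' Removes floating specks that would leave the finite-element system
#' singular. The default 26-connectivity preserves thin oblique trabeculae.
#' Size ties are broken deterministically: the component containing the
#' smallest (column-major) voxel index wins.
#'
#' @param bin a [binary_volume()] with at least one bone voxel.
#' @param connectivity 6 or 26 (default).
#' @return A [binary_volume()] with a single connected component.
#' @export
largest_component <- function(bin, connectivity = 26) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!any(bin$data)) stop_param("empty volume: no bone voxels")
  lab <- label_components(bin, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # labels are assigned in column-major scan order, so the smallest label
    # among the tied components is the one first reached
    first_idx <- vapply(biggest, function(l) min(which(lab == l)), numeric(1))
    biggest <- biggest[which.min(first_idx)]
  }
  binary_volume(lab == biggest[1], bin$spacing, bin$origin)
}
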