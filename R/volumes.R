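#' Grayscale image volume
#'
#' Container for a 3D scalar image with isotropic voxel spacing, the working
#' representation of a micro-CT reconstruction. Axes are (x, y, z) with z the
#' specimen (loading) axis; voxel `(1,1,1)` has its corner at `origin`.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing voxel edge length in mm (isotropic), > 0.
#' @param origin physical coordinates (mm) of the corner of voxel (1,1,1).
#' @return An object of class `gray_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
gray_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop_param("`data` must be a 3D array")
  if (!all(is.finite(data))) stop_param("intensities must be finite")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) stop_param("`spacing` must be a positive scalar (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "gray_volume")
}

#' Binary (segmented) volume
#'
#' Boolean 3D grid marking bone voxels, with the geometry of its source
#' [gray_volume()].
#'
#' @param data 3D logical array, `TRUE` = bone.
#' @param spacing voxel edge length (mm).
#' @param origin corner of voxel (1,1,1) in mm.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop_param("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop_param("mask must not contain NA")
  if (!is.numeric(spacing) || spacing <= 0)
    stop_param("`spacing` must be positive")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_volume")
}

#' Areal density map
#'
#' 2D scalar grid emulating a DXA projection. The first index is the
#' transverse direction, the second the specimen height (index 1 at the
#' clamped bottom). Gray values are 8-bit (0-255) by convention.
#'
#' @param data 2D numeric matrix of gray values, all >= 0.
#' @param spacing pixel edge length in mm (0.5 mm is the DXA-like default).
#' @return An object of class `areal_map`.
#' @export
areal_map <- function(data, spacing = 0.5) {
  data <- as.matrix(data)
  if (any(!is.finite(data)) || any(data < 0))
    stop_param("gray values must be finite and >= 0")
  if (!is.numeric(spacing) || spacing <= 0)
    stop_param("`spacing` must be positive")
  structure(list(data = data, spacing = spacing), class = "areal_map")
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gray_volume> %d x %d x %d voxels @ %.4g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %.4g mm, %d bone voxels (%.1f%%)\n",
              d[1], d[2], d[3], x$spacing, sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

#' @export
print.areal_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<areal_map> %d x %d pixels @ %.4g mm, gray range [%.4g, %.4g]\n",
              d[1], d[2], x$spacing, min(x$data), max(x$data)))
  invisible(x)
}
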