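#' Nominal cross-section area of a cylindrical core
#'
#' @param diameter_mm nominal core diameter (mm); 14 mm for the specimens
#'   these tools emulate.
#' @return Area in mm^2.
#' @export
nominal_area <- function(diameter_mm = 14) {
  if (diameter_mm <= 0) stop_param("diameter must be positive")
  pi * diameter_mm^2 / 4
}

#' Effective load-bearing area of a slice
#'
#' The nominal cross-section scaled by the bone volume fraction of the slice:
#' `A_eff = A_n * BV/TV`.
#'
#' @param a_n nominal area (mm^2), > 0.
#' @param bvtv bone volume fraction(s) in \[0, 1\].
#' @return Effective area(s), mm^2.
#' @export
effective_area <- function(a_n, bvtv) {
  if (!is.numeric(a_n) || a_n <= 0) stop_param("`a_n` must be positive")
  if (any(bvtv < 0 | bvtv > 1)) stop_param("`bvtv` must lie in [0, 1]")
  a_n * bvtv
}

#' BV/TV profile of a segmented core
#'
#' Bone volume fraction per slice along the specimen axis, and averaged over
#' consecutive stacks of slices (the profiles these emulate average every 8
#' image stacks). The total volume of each slice is the set of voxels inside
#' the nominal circular footprint of the core, not the bounding box: the
#' cores are cylindrical and a box denominator would bias BV/TV low.
#'
#' Height is normalized to \[0, 1\] with 0 at the clamped (bottom, slice 1)
#' face and 1 at the loaded (top) face.
#'
#' @param bin a [binary_volume()].
#' @param axis slice axis, one of `"x"`, `"y"`, `"z"` (default `"z"`, the
#'   loading axis).
#' @param stack_size number of consecutive slices averaged per stack
#'   (default 8); a final partial stack is averaged over its actual length.
#' @param a_n nominal cross-section area in mm^2 used for effective areas.
#'   Defaults to the area of the circular footprint actually used as TV.
#' @param footprint_diameter_mm diameter of the circular TV footprint;
#'   default is the transverse extent of the grid (inscribed circle).
#' @return A `morphometry_profile` list: `bvtv_per_slice`, `slice_heights`,
#'   `bvtv_per_stack`, `stack_heights`, `a_n`, `a_eff_per_slice`,
#'   `stack_size`.
#' @export
bvtv_profile <- function(bin, axis = "z", stack_size = 8, a_n = NULL,
                         footprint_diameter_mm = NULL) {
  stopifnot(inherits(bin, "binary_volume"))
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  d <- dim(bin$data)
  nslice <- d[ax]
  stack_size <- as.integer(stack_size)
  if (stack_size < 1L) stop_param("`stack_size` must be >= 1")
  if (stack_size > nslice)
    stop_param("`stack_size` exceeds the number of slices")

  tr <- setdiff(1:3, ax)                  # transverse axes
  h <- bin$spacing
  if (is.null(footprint_diameter_mm))
    footprint_diameter_mm <- min(d[tr]) * h
  rad <- footprint_diameter_mm / 2
  cx <- d[tr[1]] * h / 2
  cy <- d[tr[2]] * h / 2
  u <- (seq_len(d[tr[1]]) - 0.5) * h
  v <- (seq_len(d[tr[2]]) - 0.5) * h
  inside <- outer((u - cx)^2, (v - cy)^2, "+") <= rad^2
  n_tv <- sum(inside)
  if (n_tv == 0L) stop_param("footprint contains no voxels")

  bv <- vapply(seq_len(nslice), function(s) {
    sl <- switch(ax,
                 bin$data[s, , ],
                 bin$data[, s, ],
                 bin$data[, , s])
    sum(sl[inside])
  }, numeric(1))
  bvtv <- bv / n_tv

  if (is.null(a_n)) a_n <- pi * footprint_diameter_mm^2 / 4
  stack_id <- (seq_len(nslice) - 1L) %/% stack_size + 1L
  bvtv_stack <- as.numeric(tapply(bvtv, stack_id, mean))
  zh <- (seq_len(nslice) - 0.5) / nslice
  stack_h <- as.numeric(tapply(zh, stack_id, mean))

  structure(list(bvtv_per_slice = bvtv,
                 slice_heights = zh,
                 bvtv_per_stack = bvtv_stack,
                 stack_heights = stack_h,
                 a_n = a_n,
                 a_eff_per_slice = effective_area(a_n, bvtv),
                 stack_size = stack_size),
            class = "morphometry_profile")
}

#' @export
print.morphometry_profile <- function(x, ...) {
  cat(sprintf("<morphometry_profile> %d slices, BV/TV %.3f (min %.3f @ z=%.2f), A_n %.2f mm^2\n",
              length(x$bvtv_per_slice), mean(x$bvtv_per_slice),
              min(x$bvtv_per_slice),
              x$slice_heights[which.min(x$bvtv_per_slice)], x$a_n))
  invisible(x)
}

#' Write a morphometry profile to CSV
#'
#' Columns: `slice_index, z_norm, bvtv, a_eff_mm2`.
#'
#' @param profile a [bvtv_profile()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(profile, path) {
  stopifnot(inherits(profile, "morphometry_profile"))
  df <- data.frame(slice_index = seq_along(profile$bvtv_per_slice),
                   z_norm = profile$slice_heights,
                   bvtv = profile$bvtv_per_slice,
                   a_eff_mm2 = profile$a_eff_per_slice)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
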