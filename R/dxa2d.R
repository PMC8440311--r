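#' Calibrate the global elastic modulus from a compression test
#'
#' The global modulus is the test stress over the test strain, with the
#' stress referred to the weakest cross-section:
#' `E0 = (F / min(A_eff)) / (u / L_eff)`.
#'
#' @param f test force (N).
#' @param u crosshead displacement (mm).
#' @param l_eff effective specimen length (mm); 16 mm for the cores these
#'   tools emulate (distance between endcaps).
#' @param a_eff_min minimum effective area over the slices (mm^2), from
#'   micro-CT morphometry (see [bvtv_profile()]).
#' @return A `calibration_record` list with the inputs and `e0` (MPa).
#' @export
calibrate_e0 <- function(f, u, l_eff = 16, a_eff_min) {
  vals <- c(f = f, u = u, l_eff = l_eff, a_eff_min = a_eff_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_param("all calibration inputs must be positive and finite")
  structure(list(f = f, u = u, l_eff = l_eff, a_eff_min = a_eff_min,
                 e0 = (f / a_eff_min) / (u / l_eff)),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("<calibration_record> F = %g N, u = %g mm, Leff = %g mm, min(Aeff) = %g mm^2 -> E0 = %.4g MPa\n",
              x$f, x$u, x$l_eff, x$a_eff_min, x$e0))
  invisible(x)
}

# Linear mean-normalized gray -> modulus law on a vector of gray values.
gray_to_modulus_values <- function(g, e0, exponent = 1) {
  gw <- g^exponent
  e0 * gw / mean(gw)
}

#' Map gray levels to local elastic moduli
#'
#' Distributes the calibrated global modulus over the pixels of an areal map
#' in proportion to their gray level: `E_e = E0 * g_e / mean(g)`, the mean
#' taken over nonzero pixels. This is the unique linear law whose average
#' modulus reproduces the measured global modulus exactly. A power-law
#' alternative is exposed through `exponent`.
#'
#' @param map an [areal_map()] with at least one nonzero pixel.
#' @param e0 global elastic modulus (MPa), > 0.
#' @param exponent gray-level exponent (default 1, linear).
#' @return Numeric vector of moduli (MPa), one per nonzero pixel in
#'   column-major order; the pixel indices are attached as attribute
#'   `pixel_index`.
#' @export
gray_to_modulus <- function(map, e0, exponent = 1) {
  stopifnot(inherits(map, "areal_map"))
  if (e0 <= 0) stop_param("`e0` must be positive")
  idx <- which(map$data > 0)
  if (length(idx) == 0L) stop_param("all-zero map")
  mod <- gray_to_modulus_values(map$data[idx], e0, exponent)
  attr(mod, "pixel_index") <- idx
  mod
}

#' Equivalent thickness of the 2D model
#'
#' Chooses the out-of-plane thickness so that the 2D model's cross-section
#' (model width x thickness) equals the real cylindrical specimen's nominal
#' cross-section: `t = A_n / W`, with `W` the nonzero-column width of the
#' map.
#'
#' @param a_n nominal cross-section area (mm^2).
#' @param map an [areal_map()] with at least one nonzero column.
#' @return Thickness in mm.
#' @export
model_thickness <- function(a_n, map) {
  stopifnot(inherits(map, "areal_map"))
  if (a_n <= 0) stop_param("`a_n` must be positive")
  ncol_nz <- sum(apply(map$data > 0, 1, any))   # first index = transverse
  w <- ncol_nz * map$spacing
  if (w <= 0) stop_param("map has zero width")
  a_n / w
}

#' Strain index of bone (SIB) and per-row profile
#'
#' The SIB is the scaled peak compressive principal strain of the 2D model:
#' `SIB = max |eps_p_min| * 1e4` over all integration points. For the
#' per-section profile, the four integration-point values of each element
#' are averaged, then the maximum over each element row (cross-section) is
#' taken; the weakest row is the profile's argmax.
#'
#' @param res an [fe_solve()] result on a `quad_mesh`.
#' @return A `sib_result`: `sib` (dimensionless), `row_profile` (data frame
#'   `z_norm`, `sib` per element row), `weakest_row` (index from the clamped
#'   bottom) and `weakest_height` (normalized).
#' @export
sib <- function(res) {
  stopifnot(inherits(res, "fe_result"))
  mesh <- res$mesh
  if (!inherits(mesh, "quad_mesh"))
    stop_param("SIB is defined on 2D (quad) models")
  if (length(res$eps_p_min) == 0L) stop_param("empty result")
  vals <- abs(res$eps_p_min) * 1e4
  sib_global <- max(vals)
  elem_mean <- rowMeans(vals)
  rows <- arrayInd(mesh$pixel_index, mesh$dims)[, 2]
  prof <- tapply(elem_mean, rows, max)
  row_ids <- as.integer(names(prof))
  n_rows <- mesh$dims[2]
  z <- (row_ids - 0.5) / n_rows
  wk <- which.max(prof)
  structure(list(sib = sib_global,
                 row_profile = data.frame(row = row_ids, z_norm = z,
                                          sib = as.numeric(prof)),
                 weakest_row = row_ids[wk],
                 weakest_height = z[wk]),
            class = "sib_result")
}

#' @export
print.sib_result <- function(x, ...) {
  cat(sprintf("<sib_result> SIB = %.4g, weakest row %d (z = %.3f)\n",
              x$sib, x$weakest_row, x$weakest_height))
  invisible(x)
}

#' Write a SIB row profile to CSV
#'
#' Columns `z_norm, sib`.
#'
#' @param s a [sib()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sib_csv <- function(s, path) {
  stopifnot(inherits(s, "sib_result"))
  write.csv(s$row_profile[, c("z_norm", "sib")], path, row.names = FALSE)
  invisible(path)
}
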