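# End-to-end pipelines tying the modules together; these back the command
# line interface and the worked examples.

#' 2D DXA-based damage localization
#'
#' Full 2D chain on a segmented volume: project to a DXA-like areal map,
#' build the plane-strain model (gray-scaled moduli around the global
#' modulus, equivalent-section thickness), solve the compressive load case
#' and post-process the SIB row profile.
#'
#' @param bin a [binary_volume()] (segmented core).
#' @param e0 global elastic modulus (MPa).
#' @param f total compressive force (N).
#' @param pixel_mm areal-map pixel size; default twice the voxel spacing
#'   (a scaled-down DXA for miniature phantoms; use 0.5 for full-size
#'   specimens).
#' @param a_n nominal cross-section area (mm^2); default the area of the
#'   volume's inscribed circular footprint.
#' @param constraint bottom boundary condition (see [load_case()]).
#' @param psf_sigma_px detector point-spread blur passed to
#'   [project_dxa()]; the default 0.7 px suppresses single-pixel dropouts
#'   that a real detector could not resolve.
#' @return List: `map`, `mesh`, `result`, `sib` (a [sib()] result),
#'   `profile` (the [bvtv_profile()] of the volume).
#' @export
localize_damage_2d <- function(bin, e0 = 3029, f = 1200,
                               pixel_mm = 2 * bin$spacing, a_n = NULL,
                               constraint = "clamp", psf_sigma_px = 0.7) {
  stopifnot(inherits(bin, "binary_volume"))
  if (is.null(a_n)) {
    dia <- min(dim(bin$data)[1:2]) * bin$spacing
    a_n <- pi * dia^2 / 4
  }
  prof <- bvtv_profile(bin, a_n = a_n)
  map <- project_dxa(bin, pixel_mm = pixel_mm, psf_sigma_px = psf_sigma_px)
  thick <- model_thickness(a_n, map)
  mesh <- pixels_to_quad(map, e0 = e0, thickness = thick)
  res <- fe_solve(mesh, material_model(nu = 0.3),
                  load_case(f, constraint = constraint, distribution = "platen"))
  list(map = map, mesh = mesh, result = res, sib = sib(res), profile = prof)
}

#' 3D micro-FE damage localization
#'
#' Meshes a segmented volume (voxel-to-hexahedron, optional coarsening),
#' solves the uniform-modulus compressive load case and reports the
#' critical slice.
#'
#' @param bin a [binary_volume()].
#' @param e Young modulus (MPa).
#' @param f total compressive force (N).
#' @param coarsen voxel coarsening factor for the global model.
#' @param constraint bottom boundary condition.
#' @param nu Poisson ratio.
#' @return List: `mesh`, `result`, `critical` (a [critical_slice()] value),
#'   `quality` (the [mesh_quality()] report).
#' @export
localize_damage_3d <- function(bin, e = 3029, f = 1200, coarsen = 2,
                               constraint = "clamp", nu = 0.3) {
  stopifnot(inherits(bin, "binary_volume"))
  mesh <- voxels_to_hex(bin, coarsen = coarsen)
  res <- fe_solve(mesh, material_model(e = e, nu = nu),
                  load_case(f, constraint = constraint, distribution = "platen"))
  list(mesh = mesh, result = res, critical = critical_slice(res),
       quality = mesh_quality(mesh))
}

#' Global-to-trabecula sub-modeling chain
#'
#' Runs the two-level refinement on a solved global model: the force-driven
#' failure-band disk (sub-model I), the displacement-driven brick around its
#' peak (sub-model II), and the most-strained-trabecula report.
#'
#' @param bin the full-resolution [binary_volume()].
#' @param global a [localize_damage_3d()] result (or a list with `result`).
#' @param spec a [submodel_spec()].
#' @return List: `sub1`, `sub2` (both `submodel`s), `trabecula`
#'   (a [weakest_trabecula()] report).
#' @export
run_submodel_chain <- function(bin, global, spec = submodel_spec()) {
  sub1 <- extract_submodel_i(bin, global$result, spec)
  sub2 <- extract_submodel_ii(sub1, bin, spec)
  list(sub1 = sub1, sub2 = sub2,
       trabecula = weakest_trabecula(sub2$result))
}
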