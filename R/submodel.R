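#' Sub-model specification
#'
#' Geometry and drive of a refinement sub-model: a disk (axial slab) for the
#' failure-band model, or a brick for the trabecula-scale model.
#'
#' @param disk_height_mm slab height for sub-model I (default 4 mm).
#' @param brick_mm brick edge lengths (x, y, z) for sub-model II (default
#'   3 x 3 x 4 mm).
#' @param refine integer >= 1; sub-model voxels are the parent volume's
#'   full-resolution voxels subdivided by this factor (geometry is always
#'   re-extracted from the full-resolution volume, never from coarsened
#'   elements, so thinner trabeculae invisible to the global model are
#'   resolved).
#' @param drive `"force"` (default; top load + clamped bottom, as for the
#'   global model) or `"displacement"` (faces driven by the parent
#'   solution).
#' @return A `submodel_spec` list.
#' @export
submodel_spec <- function(disk_height_mm = 4, brick_mm = c(3, 3, 4),
                          refine = 1, drive = c("force", "displacement")) {
  refine <- as.integer(refine)
  if (refine < 1L) stop_param("`refine` must be >= 1")
  if (disk_height_mm <= 0 || any(brick_mm <= 0))
    stop_param("region sizes must be positive")
  structure(list(disk_height_mm = disk_height_mm,
                 brick_mm = rep(brick_mm, length.out = 3),
                 refine = refine, drive = match.arg(drive)),
            class = "submodel_spec")
}

# Trilinear interpolation of a nodal field of `parent` (hex_mesh) at
# physical points (k x 3). Points outside all parent elements are snapped to
# the nearest element within half an edge length, else an error is raised.
interp_displacement <- function(parent, u_nodes, points) {
  h <- parent$elem_size
  d <- parent$dims
  out <- matrix(0, nrow(points), 3)
  for (p in seq_len(nrow(points))) {
    x <- points[p, ]
    t0 <- (x - parent$origin) / h
    vi <- pmin(pmax(floor(t0) + 1, 1), d)
    e <- parent$elem_of_voxel[vi[1], vi[2], vi[3]]
    if (e == 0L) {
      # snap: search the 3^3 neighbourhood for the nearest bone element
      best <- 0L; best_d <- Inf
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        w <- vi + c(dx, dy, dz)
        if (any(w < 1L) || any(w > d)) next
        ee <- parent$elem_of_voxel[w[1], w[2], w[3]]
        if (ee == 0L) next
        lo <- parent$origin + (w - 1) * h
        gap <- pmax(lo - x, x - (lo + h), 0)
        dist <- sqrt(sum(gap^2))
        if (dist < best_d) { best_d <- dist; best <- ee; vi_best <- w }
      }
      if (best == 0L || best_d > h / 2 + 1e-9)
        stop_param("cut-boundary point intersects no parent element")
      e <- best; vi <- vi_best
    }
    lo <- parent$origin + (vi - 1) * h
    xi <- pmin(pmax(2 * (x - lo) / h - 1, -1), 1)
    N <- (1 + .hex_xi[, 1] * xi[1]) * (1 + .hex_xi[, 2] * xi[2]) *
      (1 + .hex_xi[, 3] * xi[3]) / 8
    out[p, ] <- colSums(N * u_nodes[parent$elements[e, ], , drop = FALSE])
  }
  out
}

# Extract the voxel range of `bin` covering [lo, hi] (mm) along each axis.
crop_volume <- function(bin, lo, hi) {
  h <- bin$spacing
  d <- dim(bin$data)
  i0 <- pmax(1L, as.integer(floor((lo - bin$origin) / h - 1e-9)) + 1L)
  i1 <- pmin(d, as.integer(ceiling((hi - bin$origin) / h + 1e-9)))
  if (any(i1 < i0)) stop_param("region lies outside the volume")
  sub <- bin$data[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  binary_volume(sub, h, bin$origin + (i0 - 1L) * h)
}

#' Sub-model I: refined failure-band disk
#'
#' Extracts an axial slab of the full-resolution segmented volume centered
#' on the global model's critical (most strained) slice, meshes it at the
#' requested refinement, and solves it with the same force-driven boundary
#' conditions as the global model: total compressive force at the top face,
#' clamped bottom face. A displacement-driven variant interpolates the
#' parent solution onto the slab's top and bottom faces instead.
#'
#' @param volume the full-resolution [binary_volume()] the global model was
#'   built from.
#' @param global_res the global [fe_solve()] result (on a `hex_mesh`).
#' @param spec a [submodel_spec()].
#' @param load [load_case()] for the force-driven solve (defaults to the
#'   global result's load).
#' @param ... passed to [fe_solve()].
#' @return A `submodel` list: `mesh`, `result`, `region` (z range, mm),
#'   `spec`.
#' @export
extract_submodel_i <- function(volume, global_res, spec = submodel_spec(),
                               load = NULL, ...) {
  stopifnot(inherits(volume, "binary_volume"),
            inherits(global_res, "fe_result"))
  axis <- global_res$axis
  zc <- global_res$peak$location[axis]
  half <- spec$disk_height_mm / 2
  ext_lo <- volume$origin
  ext_hi <- volume$origin + dim(volume$data) * volume$spacing
  lo <- ext_lo; hi <- ext_hi
  lo[axis] <- max(ext_lo[axis], zc - half)
  hi[axis] <- min(ext_hi[axis], zc + half)
  slab <- crop_volume(volume, lo, hi)
  if (!any(slab$data)) stop_param("slab contains no bone")
  slab <- subdivide_volume(slab, spec$refine)
  mesh <- voxels_to_hex(slab, coarsen = 1)
  if (is.null(load)) load <- global_res$load
  if (spec$drive == "force") {
    res <- fe_solve(mesh, material_model(e = scalar_modulus(global_res),
                                         nu = global_res$nu), load, ...)
  } else {
    res <- solve_displacement_driven(mesh, global_res,
                                     faces = c("min", "max"), axis = axis,
                                     ...)
  }
  structure(list(mesh = mesh, result = res,
                 region = rbind(lo = lo, hi = hi), spec = spec),
            class = "submodel")
}

scalar_modulus <- function(res) {
  e <- res$material$e
  if (is.null(e)) stop_param("parent result has no uniform modulus")
  e[1]
}

# Solve `mesh` with all dofs prescribed (from `parent_res`) on the selected
# boundary planes; interior unconstrained, no external load.
solve_displacement_driven <- function(mesh, parent_res, faces, axis,
                                      planes = NULL, tol = 1e-8,
                                      method = "auto") {
  nodes_fixed <- integer(0)
  tolh <- mesh$elem_size / 4
  if (!is.null(planes)) {
    for (ax in 1:3) {
      z <- mesh$nodes[, ax]
      nodes_fixed <- c(nodes_fixed,
                       which(abs(z - planes[1, ax]) < tolh |
                             abs(z - planes[2, ax]) < tolh))
    }
  } else {
    for (f in faces) nodes_fixed <- c(nodes_fixed, face_nodes(mesh, axis, f))
  }
  nodes_fixed <- sort(unique(nodes_fixed))
  if (length(nodes_fixed) == 0L) stop_param("no cut-boundary nodes found")
  # drop element components not anchored by any prescribed node
  mesh <- drop_unanchored(mesh, nodes_fixed)
  nodes_fixed <- mesh$renumbered_fixed
  uvals <- interp_displacement(parent_res$mesh, parent_res$u,
                               mesh$nodes[nodes_fixed, , drop = FALSE])
  fixed <- as.vector(t(cbind(3 * (nodes_fixed - 1L) + 1L,
                             3 * (nodes_fixed - 1L) + 2L,
                             3 * (nodes_fixed - 1L) + 3L)))
  fixed_vals <- as.vector(t(uvals))
  e_par <- scalar_modulus(parent_res)
  K <- assemble_stiffness(mesh, e_par, parent_res$nu)
  sol <- solve_constrained(K, numeric(nrow(K)), fixed, fixed_vals, tol,
                           method)
  res <- fe_postprocess(mesh, sol$u, parent_res$nu, axis)
  res$material <- material_model(e_par, parent_res$nu)
  res$info <- sol$info
  res$prescribed_nodes <- nodes_fixed
  res
}

# Remove element components that contain no prescribed node; returns the
# pruned mesh with `renumbered_fixed` giving the new indices of the kept
# prescribed nodes.
drop_unanchored <- function(mesh, nodes_fixed) {
  occ <- array(FALSE, mesh$dims)
  occ[mesh$voxel_index] <- TRUE
  lab <- label_components_cpp(as.logical(occ), mesh$dims, 6L)
  dim(lab) <- mesh$dims
  elem_lab <- lab[mesh$voxel_index]
  # element components touching a prescribed node
  node_elem <- rep(seq_len(nrow(mesh$elements)), times = 8L)
  node_id <- as.vector(mesh$elements)
  anchored <- unique(elem_lab[node_elem[node_id %in% nodes_fixed]])
  keep <- elem_lab %in% anchored
  if (all(keep)) {
    mesh$renumbered_fixed <- nodes_fixed
    return(mesh)
  }
  el <- mesh$elements[keep, , drop = FALSE]
  used <- sort(unique(as.vector(el)))
  mesh$elements <- matrix(match(el, used), nrow(el), ncol(el))
  mesh$nodes <- mesh$nodes[used, , drop = FALSE]
  mesh$voxel_index <- mesh$voxel_index[keep]
  eov <- array(0L, mesh$dims)
  eov[mesh$voxel_index] <- seq_len(nrow(mesh$elements))
  mesh$elem_of_voxel <- eov
  mesh$renumbered_fixed <- match(intersect(nodes_fixed, used), used)
  mesh
}

#' Sub-model II: trabecula-scale brick driven by sub-model I
#'
#' Extracts a brick around sub-model I's peak strain location from the
#' full-resolution volume, subdivides it by the requested refinement, and
#' prescribes on all its cut-boundary planes the displacement field
#' trilinearly interpolated from sub-model I's solution; the interior is
#' unconstrained. Element components not anchored by any prescribed node are
#' dropped (they would float).
#'
#' @param sub1 an [extract_submodel_i()] result.
#' @param volume the full-resolution [binary_volume()].
#' @param spec a [submodel_spec()]; `brick_mm` and `refine` are used.
#' @param ... passed to the constrained solver (`tol`, `method`).
#' @return A `submodel` list: `mesh`, `result`, `region`, `spec`.
#' @export
extract_submodel_ii <- function(sub1, volume, spec = sub1$spec, ...) {
  stopifnot(inherits(sub1, "submodel"), inherits(volume, "binary_volume"))
  ctr <- sub1$result$peak$location
  lo <- ctr - spec$brick_mm / 2
  hi <- ctr + spec$brick_mm / 2
  # clip to the parent (sub-model I) region so every cut node can be driven
  lo <- pmax(lo, sub1$region["lo", ])
  hi <- pmin(hi, sub1$region["hi", ])
  brick <- crop_volume(volume, lo, hi)
  if (!any(brick$data)) stop_param("brick contains no bone")
  brick <- subdivide_volume(brick, spec$refine)
  mesh <- voxels_to_hex(brick, coarsen = 1)
  planes <- rbind(brick$origin,
                  brick$origin + dim(brick$data) * brick$spacing)
  res <- solve_displacement_driven(mesh, sub1$result, faces = NULL,
                                   axis = sub1$result$axis, planes = planes,
                                   ...)
  structure(list(mesh = res$mesh %||% mesh, result = res,
                 region = rbind(lo = lo, hi = hi), spec = spec),
            class = "submodel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identify the most strained trabecula
#'
#' Segments the trabecula responsible for the peak compressive strain: the
#' face-connected set of elements, grown from the peak element, whose
#' element-averaged |minimum principal strain| is at least `frac` of the
#' peak. Reports the component, its principal (longest inertia) axis
#' orientation relative to the load axis, and the peak location.
#'
#' @param res a solved [fe_solve()] result (typically sub-model II's).
#' @param mesh the corresponding `hex_mesh` (default `res$mesh`).
#' @param frac strain fraction defining the trabecula (default 0.5).
#' @return A `trabecula_report`: `peak_strain` (signed), `component_id`,
#'   `n_elements`, `orientation` (degrees, 0 = aligned with the load axis,
#'   90 = perpendicular; NA when fewer than 3 elements), `location` (mm).
#' @export
weakest_trabecula <- function(res, mesh = res$mesh, frac = 0.5) {
  stopifnot(inherits(res, "fe_result"), inherits(mesh, "hex_mesh"))
  elem_abs <- rowMeans(abs(res$eps_p_min))
  pk <- res$peak$element
  thr <- frac * max(elem_abs)
  occ <- array(FALSE, mesh$dims)
  occ[mesh$voxel_index[elem_abs >= thr]] <- TRUE
  lab <- label_components_cpp(as.logical(occ), mesh$dims, 6L)
  dim(lab) <- mesh$dims
  comp <- lab[mesh$voxel_index[pk]]
  members <- which(lab[mesh$voxel_index] == comp & elem_abs >= thr)
  ai <- arrayInd(mesh$voxel_index[members], mesh$dims)
  centroids <- sweep((ai - 0.5) * mesh$elem_size, 2, mesh$origin, "+")
  orientation <- NA_real_
  if (length(members) >= 3L) {
    cv <- stats::cov(centroids)
    ev <- eigen(cv, symmetric = TRUE)
    axis_vec <- numeric(3); axis_vec[res$axis] <- 1
    cosang <- abs(sum(ev$vectors[, 1] * axis_vec))
    orientation <- acos(pmin(1, cosang)) * 180 / pi
  }
  structure(list(peak_strain = res$peak$value,
                 component_id = comp,
                 n_elements = length(members),
                 orientation = orientation,
                 location = res$peak$location),
            class = "trabecula_report")
}

#' @export
print.trabecula_report <- function(x, ...) {
  cat(sprintf("<trabecula_report> peak eps_p_min = %.4e, component %d (%d elements), orientation %.1f deg to load axis\n",
              x$peak_strain, x$component_id, x$n_elements, x$orientation))
  invisible(x)
}

#' @export
print.submodel <- function(x, ...) {
  cat(sprintf("<submodel> %d elements, peak eps_p_min = %.4e\n",
              nrow(x$mesh$elements), x$result$peak$value))
  invisible(x)
}
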