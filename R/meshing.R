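#' Convert a segmented volume to a hexahedral finite-element mesh
#'
#' Direct voxel-to-hexahedron conversion: one cube element per bone voxel,
#' with shared corner nodes deduplicated. This is the standard micro-FE
#' meshing route; every element is a perfect cube, so the mesh satisfies the
#' usual hexahedral quality thresholds (aspect ratio <= 3, corner angles
#' < 160 degrees, scaled Jacobian > 0.7) by construction.
#'
#' Optional coarsening groups `coarsen^3` voxels per element by majority
#' vote, with ties counted as bone (conservative for load paths). The mesh is
#' restricted to the largest face-connected set of elements: corner-only
#' contacts transmit no stiffness and would leave the system singular.
#'
#' @param bin a [binary_volume()] with at least one bone voxel.
#' @param coarsen integer >= 1, edge length of the voxel block merged into
#'   one element.
#' @return A `hex_mesh`: `nodes` (n x 3, mm), `elements` (m x 8, VTK corner
#'   ordering), `elem_size` (mm), `dims` (element-grid dimensions),
#'   `voxel_index` (linear index of each element in that grid),
#'   `elem_of_voxel` (inverse lookup array), `origin`.
#' @export
voxels_to_hex <- function(bin, coarsen = 1) {
  stopifnot(inherits(bin, "binary_volume"))
  coarsen <- as.integer(coarsen)
  if (coarsen < 1L) stop_param("`coarsen` must be an integer >= 1")
  if (!any(bin$data)) stop_param("empty bone set: nothing to mesh")

  occ <- bin$data
  h <- bin$spacing
  if (coarsen > 1L) {
    occ <- majority_downsample(occ, coarsen)
    h <- h * coarsen
  }
  # keep only the largest face-connected element set
  lab <- label_components_cpp(as.logical(occ), dim(occ), 6L)
  dim(lab) <- dim(occ)
  if (max(lab) == 0L) stop_param("empty bone set after coarsening")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  occ <- lab == keep

  d <- dim(occ)
  idx <- which(occ)
  ai <- arrayInd(idx, d)
  m <- nrow(ai)
  nxp <- d[1] + 1L; nyp <- d[2] + 1L
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  conn <- matrix(0L, m, 8L)
  for (k in 1:8) {
    a <- ai[, 1] + offs[k, 1]
    b <- ai[, 2] + offs[k, 2]
    cc <- ai[, 3] + offs[k, 3]
    conn[, k] <- a + nxp * ((b - 1L) + nyp * (cc - 1L))
  }
  used <- sort(unique(as.vector(conn)))
  elements <- matrix(match(conn, used), m, 8L)
  if (length(used) < 8L) stop_param("mesh has fewer than 8 nodes")
  ca <- (used - 1L) %% nxp
  cb <- ((used - 1L) %/% nxp) %% nyp
  ccc <- (used - 1L) %/% (nxp * nyp)
  nodes <- cbind(bin$origin[1] + ca * h,
                 bin$origin[2] + cb * h,
                 bin$origin[3] + ccc * h)
  eov <- array(0L, d)
  eov[idx] <- seq_len(m)
  structure(list(nodes = nodes, elements = elements, elem_size = h,
                 dims = d, voxel_index = idx, elem_of_voxel = eov,
                 origin = bin$origin),
            class = "hex_mesh")
}

# Majority-vote block downsampling of a logical array; ties count as bone.
# Partial edge blocks vote over the voxels they actually contain.
majority_downsample <- function(a, f) {
  d <- dim(a)
  d2 <- as.integer(ceiling(d / f))
  pad <- d2 * f - d
  if (any(pad > 0L)) {
    b <- array(FALSE, d2 * f)
    b[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    a <- b
  }
  x <- a * 1L
  dim(x) <- c(f, d2[1] * f * d2[2] * f * d2[3])
  x <- colSums(x)
  dim(x) <- c(d2[1], f, d2[2], f, d2[3])
  x <- aperm(x, c(2, 1, 3, 4, 5))
  dim(x) <- c(f, d2[1] * d2[2] * f * d2[3])
  x <- colSums(x)
  dim(x) <- c(d2[1], d2[2], f, d2[3])
  x <- aperm(x, c(3, 1, 2, 4))
  dim(x) <- c(f, d2[1] * d2[2] * d2[3])
  counts <- colSums(x)
  dim(counts) <- d2
  # per-block voxel totals (partial blocks at the high edges)
  lens <- lapply(1:3, function(ax) {
    l <- rep(f, d2[ax]); if (pad[ax] > 0L) l[d2[ax]] <- f - pad[ax]; l
  })
  denom <- outer(outer(lens[[1]], lens[[2]]), lens[[3]])
  out <- counts * 2 >= denom
  out & denom > 0
}

# Upsample a binary volume by integer factor s (each voxel -> s^3 voxels).
subdivide_volume <- function(bin, s) {
  s <- as.integer(s)
  if (s < 1L) stop_param("subdivision factor must be >= 1")
  if (s == 1L) return(bin)
  d <- dim(bin$data)
  a <- bin$data[rep(seq_len(d[1]), each = s),
                rep(seq_len(d[2]), each = s),
                rep(seq_len(d[3]), each = s)]
  binary_volume(a, bin$spacing / s, bin$origin)
}

#' Convert an areal map to a plane-strain quadrilateral mesh
#'
#' One square element per nonzero pixel, with the element edge equal to the
#' pixel spacing. Per-element elastic moduli are assigned from the gray
#' levels via [gray_to_modulus()], so the mean modulus over the mesh equals
#' the calibrated global modulus `e0`. Isolated pixels detached from the
#' main body are dropped (largest face-connected component rule).
#'
#' @param map an [areal_map()]; first index transverse, second axial
#'   (row 1 at the clamped bottom).
#' @param e0 global elastic modulus (MPa), > 0.
#' @param thickness out-of-plane model thickness (mm); see
#'   [model_thickness()].
#' @return A `quad_mesh`: `nodes` (n x 2, mm), `elements` (m x 4, VTK
#'   ordering), `elem_modulus` (MPa), `elem_size`, `thickness`, `dims`,
#'   `pixel_index`, `e0`.
#' @export
pixels_to_quad <- function(map, e0, thickness) {
  stopifnot(inherits(map, "areal_map"))
  if (e0 <= 0) stop_param("`e0` must be positive")
  if (thickness <= 0) stop_param("`thickness` must be positive")
  occ <- map$data > 0
  if (!any(occ)) stop_param("all-zero map: nothing to mesh")
  d3 <- c(dim(occ), 1L)
  lab <- label_components_cpp(as.logical(occ), d3, 6L)
  dim(lab) <- dim(occ)
  sizes <- tabulate(lab[lab > 0L])
  occ <- lab == which.max(sizes)

  d <- dim(occ)
  idx <- which(occ)
  ai <- arrayInd(idx, d)
  m <- nrow(ai)
  h <- map$spacing
  nxp <- d[1] + 1L
  offs <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  conn <- matrix(0L, m, 4L)
  for (k in 1:4) {
    a <- ai[, 1] + offs[k, 1]
    b <- ai[, 2] + offs[k, 2]
    conn[, k] <- a + nxp * (b - 1L)
  }
  used <- sort(unique(as.vector(conn)))
  elements <- matrix(match(conn, used), m, 4L)
  nodes <- cbind(((used - 1L) %% nxp) * h,
                 ((used - 1L) %/% nxp) * h)
  moduli <- gray_to_modulus_values(map$data[idx], e0)
  structure(list(nodes = nodes, elements = elements,
                 elem_modulus = moduli, elem_size = h,
                 thickness = thickness, dims = d, pixel_index = idx,
                 e0 = e0),
            class = "quad_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d elements, %d nodes, edge %.4g mm\n",
              nrow(x$elements), nrow(x$nodes), x$elem_size))
  invisible(x)
}

#' @export
print.quad_mesh <- function(x, ...) {
  cat(sprintf("<quad_mesh> %d elements, %d nodes, edge %.4g mm, t = %.3g mm, E0 = %.4g MPa\n",
              nrow(x$elements), nrow(x$nodes), x$elem_size, x$thickness,
              x$e0))
  invisible(x)
}

# corner -> adjacent-corner triples (VTK hexahedron), ordered so the edge
# triad has positive determinant on a right-handed element
.hex_corner_adj <- list(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
                        c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))
.hex_edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                    c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                    c(1, 5), c(2, 6), c(3, 7), c(4, 8))
.quad_corner_adj <- list(c(2, 4), c(3, 1), c(4, 2), c(1, 3))
.quad_edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))

#' Mesh quality report
#'
#' Computes the three quality measures customarily checked for image-based
#' hexahedral meshes: worst aspect ratio (longest/shortest element edge),
#' worst corner angle (degrees, from adjacent edge vectors), and worst
#' scaled Jacobian (corner edge-triad determinant divided by the edge-length
#' product). For an undistorted voxel mesh these are exactly 1, 90 degrees
#' and 1. Degenerate elements are reported (as non-finite entries), not
#' raised.
#'
#' @param mesh a `hex_mesh` or `quad_mesh`.
#' @return A `mesh_quality_report` list: `aspect_ratio`, `max_corner_angle`,
#'   `min_scaled_jacobian`.
#' @export
mesh_quality <- function(mesh) {
  if (inherits(mesh, "hex_mesh")) {
    adj <- .hex_corner_adj; edges <- .hex_edges; dim_n <- 3L
  } else if (inherits(mesh, "quad_mesh")) {
    adj <- .quad_corner_adj; edges <- .quad_edges; dim_n <- 2L
  } else stop_param("`mesh` must be a hex_mesh or quad_mesh")
  el <- mesh$elements
  nd <- mesh$nodes
  m <- nrow(el)
  nc <- ncol(el)
  # coordinates per corner: list of m x dim matrices
  X <- lapply(seq_len(nc), function(k) nd[el[, k], , drop = FALSE])

  elen <- sapply(seq_len(nrow(edges)), function(e) {
    v <- X[[edges[e, 2]]] - X[[edges[e, 1]]]
    sqrt(rowSums(v^2))
  })
  elen <- matrix(elen, nrow = m)
  ar <- apply(elen, 1, max) / apply(elen, 1, min)

  max_ang <- rep(-Inf, m)
  min_sj <- rep(Inf, m)
  for (c_i in seq_len(nc)) {
    es <- lapply(adj[[c_i]], function(a) X[[a]] - X[[c_i]])
    ln <- lapply(es, function(v) sqrt(rowSums(v^2)))
    np <- length(es)
    for (a in seq_len(np - 1)) for (b in seq((a + 1), np)) {
      cosang <- rowSums(es[[a]] * es[[b]]) / (ln[[a]] * ln[[b]])
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      max_ang <- pmax(max_ang, ang)
    }
    if (dim_n == 3L) {
      e1 <- es[[1]]; e2 <- es[[2]]; e3 <- es[[3]]
      det3 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
              e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
              e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
      sj <- det3 / (ln[[1]] * ln[[2]] * ln[[3]])
    } else {
      e1 <- es[[1]]; e2 <- es[[2]]
      sj <- (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / (ln[[1]] * ln[[2]])
    }
    min_sj <- pmin(min_sj, sj)
  }
  structure(list(aspect_ratio = max(ar),
                 max_corner_angle = max(max_ang),
                 min_scaled_jacobian = min(min_sj)),
            class = "mesh_quality_report")
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat(sprintf("<mesh_quality> AR = %.3f, max angle = %.1f deg, min scaled J = %.3f\n",
              x$aspect_ratio, x$max_corner_angle, x$min_scaled_jacobian))
  invisible(x)
}
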