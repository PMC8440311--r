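# Element-level machinery for axis-aligned box elements: trilinear (8-node)
# hexahedra with 2x2x2 Gauss integration and bilinear (4-node) plane-strain
# quadrilaterals with 2x2 integration. Element dof ordering is interleaved
# per node: (u1x, u1y[, u1z], u2x, ...), nodes in VTK corner order.

.hex_xi <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
                 c(-1, -1, 1, 1, -1, -1, 1, 1),
                 c(-1, -1, -1, -1, 1, 1, 1, 1))
.quad_xi <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))

# Gauss points (natural coordinates) for the 2-point rule, unit weights.
gauss_points <- function(dim) {
  g <- 1 / sqrt(3)
  if (dim == 3L) .hex_xi * g else .quad_xi * g
}

# Shape-function gradients w.r.t. natural coordinates at point `xi`.
# Returns nnode x dim matrix.
shape_grad <- function(dim, xi) {
  if (dim == 3L) {
    nd <- .hex_xi
    cbind(nd[, 1] * (1 + nd[, 2] * xi[2]) * (1 + nd[, 3] * xi[3]),
          nd[, 2] * (1 + nd[, 1] * xi[1]) * (1 + nd[, 3] * xi[3]),
          nd[, 3] * (1 + nd[, 1] * xi[1]) * (1 + nd[, 2] * xi[2])) / 8
  } else {
    nd <- .quad_xi
    cbind(nd[, 1] * (1 + nd[, 2] * xi[2]),
          nd[, 2] * (1 + nd[, 1] * xi[1])) / 4
  }
}

# Strain-displacement matrix for an axis-aligned box of edge length(s) h.
# 3D rows: (exx, eyy, ezz, gxy, gyz, gxz); 2D rows: (exx, eyy, gxy).
# Engineering shear convention.
bmat_box <- function(dim, h, xi) {
  h <- rep(h, length.out = dim)
  dn <- shape_grad(dim, xi)
  dn <- sweep(dn, 2, 2 / h, "*")          # d/dx = d/dxi * 2/h
  nn <- nrow(dn)
  if (dim == 3L) {
    B <- matrix(0, 6, 3 * nn)
    for (i in seq_len(nn)) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- dn[i, 1]
      B[2, c0 + 2] <- dn[i, 2]
      B[3, c0 + 3] <- dn[i, 3]
      B[4, c0 + 1] <- dn[i, 2]; B[4, c0 + 2] <- dn[i, 1]
      B[5, c0 + 2] <- dn[i, 3]; B[5, c0 + 3] <- dn[i, 2]
      B[6, c0 + 1] <- dn[i, 3]; B[6, c0 + 3] <- dn[i, 1]
    }
  } else {
    B <- matrix(0, 3, 2 * nn)
    for (i in seq_len(nn)) {
      c0 <- 2 * (i - 1)
      B[1, c0 + 1] <- dn[i, 1]
      B[2, c0 + 2] <- dn[i, 2]
      B[3, c0 + 1] <- dn[i, 2]; B[3, c0 + 2] <- dn[i, 1]
    }
  }
  B
}

# Isotropic elasticity matrices (unit Young modulus; scale by E).
dmat_iso3d <- function(nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

dmat_plane_strain <- function(nu) {
  f <- 1 / ((1 + nu) * (1 - 2 * nu))
  f * rbind(c(1 - nu, nu, 0),
            c(nu, 1 - nu, 0),
            c(0, 0, (1 - 2 * nu) / 2))
}

# Unit-modulus element stiffness for an axis-aligned box. `thickness` is
# used in 2D (plane strain) only.
ke_box <- function(dim, h, nu, thickness = 1) {
  h <- rep(h, length.out = dim)
  D <- if (dim == 3L) dmat_iso3d(nu) else dmat_plane_strain(nu)
  detj <- prod(h) / 2^dim
  if (dim == 2L) detj <- detj * thickness
  gp <- gauss_points(dim)
  nde <- dim * nrow(gp)
  Ke <- matrix(0, nde, nde)
  for (g in seq_len(nrow(gp))) {
    B <- bmat_box(dim, h, gp[g, ])
    Ke <- Ke + t(B) %*% D %*% B * detj
  }
  (Ke + t(Ke)) / 2
}

#' Material model
#'
#' Isotropic linear-elastic material. The bone-tissue default Poisson ratio
#' is 0.3; the Young modulus is typically calibrated from the experimental
#' force-displacement response (see [calibrate_e0()]).
#'
#' @param e Young modulus in MPa (scalar, or one value per element). May be
#'   `NULL` for meshes carrying their own per-element moduli.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @return A `material_model` list.
#' @export
material_model <- function(e = NULL, nu = 0.3) {
  if (!is.null(e) && any(e <= 0)) stop_param("`e` must be positive")
  if (nu <= -1 || nu >= 0.5) stop_param("`nu` must lie in (-1, 0.5)")
  structure(list(e = e, nu = nu), class = "material_model")
}

#' Compressive load case
#'
#' The uniaxial-test loading pattern: a total compressive force applied along
#' the specimen axis, shared equally among the loaded-face (top) nodes, with
#' the bottom face either fully clamped (the experimental endcap condition)
#' or on axial rollers (the idealized condition used for analytic
#' validation; rigid-body modes are pinned at two bottom nodes, which carry
#' no force in a uniform field).
#'
#' @param f total compressive force magnitude in N (> 0).
#' @param constraint `"clamp"` (default) or `"roller"`.
#' @param axis loading axis index; default the mesh's last coordinate
#'   (height).
#' @param distribution `"equal"` (default): the force is divided equally
#'   among the loaded-face nodes, the plain reading of a uniformly
#'   distributed nodal load; `"consistent"`: tributary-area weighting
#'   (corner/edge face nodes carry their element-face share), the exact
#'   lumping of a uniform traction — use this for patch-test validation,
#'   where it reproduces a uniform stress state to machine precision;
#'   `"platen"`: the loaded face moves as a rigid platen (uniform axial
#'   displacement, lateral dofs free), scaled so the total transmitted
#'   force equals `f` — this emulates a specimen glued into a rigid endcap
#'   and avoids spurious strain spikes where a nodal force would be pushed
#'   into a locally compliant boundary element.
#' @return A `load_case` list.
#' @export
load_case <- function(f = 1200, constraint = c("clamp", "roller"),
                      axis = NULL,
                      distribution = c("equal", "consistent", "platen")) {
  if (!is.numeric(f) || f <= 0) stop_param("`f` must be a positive force (N)")
  structure(list(f = f, constraint = match.arg(constraint), axis = axis,
                 distribution = match.arg(distribution)),
            class = "load_case")
}
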