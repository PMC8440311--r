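# Sparse linear-elastic solver for voxel/pixel meshes. All elements of a
# mesh are congruent axis-aligned boxes, so a single unit-modulus element
# stiffness serves the whole mesh, scaled per element by its Young modulus.

mesh_dim <- function(mesh) if (inherits(mesh, "hex_mesh")) 3L else 2L

# Element dof table, m x (dim * nnode), interleaved per node.
elem_dofs <- function(mesh) {
  dim_n <- mesh_dim(mesh)
  el <- mesh$elements
  m <- nrow(el)
  nde <- dim_n * ncol(el)
  ED <- matrix(0L, m, nde)
  for (k in seq_len(ncol(el))) for (c_i in seq_len(dim_n))
    ED[, dim_n * (k - 1L) + c_i] <- dim_n * (el[, k] - 1L) + c_i
  ED
}

# Global stiffness (dgCMatrix) from per-element Young moduli.
assemble_stiffness <- function(mesh, e_elem, nu) {
  dim_n <- mesh_dim(mesh)
  thick <- if (dim_n == 2L) mesh$thickness else 1
  KeU <- ke_box(dim_n, mesh$elem_size, nu, thick)
  ED <- elem_dofs(mesh)
  m <- nrow(ED)
  nde <- ncol(ED)
  e_elem <- rep(e_elem, length.out = m)
  I <- as.vector(ED[, rep(seq_len(nde), times = nde)])
  J <- as.vector(ED[, rep(seq_len(nde), each = nde)])
  X <- as.vector(outer(e_elem, as.vector(KeU)))
  ndof <- dim_n * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(ndof, ndof))
}

# Jacobi-preconditioned conjugate gradients for SPD systems.
pcg_solve <- function(K, b, tol = 1e-8, maxit = 50000L) {
  M <- Matrix::diag(K)
  if (any(M <= 0)) stop_param("non-positive diagonal: system is singular ",
                              "(floating component?)")
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(list(x = numeric(length(b)), iterations = 0L,
                           residual = 0, history = numeric(0)))
  x <- numeric(length(b))
  r <- b
  z <- r / M
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bn
    if (it %% 50L == 0L || res <= tol) hist <- c(hist, res)
    if (res <= tol)
      return(list(x = x, iterations = it, residual = res, history = hist))
    z <- r / M
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop_param(sprintf(
    "PCG did not converge in %d iterations (relative residual %.3e); %s",
    maxit, res, paste0("history tail: ",
                       paste(signif(tail(hist, 5), 3), collapse = " "))))
}

# Core reduced-system solve with prescribed dofs.
# fixed: integer dof indices; fixed_vals: prescribed values (same length).
solve_constrained <- function(K, f_ext, fixed, fixed_vals, tol, method,
                              dense_threshold = 500L) {
  ndof <- nrow(K)
  free <- setdiff(seq_len(ndof), fixed)
  if (length(free) == 0L) stop_param("no free degrees of freedom")
  u <- numeric(ndof)
  u[fixed] <- fixed_vals
  rhs <- f_ext[free]
  if (any(fixed_vals != 0))
    rhs <- rhs - as.numeric(K[free, fixed, drop = FALSE] %*% fixed_vals)
  Kff <- K[free, free]
  if (method == "auto")
    method <- if (length(free) <= dense_threshold) "dense" else "pcg"
  info <- list(method = method, iterations = NA_integer_, residual = NA_real_)
  if (method == "dense") {
    uf <- solve(as.matrix(Matrix::forceSymmetric(Kff)), rhs)
    info$residual <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2)) /
      max(sqrt(sum(rhs^2)), .Machine$double.eps)
  } else {
    sol <- pcg_solve(Kff, rhs, tol = tol)
    uf <- sol$x
    info$iterations <- sol$iterations
    info$residual <- sol$residual
  }
  u[free] <- as.numeric(uf)
  list(u = u, free = free, info = info)
}

# Identify face nodes along `axis`: nodes whose coordinate is within half an
# element edge of the extreme.
face_nodes <- function(mesh, axis, which_face = c("min", "max")) {
  which_face <- match.arg(which_face)
  z <- mesh$nodes[, axis]
  tol <- mesh$elem_size / 2
  if (which_face == "min") which(z < min(z) + tol) else which(z > max(z) - tol)
}

# Tributary-area weights over the loaded-face nodes: each element face on
# the load plane contributes an equal share to its corner nodes (all voxel
# faces are congruent squares). Returns weights summing to 1, aligned with
# `top`.
load_face_weights <- function(mesh, top, axis) {
  dim_n <- mesh_dim(mesh)
  on_top <- logical(nrow(mesh$nodes))
  on_top[top] <- TRUE
  el <- mesh$elements
  per_face <- if (dim_n == 3L) 4L else 2L
  counts <- numeric(nrow(mesh$nodes))
  face_nodes_el <- apply(el, 1, function(e) {
    f <- e[on_top[e]]
    if (length(f) == per_face) f else NULL
  }, simplify = FALSE)
  for (f in face_nodes_el) if (!is.null(f))
    counts[f] <- counts[f] + 1
  w <- counts[top]
  if (sum(w) == 0) stop_param("no element face lies on the load plane")
  w / sum(w)
}

# Fixed dofs for the load case; returns integer vector.
constraint_dofs <- function(mesh, load, axis) {
  dim_n <- mesh_dim(mesh)
  bottom <- face_nodes(mesh, axis, "min")
  if (length(bottom) == 0L) stop_param("constraint face is empty")
  if (load$constraint == "clamp") {
    as.vector(outer(seq_len(dim_n), dim_n * (bottom - 1L), "+"))
  } else {
    fixed <- dim_n * (bottom - 1L) + axis
    lateral <- setdiff(seq_len(dim_n), axis)
    # pin remaining rigid modes without constraining lateral expansion:
    # all lateral dofs at the lexicographically first bottom node; in 3D
    # additionally the second lateral dof at the bottom node farthest along
    # the first lateral axis (the in-plane rotation it fixes is strain-free)
    xy <- mesh$nodes[bottom, lateral, drop = FALSE]
    ordb <- do.call(order, as.data.frame(xy))
    a <- bottom[ordb[1]]
    fixed <- c(fixed, dim_n * (a - 1L) + lateral)
    if (dim_n == 3L && length(bottom) > 1L) {
      dx <- abs(xy[, 1] - xy[ordb[1], 1])
      if (max(dx) > 0) {
        b <- bottom[which.max(dx)]
        fixed <- c(fixed, dim_n * (b - 1L) + lateral[2])
      }
    }
    fixed
  }
}

#' Solve a linear-elastic finite-element model
#'
#' Assembles and solves the compressive load case on a voxel (`hex_mesh`) or
#' pixel (`quad_mesh`) model: the total force is divided equally among the
#' top-face nodes and the bottom face is clamped (or put on axial rollers).
#' Quadrilaterals are plane-strain with 2x2 Gauss integration; hexahedra are
#' trilinear bricks with full 2x2x2 integration (reduced integration without
#' hourglass control is not stable in a self-contained solver, and locking
#' is negligible for voxel meshes at trabecular resolution). The reduced
#' system is solved with Jacobi-preconditioned conjugate gradients, or by
#' dense factorization below 500 free degrees of freedom.
#'
#' @param mesh a `hex_mesh` or `quad_mesh` (see [voxels_to_hex()],
#'   [pixels_to_quad()]).
#' @param mat a [material_model()]. For `quad_mesh`es carrying per-element
#'   moduli, only `nu` is used; for `hex_mesh`es `e` may be a scalar or one
#'   value per element.
#' @param load a [load_case()].
#' @param tol relative-residual convergence tolerance (default 1e-8).
#' @param method `"auto"` (default), `"pcg"` or `"dense"`.
#' @return An `fe_result`: nodal displacements `u` (mm), integration-point
#'   strain tensors `eps_ip`, minimum principal strain `eps_p_min` per
#'   integration point, `peak` (value, element, integration point, physical
#'   location in mm), `stiffness` (N/mm), `reaction_sum`, solver `info`,
#'   and the `mesh` and inputs for downstream post-processing.
#' @export
fe_solve <- function(mesh, mat = material_model(), load = load_case(),
                     tol = 1e-8, method = c("auto", "pcg", "dense")) {
  method <- match.arg(method)
  dim_n <- mesh_dim(mesh)
  axis <- if (is.null(load$axis)) dim_n else load$axis
  e_elem <- if (inherits(mesh, "quad_mesh") && !is.null(mesh$elem_modulus))
    mesh$elem_modulus else mat$e
  if (is.null(e_elem)) stop_param("no Young modulus: supply `mat$e` or a ",
                                  "mesh with per-element moduli")
  nu <- mat$nu

  K <- assemble_stiffness(mesh, e_elem, nu)
  top <- face_nodes(mesh, axis, "max")
  if (length(top) == 0L) stop_param("load face is empty")
  distribution <- load$distribution %||% "equal"
  f_ext <- numeric(nrow(K))
  fixed <- constraint_dofs(mesh, load, axis)
  if (distribution == "platen") {
    # rigid-endcap loading: prescribe a unit axial platen displacement,
    # then scale the linear solution to the target total force
    top_ax <- dim_n * (top - 1L) + axis
    fixed_all <- c(fixed, setdiff(top_ax, fixed))
    vals <- c(numeric(length(fixed)),
              rep(-1, length(setdiff(top_ax, fixed))))
    sol <- solve_constrained(K, f_ext, fixed_all, vals, tol, method)
    f_tot <- abs(sum((as.numeric(K %*% sol$u))[top_ax]))
    if (f_tot <= 0) stop_param("platen transmits no force")
    sol$u <- sol$u * (load$f / f_tot)
  } else {
    if (distribution == "equal") {
      f_ext[dim_n * (top - 1L) + axis] <- -load$f / length(top)
    } else {
      w <- load_face_weights(mesh, top, axis)
      f_ext[dim_n * (top - 1L) + axis] <- -load$f * w
    }
    f_ext[fixed] <- 0
    sol <- solve_constrained(K, f_ext, fixed, numeric(length(fixed)),
                             tol, method)
  }
  res <- fe_postprocess(mesh, sol$u, nu, axis)
  res$load <- load
  res$material <- material_model(if (length(unique(e_elem)) == 1L)
    e_elem[1] else e_elem, nu)
  # mean axial displacement magnitude of the loaded face -> model stiffness
  u_mat <- matrix(sol$u, ncol = dim_n, byrow = TRUE)
  mean_top <- mean(abs(u_mat[top, axis]))
  if (mean_top == 0) stop_param("zero top-face displacement")
  res$stiffness <- load$f / mean_top
  # reaction balance at the constrained face
  r_all <- as.numeric(K %*% sol$u) - f_ext
  bottom <- face_nodes(mesh, axis, "min")
  res$reaction_sum <- sum(r_all[dim_n * (bottom - 1L) + axis])
  res$info <- sol$info
  res
}

# Strain recovery and peak extraction shared by force- and
# displacement-driven solves.
fe_postprocess <- function(mesh, u, nu, axis) {
  dim_n <- mesh_dim(mesh)
  ED <- elem_dofs(mesh)
  m <- nrow(ED)
  gp <- gauss_points(dim_n)
  ngp <- nrow(gp)
  ncomp <- if (dim_n == 3L) 6L else 3L
  Ue <- matrix(u[ED], m, ncol(ED))
  eps_ip <- array(0, c(m, ngp, ncomp))
  for (g in seq_len(ngp)) {
    B <- bmat_box(dim_n, mesh$elem_size, gp[g, ])
    eps_ip[, g, ] <- Ue %*% t(B)
  }
  eps_p_min <- matrix(0, m, ngp)
  for (g in seq_len(ngp)) {
    E <- eps_ip[, g, , drop = TRUE]
    if (m == 1L) E <- matrix(E, 1L)
    eps_p_min[, g] <- if (dim_n == 3L)
      eig3_min(E[, 1], E[, 2], E[, 3], E[, 4] / 2, E[, 5] / 2, E[, 6] / 2)
    else
      plane_strain_min(E[, 1], E[, 2], E[, 3])
  }
  pk <- which.max(abs(eps_p_min))
  pk_elem <- (pk - 1L) %% m + 1L
  pk_gp <- (pk - 1L) %/% m + 1L
  centroid <- colMeans(matrix(mesh$nodes[mesh$elements[pk_elem, ], ],
                              ncol = dim_n))
  loc <- centroid + gp[pk_gp, ] * mesh$elem_size / 2
  u_mat <- matrix(u, ncol = dim_n, byrow = TRUE)
  structure(list(u = u_mat, eps_ip = eps_ip, eps_p_min = eps_p_min,
                 peak = list(value = eps_p_min[pk_elem, pk_gp],
                             abs_value = abs(eps_p_min[pk_elem, pk_gp]),
                             element = pk_elem, ip = pk_gp, location = loc),
                 axis = axis, mesh = mesh, nu = nu),
            class = "fe_result")
}

# Smallest eigenvalue of symmetric 3x3 tensors, vectorized (trigonometric
# closed form; Cardano on the deviatoric invariants).
eig3_min <- function(a11, a22, a33, a12, a23, a13) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  scale <- pmax(abs(a11), abs(a22), abs(a33), abs(a12), abs(a23), abs(a13))
  out <- q
  nz <- p > 1e-14 * pmax(scale, 1e-300)
  if (any(nz)) {
    pn <- p[nz]
    b11 <- (a11[nz] - q[nz]) / pn; b22 <- (a22[nz] - q[nz]) / pn
    b33 <- (a33[nz] - q[nz]) / pn
    b12 <- a12[nz] / pn; b23 <- a23[nz] / pn; b13 <- a13[nz] / pn
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(1, pmax(-1, detb / 2))
    phi <- acos(r) / 3
    out[nz] <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
  }
  out
}

# Minimum principal strain of a plane-strain state (the zero out-of-plane
# strain is itself a principal value).
plane_strain_min <- function(exx, eyy, gxy) {
  ctr <- (exx + eyy) / 2
  rad <- sqrt(((exx - eyy) / 2)^2 + (gxy / 2)^2)
  pmin(ctr - rad, 0)
}

#' Minimum principal strain of a strain tensor
#'
#' Smallest eigenvalue of a symmetric strain tensor — the most negative
#' principal strain under compression, the field quantity monitored for
#' damage localization.
#'
#' @param eps a symmetric 3x3 (or 2x2) matrix of tensor strain components.
#' @return The smallest eigenvalue (dimensionless).
#' @export
principal_min <- function(eps) {
  if (!is.matrix(eps) || nrow(eps) != ncol(eps) ||
      !nrow(eps) %in% c(2L, 3L) || any(!is.finite(eps)))
    stop_param("`eps` must be a finite 2x2 or 3x3 matrix")
  if (max(abs(eps - t(eps))) > 1e-8 * max(abs(eps), 1e-300))
    stop_param("`eps` must be symmetric")
  if (nrow(eps) == 3L)
    eig3_min(eps[1, 1], eps[2, 2], eps[3, 3], eps[1, 2], eps[2, 3],
             eps[1, 3])
  else {
    ctr <- (eps[1, 1] + eps[2, 2]) / 2
    rad <- sqrt(((eps[1, 1] - eps[2, 2]) / 2)^2 + eps[1, 2]^2)
    ctr - rad
  }
}

#' Model stiffness
#'
#' Total applied force divided by the mean axial displacement magnitude of
#' the loaded face — the numerical counterpart of the experimental
#' force/displacement stiffness used for model validation.
#'
#' @param res an [fe_solve()] result.
#' @return Stiffness in N/mm.
#' @export
model_stiffness <- function(res) {
  stopifnot(inherits(res, "fe_result"))
  if (is.null(res$stiffness) || !is.finite(res$stiffness))
    stop_param("result carries no stiffness (displacement-driven solve?)")
  res$stiffness
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("<fe_result> %d elements, peak eps_p_min = %.4e at (%s) mm",
              nrow(x$eps_p_min), x$peak$value,
              paste(signif(x$peak$location, 4), collapse = ", ")))
  if (!is.null(x$stiffness))
    cat(sprintf(", stiffness = %.4g N/mm", x$stiffness))
  cat("\n")
  invisible(x)
}
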