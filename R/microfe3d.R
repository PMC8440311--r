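#' Run the damage-condition series of 3D global models
#'
#' Solves one 3D model per interrupted-fatigue condition (pre-fatigue,
#' interruptions, post-fatigue), each with its own mesh (conditions are
#' re-scanned and re-segmented independently; no mesh morphing) and its own
#' experimentally measured uniform Young modulus, under the shared
#' compressive load case (1200 N at the top surface, clamped bottom, by
#' default). A condition whose solve fails is recorded as an error and the
#' remaining conditions still run.
#'
#' @param meshes list of `hex_mesh`es, one per condition.
#' @param e_values Young moduli (MPa), one per condition.
#' @param load a [load_case()] shared by all conditions.
#' @param n_cycles cycle counts per condition (for labeling/ordering).
#' @param labels condition names; defaults to
#'   pre-fatigue / interrupted_k / post-fatigue.
#' @param nu Poisson ratio (default 0.3).
#' @return A `condition_series`: `labels`, `e_values`, `n_cycles`, `results`
#'   (list of `fe_result` or error condition), and `metrics`, a
#'   `damage_metrics` list with `peak_abs_eps_min`, `pct_change_vs_pre`,
#'   `critical_slice` and `critical_z_norm` per condition.
#' @export
run_series <- function(meshes, e_values, load = load_case(1200),
                       n_cycles = seq_along(meshes) - 1, labels = NULL,
                       nu = 0.3) {
  k <- length(meshes)
  if (length(e_values) != k || length(n_cycles) != k)
    stop_param("one mesh, modulus and cycle count per condition")
  if (is.null(labels)) {
    labels <- if (k >= 2)
      c("pre-fatigue",
        if (k > 2) paste0("interrupted_", seq_len(k - 2)),
        "post-fatigue")
    else "pre-fatigue"
  }
  if (anyDuplicated(labels)) stop_param("labels must be unique")
  ord <- order(n_cycles)
  if (!identical(ord, seq_len(k)))
    stop_param("conditions must be ordered by cycle count")
  results <- vector("list", k)
  names(results) <- labels
  for (i in seq_len(k)) {
    results[[i]] <- tryCatch(
      fe_solve(meshes[[i]], material_model(e = e_values[i], nu = nu), load),
      error = function(e) e)
  }
  ok <- !vapply(results, inherits, logical(1), "error")
  peaks <- rep(NA_real_, k)
  cs <- rep(NA_integer_, k)
  cz <- rep(NA_real_, k)
  for (i in which(ok)) {
    peaks[i] <- results[[i]]$peak$abs_value
    sl <- critical_slice(results[[i]])
    cs[i] <- sl$slice
    cz[i] <- sl$z_norm
  }
  pct <- if (ok[1]) vapply(seq_len(k), function(i)
    if (ok[i]) pct_change(peaks[1], peaks[i]) else NA_real_, numeric(1))
  else rep(NA_real_, k)
  structure(list(labels = labels, e_values = e_values, n_cycles = n_cycles,
                 results = results,
                 metrics = structure(list(peak_abs_eps_min = peaks,
                                          pct_change_vs_pre = pct,
                                          critical_slice = cs,
                                          critical_z_norm = cz),
                                     class = "damage_metrics")),
            class = "condition_series")
}

#' @export
print.condition_series <- function(x, ...) {
  cat("<condition_series>\n")
  df <- data.frame(condition = x$labels, cycles = x$n_cycles,
                   E_MPa = x$e_values,
                   peak_abs_eps_min = signif(x$metrics$peak_abs_eps_min, 4),
                   pct_vs_pre = round(x$metrics$pct_change_vs_pre, 1),
                   critical_slice = x$metrics$critical_slice)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Percentage change relative to a reference
#'
#' `(other - reference) / reference * 100`. The reference-first convention
#' matters: damage-progression deltas use the earlier (or experimental)
#' value as the denominator. Use `rounded = TRUE` to report the nearest
#' integer percent of the magnitude, the form such deltas are customarily
#' quoted in.
#'
#' @param reference reference value (nonzero).
#' @param other comparison value.
#' @param rounded if `TRUE`, return `round(abs(.))`.
#' @return Percent change (full precision by default).
#' @export
pct_change <- function(reference, other, rounded = FALSE) {
  if (any(reference == 0)) stop_param("zero reference")
  p <- (other - reference) / reference * 100
  if (rounded) round(abs(p)) else p
}

#' Critical slice of a 3D strain field
#'
#' The axial slice (element layer) containing the global peak of
#' |minimum principal strain|, with the element-averaged strain map of that
#' slice for rendering. Ties inside an element layer are resolved by the
#' peak integration point; a uniform field reports the lowest slice index
#' containing the first peak in scan order.
#'
#' @param res an [fe_solve()] result on a `hex_mesh`.
#' @param axis slice axis index (default the loading axis).
#' @return A list: `slice` (1-based element-layer index), `z_norm`
#'   (normalized height of the layer center), `slice_map` (2D matrix of
#'   element-averaged minimum principal strain over that layer, NA where no
#'   bone).
#' @export
critical_slice <- function(res, axis = NULL) {
  stopifnot(inherits(res, "fe_result"))
  mesh <- res$mesh
  if (!inherits(mesh, "hex_mesh"))
    stop_param("critical_slice requires a 3D (hex) result")
  if (is.null(axis)) axis <- res$axis
  ai <- arrayInd(mesh$voxel_index, mesh$dims)
  slices <- ai[, axis]
  pk <- res$peak$element
  slice <- slices[pk]
  n_sl <- mesh$dims[axis]
  tr <- setdiff(1:3, axis)
  inslice <- which(slices == slice)
  map <- matrix(NA_real_, mesh$dims[tr[1]], mesh$dims[tr[2]])
  elem_mean <- rowMeans(res$eps_p_min[inslice, , drop = FALSE])
  map[cbind(ai[inslice, tr[1]], ai[inslice, tr[2]])] <- elem_mean
  list(slice = slice, z_norm = (slice - 0.5) / n_sl, slice_map = map)
}
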