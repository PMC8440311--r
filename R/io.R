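# File interfaces: multi-page TIFF stacks and MetaImage (.mhd/.raw) volumes
# in, VTK legacy unstructured grids and summary JSON out.

#' Read a multi-page TIFF stack as a grayscale volume
#'
#' Pages are stacked along z (bottom slice first); within a page, columns
#' map to x and rows to y. Intensities are returned on the 0-255 scale.
#'
#' @param path TIFF file.
#' @param spacing voxel edge (mm); TIFF carries no physical spacing, so it
#'   must be supplied (25.6e-3 mm is the micro-CT-like default).
#' @return A [gray_volume()].
#' @export
read_tiff_stack <- function(path, spacing = 0.0256) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  d <- dim(pages[[1]])
  data <- array(0, c(d[2], d[1], length(pages)))
  for (s in seq_along(pages)) data[, , s] <- t(pages[[s]])
  gray_volume(data * 255, spacing)
}

#' Write a volume as a multi-page 8-bit TIFF stack
#'
#' Gray volumes are min-max rescaled to 8-bit; binary volumes are written as
#' \{0, 255\}.
#'
#' @param vol a [gray_volume()] or [binary_volume()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(vol, path) {
  x <- if (inherits(vol, "binary_volume")) vol$data * 255 else {
    r <- range(vol$data)
    if (r[2] > r[1]) 255 * (vol$data - r[1]) / (r[2] - r[1]) else vol$data * 0
  }
  pages <- lapply(seq_len(dim(x)[3]), function(s) t(x[, , s]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a MetaImage (.mhd + .raw) volume
#'
#' Supports uncompressed local raw payloads of type MET_UCHAR, MET_SHORT,
#' MET_USHORT, MET_FLOAT or MET_DOUBLE. Spacing is taken from
#' `ElementSpacing` (isotropic required) unless overridden.
#'
#' @param path the `.mhd` header file.
#' @param spacing optional override of the header spacing (mm).
#' @return A [gray_volume()].
#' @export
read_mhd <- function(path, spacing = NULL) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(k) vals[match(k, keys)]
  d <- as.integer(strsplit(trimws(get("DimSize")), "\\s+")[[1]])
  sp <- as.numeric(strsplit(trimws(get("ElementSpacing")), "\\s+")[[1]])
  off <- get("Offset")
  origin <- if (is.na(off)) c(0, 0, 0)
  else as.numeric(strsplit(trimws(off), "\\s+")[[1]])
  typ <- trimws(get("ElementType"))
  raw_file <- file.path(dirname(path), trimws(get("ElementDataFile")))
  n <- prod(d)
  con <- file(raw_file, "rb")
  on.exit(close(con))
  data <- switch(typ,
    MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1,
                                   signed = FALSE)),
    MET_SHORT = as.numeric(readBin(con, "integer", n, size = 2,
                                   signed = TRUE, endian = "little")),
    MET_USHORT = as.numeric(readBin(con, "integer", n, size = 2,
                                    signed = FALSE, endian = "little")),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop_param("unsupported ElementType: ", typ))
  dim(data) <- d
  if (is.null(spacing)) {
    if (length(unique(round(sp, 9))) != 1L)
      stop_param("anisotropic spacing not supported")
    spacing <- sp[1]
  }
  gray_volume(data, spacing, origin)
}

#' Write a volume as MetaImage (.mhd + .raw)
#'
#' Binary volumes are stored as 8-bit \{0, 255\} (MET_UCHAR); gray volumes
#' as little-endian MET_FLOAT.
#'
#' @param vol a [gray_volume()] or [binary_volume()].
#' @param path the `.mhd` header path; the raw payload is written next to
#'   it.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(vol, path) {
  d <- dim(vol$data)
  raw_name <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  is_bin <- inherits(vol, "binary_volume")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =",
                 paste(rep(vol$spacing, 3), collapse = " ")),
           paste("Offset =", paste(vol$origin, collapse = " ")),
           paste("ElementType =", if (is_bin) "MET_UCHAR" else "MET_FLOAT"),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (is_bin) {
    writeBin(as.integer(vol$data) * 255L, con, size = 1)
  } else {
    writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a mesh (with optional results) as a legacy VTK unstructured grid
#'
#' Hexahedra are written as VTK cell type 12, quadrilaterals as type 9 (2D
#' nodes are padded with z = 0). Cell data always include the element
#' modulus or material index when present; an [fe_solve()] result adds
#' nodal displacement vectors and cell-averaged minimum principal strain.
#'
#' @param mesh a `hex_mesh` or `quad_mesh`.
#' @param path output `.vtk` path.
#' @param result optional `fe_result` on this mesh.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, result = NULL) {
  dim_n <- mesh_dim(mesh)
  nd <- mesh$nodes
  if (dim_n == 2L) nd <- cbind(nd, 0)
  el <- mesh$elements
  m <- nrow(el)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("trabesim mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d float", nrow(nd))
  writeLines(apply(nd, 1, function(r) paste(format(r, digits = 9),
                                            collapse = " ")), con)
  w("CELLS %d %d", m, m * (ncol(el) + 1L))
  writeLines(apply(el, 1, function(r)
    paste(c(ncol(el), r - 1L), collapse = " ")), con)
  w("CELL_TYPES %d", m)
  writeLines(rep(if (dim_n == 3L) "12" else "9", m), con)

  cell_scalars <- list()
  if (!is.null(mesh$elem_modulus)) cell_scalars$modulus <- mesh$elem_modulus
  if (!is.null(result))
    cell_scalars$eps_p_min <- rowMeans(result$eps_p_min)
  if (length(cell_scalars) > 0) {
    w("CELL_DATA %d", m)
    for (nm in names(cell_scalars)) {
      w("SCALARS %s float 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(format(cell_scalars[[nm]], digits = 9), con)
    }
  }
  if (!is.null(result)) {
    u <- result$u
    if (ncol(u) == 2L) u <- cbind(u, 0)
    w("POINT_DATA %d", nrow(nd))
    w("VECTORS displacement float")
    writeLines(apply(u, 1, function(r) paste(format(r, digits = 9),
                                             collapse = " ")), con)
  }
  invisible(path)
}

#' Write an FE result summary as JSON
#'
#' Records `peak_strain` (signed minimum principal strain at the peak
#' integration point), `peak_location_mm` and `stiffness_n_per_mm`.
#'
#' @param res an [fe_solve()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fe_summary <- function(res, path) {
  stopifnot(inherits(res, "fe_result"))
  jsonlite::write_json(list(peak_strain = res$peak$value,
                            peak_location_mm = res$peak$location,
                            stiffness_n_per_mm = res$stiffness),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
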