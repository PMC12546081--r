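#' Spacing-aware 3D scalar lattice
#'
#' The container underlying every image in the pipeline: a numeric 3D array
#' plus the physical voxel spacing in millimetres. Physical coordinates are
#' voxel-centre coordinates: voxel `[i, j, k]` (1-based) sits at
#' `((i-1) dx, (j-1) dy, (k-1) dz) + origin`. All geometry downstream
#' (centerlines, distances, flows) is computed in physical units.
#'
#' @param values numeric 3D array (a 2D matrix is promoted to a single-slice
#'   volume).
#' @param spacing_mm numeric length-3, strictly positive voxel spacing
#'   `(dx, dy, dz)` in mm.
#' @param origin_mm physical coordinate of the first voxel centre (default
#'   `c(0, 0, 0)`).
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_input("`values` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop_input("`spacing_mm` must be 3 strictly positive reals")
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

grid_dim <- function(g) dim(g$values)

#' Voxel volume of a grid in mm^3
#' @param g a [voxel_grid()].
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(g) prod(g$spacing_mm)

#' Convert 1-based voxel indices to physical mm coordinates
#' @param g a [voxel_grid()].
#' @param ijk integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
index_to_physical <- function(g, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk - 1, 2L, g$spacing_mm, `*`), 2L, g$origin_mm, `+`)
}

#' Convert physical mm coordinates to (fractional) 1-based voxel indices
#' @param g a [voxel_grid()].
#' @param xyz numeric matrix (n x 3) or length-3 vector, mm.
#' @return n x 3 matrix of fractional indices.
#' @export
physical_to_index <- function(g, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(sweep(xyz, 2L, g$origin_mm, `-`), 2L, g$spacing_mm, `/`) + 1
}

assert_same_geometry <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)))
    stop_input("%s have mismatched dimensions", what)
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9)
    stop_input("%s have mismatched spacing", what)
  invisible(TRUE)
}

#' Euclidean distance transform of a binary mask
#'
#' Exact anisotropic distance (mm) from every voxel to the nearest
#' foreground voxel centre. Used both for the medialness speed map in
#' centerline extraction (distance to the background) and for the
#' lesion-to-ventricle distance rule.
#'
#' @param g a [voxel_grid()] interpreted as binary (non-zero = foreground).
#' @param invert if `TRUE`, distance to the nearest background voxel
#'   (interior depth) instead.
#' @return a [voxel_grid()] of distances in mm (`Inf` if no source voxel).
#' @export
distance_transform <- function(g, invert = FALSE) {
  m <- g$values != 0
  if (invert) m <- !m
  d2 <- .cpp_edt_sq(as.integer(m), dim(g$values), g$spacing_mm)
  voxel_grid(array(sqrt(d2), dim(g$values)), g$spacing_mm, g$origin_mm)
}
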