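#' Voxel grid geometry
#'
#' A `voxel_grid` describes an axis-aligned 3-D sampling lattice: the voxel
#' spacing in mm along (x, y, z), the world position (mm) of the centre of
#' the first voxel, and the array shape. The value of a voxel is located at
#' its centre; the centre of voxel `(i, j, k)` (1-based array indices) is at
#' `origin + (c(i, j, k) - 1) * spacing`. Oblique orientations are not
#' supported.
#'
#' @param spacing_mm numeric length-3, voxel spacing in mm (x, y, z); all > 0.
#' @param shape integer length-3, array dimensions; all >= 1.
#' @param origin_mm numeric length-3, world coordinate (mm) of the centre of
#'   voxel (1, 1, 1).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(0.5, 0.5, 1), c(10, 10, 5))
#' voxel_volume_mm3(g)
#' @export
voxel_grid <- function(spacing_mm, shape, origin_mm = c(0, 0, 0)) {
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  shape <- as.integer(shape)
  stopifnot(length(spacing_mm) == 3L, length(shape) == 3L, length(origin_mm) == 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("voxel spacings must be positive and finite")
  if (any(shape < 1L)) stop("grid shape must have at least one voxel per axis")
  structure(list(spacing_mm = spacing_mm, origin_mm = origin_mm, shape = shape),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param grid a [voxel_grid].
#' @return Voxel volume in mm^3 (product of the three spacings).
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing_mm)

#' Voxel volume in mL
#'
#' One mL equals 1000 mm^3; radioactivity bookkeeping works in mL.
#' @param grid a [voxel_grid].
#' @return Voxel volume in mL.
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing_mm) / 1000

#' World coordinates of voxel centres along one axis
#' @param grid a [voxel_grid].
#' @param axis 1, 2 or 3 (x, y, z).
#' @return Numeric vector of centre coordinates in mm.
#' @export
grid_axis_mm <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing_mm[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what, call. = FALSE)
  invisible(TRUE)
}
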