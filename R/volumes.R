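#' CT volume in Hounsfield units
#'
#' A `ct_volume` holds a 3-D array of Hounsfield units (HU) on a
#' [voxel_grid], together with the scanner's representable HU range and
#' free-form provenance metadata (scanner model, kVp, reconstruction
#' kernel). Values are expected to lie within the representable range; a
#' 12-bit scanner spans -1024 to 3071 HU, a 16-bit scanner -32768 to
#' 32767 HU.
#'
#' @param values numeric 3-D array of HU.
#' @param grid a [voxel_grid]; `dim(values)` must equal `grid$shape`.
#' @param hu_limits numeric length-2, the representable (min, max) HU.
#' @param metadata named list of provenance (e.g. scanner, kvp, kernel).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, grid, hu_limits = c(-1024, 3071), metadata = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!all(dim(values) == grid$shape))
    stop("array shape does not match grid shape")
  if (hu_limits[1] >= hu_limits[2]) stop("hu_limits must be increasing")
  rng <- range(values, finite = TRUE)
  if (rng[1] < hu_limits[1] - 1e-9 || rng[2] > hu_limits[2] + 1e-9)
    warning("HU values outside the stated representable range [",
            hu_limits[1], ", ", hu_limits[2], "]")
  structure(list(values = values, grid = grid,
                 hu_min_limit = hu_limits[1], hu_max_limit = hu_limits[2],
                 metadata = metadata),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("ct_volume\n")
  print(x$grid)
  cat(sprintf("  HU range in data: [%.1f, %.1f]; representable: [%g, %g]\n",
              min(x$values), max(x$values), x$hu_min_limit, x$hu_max_limit))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Volume-of-interest mask
#'
#' A boolean voxel mask on the same grid as the volume it is applied to.
#' Masks are stored as full logical volumes, not contours.
#'
#' @param included logical 3-D array; `TRUE` marks voxels inside the VOI.
#' @param grid a [voxel_grid] matching `dim(included)`.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(included, grid) {
  if (!is.array(included) || length(dim(included)) != 3L)
    stop("included must be a 3-D logical array")
  if (!all(dim(included) == grid$shape))
    stop("mask shape does not match grid shape")
  storage.mode(included) <- "logical"
  structure(list(included = included, grid = grid), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("voi_mask: %d of %d voxels included (%.2f mL)\n",
              sum(x$included), length(x$included),
              sum(x$included) * voxel_volume_ml(x$grid)))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a [voi_mask].
#' @return Integer count of included voxels.
#' @export
mask_n_voxels <- function(mask) sum(mask$included)

#' Cylindrical VOI mask
#'
#' Builds the cylindrical analysis masks used for calibration-tube
#' radiodensity measurements (e.g. a 100 mm^2 cross-section, diameter
#' 11 mm, inside a 17 mm tube). A voxel is included iff its centre lies
#' within the cylinder.
#'
#' @param grid a [voxel_grid].
#' @param center_mm numeric length-3, world coordinates (mm) of the cylinder
#'   centre.
#' @param diameter_mm cylinder diameter in mm.
#' @param length_mm cylinder length in mm.
#' @param axis `"x"`, `"y"` or `"z"`: the cylinder axis.
#' @return A [voi_mask]. Errors if the cylinder lies fully outside the grid
#'   or covers no voxel centre.
#' @examples
#' g <- voxel_grid(c(0.5, 0.5, 0.5), c(40, 40, 70))
#' m <- make_cylinder_mask(g, c(10, 10, 17), diameter_mm = 11, length_mm = 30)
#' mask_n_voxels(m) * voxel_volume_mm3(g)  # close to pi * 5.5^2 * 30
#' @export
make_cylinder_mask <- function(grid, center_mm, diameter_mm, length_mm, axis = "z") {
  axis <- match.arg(axis, c("x", "y", "z"))
  ia <- match(axis, c("x", "y", "z"))
  ip <- setdiff(1:3, ia)
  if (diameter_mm <= 0 || length_mm <= 0)
    stop("diameter and length must be positive")
  lo <- grid$origin_mm - grid$spacing_mm / 2
  hi <- grid$origin_mm + (grid$shape - 0.5) * grid$spacing_mm
  if (center_mm[ia] + length_mm / 2 < lo[ia] || center_mm[ia] - length_mm / 2 > hi[ia] ||
      any(center_mm[ip] + diameter_mm / 2 < lo[ip]) ||
      any(center_mm[ip] - diameter_mm / 2 > hi[ip]))
    stop("cylinder lies outside the grid")
  ax <- lapply(1:3, function(k) grid_axis_mm(grid, k) - center_mm[k])
  r2 <- outer(ax[[ip[1]]]^2, ax[[ip[2]]]^2, "+")
  in_disc <- r2 <= (diameter_mm / 2)^2
  in_len <- abs(ax[[ia]]) <= length_mm / 2
  inc <- array(FALSE, grid$shape)
  # broadcast the disc over the axial direction
  perm <- order(c(ip, ia))
  disc3 <- aperm(outer(in_disc, in_len, "&"), perm)
  inc[] <- disc3
  if (!any(inc)) stop("cylinder covers no voxel centre")
  voi_mask(inc, grid)
}

#' Drop slices outside a kept range
#'
#' Removes axial (z) slices outside `keep`, e.g. tapered tube bottoms, caps
#' or the positioning racket, trimming datasets to a common length. The grid
#' origin shifts so that retained voxels keep their world coordinates.
#'
#' @param volume a [ct_volume].
#' @param keep integer slice index range (1-based, inclusive) to retain;
#'   either `c(first, last)` or a contiguous vector of indices.
#' @return The trimmed [ct_volume].
#' @export
exclude_slices <- function(volume, keep) {
  keep <- as.integer(keep)
  if (length(keep) == 2L && keep[2] >= keep[1]) keep <- keep[1]:keep[2]
  if (length(keep) == 0L) stop("empty slice interval")
  if (any(diff(keep) != 1L)) stop("kept slices must be contiguous")
  nz <- volume$grid$shape[3]
  if (keep[1] < 1L || keep[length(keep)] > nz)
    stop("slice interval outside volume bounds (1..", nz, ")")
  vals <- volume$values[, , keep, drop = FALSE]
  g <- volume$grid
  origin <- g$origin_mm
  origin[3] <- origin[3] + (keep[1] - 1L) * g$spacing_mm[3]
  newg <- voxel_grid(g$spacing_mm, c(g$shape[1:2], length(keep)), origin)
  ct_volume(vals, newg, c(volume$hu_min_limit, volume$hu_max_limit), volume$metadata)
}

#' VOI radiodensity statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum, maximum,
#' normal-approximation 95% confidence interval of the mean
#' (mean +/- 1.96 SD / sqrt(n)) and voxel count over the included voxels.
#'
#' @param volume a [ct_volume].
#' @param mask a [voi_mask] on the same grid.
#' @return An object of class `voi_stats` with fields `mean_hu`, `sd_hu`,
#'   `min_hu`, `max_hu`, `ci95`, `n_voxels`.
#' @export
voi_stats <- function(volume, mask) {
  stop_if_grid_mismatch(volume$grid, mask$grid, "volume and mask")
  v <- volume$values[mask$included]
  n <- length(v)
  if (n < 1L) stop("mask selects no voxels")
  m <- mean(v)
  s <- if (n > 1L) stats::sd(v) else 0
  structure(list(mean_hu = m, sd_hu = s, min_hu = min(v), max_hu = max(v),
                 ci95 = c(m - 1.96 * s / sqrt(n), m + 1.96 * s / sqrt(n)),
                 n_voxels = n),
            class = "voi_stats")
}

#' @export
print.voi_stats <- function(x, ...) {
  cat(sprintf("voi_stats: mean %.2f HU (SD %.2f, 95%% CI %.2f..%.2f), range [%.1f, %.1f], n = %d\n",
              x$mean_hu, x$sd_hu, x$ci95[1], x$ci95[2], x$min_hu, x$max_hu, x$n_voxels))
  invisible(x)
}

#' Trilinear resampling between grids
#'
#' Interpolates a volume (HU, concentration or activity) at the voxel
#' centres of a target grid. Values outside the source extent are zero.
#' With `conserve_total = TRUE` (appropriate for per-voxel activity maps,
#' where the summed quantity is physical) the output is rescaled so its
#' total equals the source total exactly.
#'
#' @param volume a [ct_volume] or a plain named list with `values` and
#'   `grid` (as produced by the quantification maps).
#' @param target a [voxel_grid]; must overlap the source extent.
#' @param conserve_total logical; rescale so that `sum(output) == sum(input)`.
#' @return Object of the same kind on the target grid.
#' @export
resample_trilinear <- function(volume, target, conserve_total = FALSE) {
  src <- volume$grid
  lo_s <- src$origin_mm - src$spacing_mm / 2
  hi_s <- src$origin_mm + (src$shape - 0.5) * src$spacing_mm
  lo_t <- target$origin_mm - target$spacing_mm / 2
  hi_t <- target$origin_mm + (target$shape - 0.5) * target$spacing_mm
  if (any(hi_t <= lo_s) || any(lo_t >= hi_s))
    stop("target grid does not overlap the source extent")
  # fractional source indices (1-based) of target voxel centres
  idx <- lapply(1:3, function(k)
    (grid_axis_mm(target, k) - src$origin_mm[k]) / src$spacing_mm[k] + 1)
  out <- trilinear_interp(volume$values, idx[[1]], idx[[2]], idx[[3]])
  if (conserve_total) {
    st <- sum(volume$values)
    ot <- sum(out)
    if (ot != 0) out <- out * (st / ot)
    else if (st != 0) warning("conserve_total requested but resampled total is zero")
  }
  if (inherits(volume, "ct_volume")) {
    ct_volume(out, target, c(volume$hu_min_limit, volume$hu_max_limit), volume$metadata)
  } else {
    res <- volume
    res$values <- out
    res$grid <- target
    res
  }
}

# Vectorised separable trilinear interpolation with zero outside the source.
trilinear_interp <- function(vals, xi, yi, zi) {
  d <- dim(vals)
  clampw <- function(i, n) {
    i0 <- floor(i)
    w <- i - i0
    # outside [1, n] -> weight to a phantom zero sample
    list(i0 = i0, w = w)
  }
  gx <- clampw(xi, d[1]); gy <- clampw(yi, d[2]); gz <- clampw(zi, d[3])
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  out <- array(0, c(nx, ny, nz))
  getslab <- function(ix, iy, iz) {
    okx <- ix >= 1 & ix <= d[1]
    oky <- iy >= 1 & iy <= d[2]
    okz <- iz >= 1 & iz <= d[3]
    sx <- pmin(pmax(ix, 1L), d[1]); sy <- pmin(pmax(iy, 1L), d[2]); sz <- pmin(pmax(iz, 1L), d[3])
    slab <- vals[sx, sy, sz, drop = FALSE]
    if (!all(okx)) slab[!okx, , ] <- 0
    if (!all(oky)) slab[, !oky, ] <- 0
    if (!all(okz)) slab[, , !okz] <- 0
    slab
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - gx$w else gx$w
    wy <- if (dy == 0) 1 - gy$w else gy$w
    wz <- if (dz == 0) 1 - gz$w else gz$w
    w3 <- outer(outer(wx, wy), wz)
    out <- out + w3 * getslab(as.integer(gx$i0) + dx, as.integer(gy$i0) + dy,
                              as.integer(gz$i0) + dz)
  }
  out
}
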