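#' Calibration points
#'
#' One row per phantom tube: the known Ho concentration and the VOI
#' radiodensity statistics measured in its cylindrical analysis mask.
#'
#' @param concentration_mg_per_ml numeric, mg elemental Ho per mL; >= 0.
#' @param mean_hu,sd_hu,max_hu numeric tube statistics (HU).
#' @param n_voxels optional voxel counts.
#' @return A data.frame of class `calibration_points` with a logical
#'   `saturated` column (initialised `FALSE`).
#' @export
calibration_points <- function(concentration_mg_per_ml, mean_hu, sd_hu = NA_real_,
                               max_hu = NA_real_, n_voxels = NA_integer_) {
  if (any(concentration_mg_per_ml < 0)) stop("concentrations must be >= 0")
  df <- data.frame(concentration_mg_per_ml = concentration_mg_per_ml,
                   mean_hu = mean_hu, sd_hu = sd_hu, max_hu = max_hu,
                   n_voxels = n_voxels, saturated = FALSE)
  class(df) <- c("calibration_points", "data.frame")
  df
}

#' Build calibration points from a phantom volume
#'
#' Measures [voi_stats] in each tube mask and pairs them with the known
#' concentrations.
#'
#' @param volume a [ct_volume] of the calibration phantom.
#' @param masks list of [voi_mask], one per tube.
#' @param concentrations mg Ho/mL, parallel to `masks`.
#' @return A `calibration_points` data.frame.
#' @export
calibration_points_from_volume <- function(volume, masks, concentrations) {
  stopifnot(length(masks) == length(concentrations))
  st <- lapply(masks, function(m) voi_stats(volume, m))
  calibration_points(concentrations,
                     mean_hu = vapply(st, `[[`, 0, "mean_hu"),
                     sd_hu = vapply(st, `[[`, 0, "sd_hu"),
                     max_hu = vapply(st, `[[`, 0, "max_hu"),
                     n_voxels = vapply(st, `[[`, 0L, "n_voxels"))
}

#' Exclude saturated calibration points
#'
#' Tubes whose maximum HU exceeds the scanner's detection limit (strictly
#' `max_hu > hu_max_limit`) are flagged `saturated` and removed from
#' fitting; a point exactly at the limit is retained. At least two
#' unsaturated points must remain.
#'
#' On volumes already clipped to the representable range, saturated voxels
#' sit exactly at the cap and can never exceed it; there the trustworthy
#' detection limit is one HU step below the cap (3070 on a 12-bit scanner),
#' so that any tube with a clipped voxel is excluded.
#'
#' @param points a `calibration_points` data.frame.
#' @param hu_max_limit the scanner's maximum representable HU (3071 for a
#'   12-bit system).
#' @return The points with `saturated` set; attribute `"excluded"` holds the
#'   removed rows.
#' @export
exclude_saturated <- function(points, hu_max_limit) {
  if (nrow(points) == 0L) stop("no calibration points")
  sat <- !is.na(points$max_hu) & points$max_hu > hu_max_limit
  points$saturated <- sat
  kept <- points[!sat, , drop = FALSE]
  if (nrow(kept) < 2L)
    stop("fewer than 2 calibration points remain below the detection limit of ",
         hu_max_limit, " HU")
  attr(kept, "excluded") <- points[sat, , drop = FALSE]
  kept
}

#' Fit the linear HU-versus-concentration calibration
#'
#' Ordinary least squares of tube mean HU on Ho concentration,
#' `HU = m + b * c`, with full regression diagnostics. If the standard
#' error of the intercept exceeds its absolute value (strict `>`), the line
#' is refit through the origin and flagged `forced_zero`; R-squared of a
#' through-origin fit follows the uncentered total-sum-of-squares
#' convention and is labelled as such.
#'
#' Saturated points (see [exclude_saturated]) must already have been
#' removed.
#'
#' @param points a `calibration_points` data.frame with >= 2 rows spanning
#'   >= 2 distinct concentrations.
#' @param force_zero `NA` (apply the standard-error rule), `TRUE` or `FALSE`.
#' @param metadata named list recorded on the curve (scanner, kvp, kernel);
#'   curves are scanner-specific and should not be applied across scanners.
#' @return An object of class `calibration_curve` with fields
#'   `intercept_m`, `slope_b`, `forced_zero`, `r_squared`, `f_stat`,
#'   `std_error_m`, `std_error_b`, `p_value`, `n_points`, `metadata`.
#' @examples
#' pts <- calibration_points(c(0, 1, 2), 26.36 + 29.89 * c(0, 1, 2))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, force_zero = NA, metadata = list()) {
  if (any(points$saturated)) points <- points[!points$saturated, , drop = FALSE]
  x <- points$concentration_mg_per_ml
  y <- points$mean_hu
  if (length(x) < 2L) stop("need at least 2 calibration points")
  if (length(unique(x)) < 2L) stop("all concentrations equal; slope not identifiable")
  fit <- stats::lm(y ~ x)
  co <- suppressWarnings(summary(fit))$coefficients
  m <- co[1, 1]; se_m <- co[1, 2]
  b <- co[2, 1]; se_b <- co[2, 2]
  fz <- if (is.na(force_zero)) isTRUE(se_m > abs(m)) else isTRUE(force_zero)
  if (fz) {
    fit0 <- stats::lm(y ~ 0 + x)
    s0 <- suppressWarnings(summary(fit0))
    b <- s0$coefficients[1, 1]; se_b <- s0$coefficients[1, 2]
    m <- 0; se_m <- 0
    r2 <- s0$r.squared  # uncentered convention for through-origin fits
    fstat <- unname(s0$fstatistic[1])
    pval <- s0$coefficients[1, 4]
  } else {
    s1 <- suppressWarnings(summary(fit))
    r2 <- s1$r.squared
    fstat <- if (!is.null(s1$fstatistic)) unname(s1$fstatistic[1]) else NA_real_
    pval <- co[2, 4]
  }
  if (b <= 0) stop("fitted slope is not positive; calibration data unusable")
  if (!is.na(pval) && pval >= 0.05)
    warning("calibration slope not significant at p < 0.05 (p = ", signif(pval, 3), ")")
  structure(list(intercept_m = m, slope_b = b, forced_zero = fz,
                 r_squared = r2, f_stat = fstat,
                 std_error_m = se_m, std_error_b = se_b, p_value = pval,
                 n_points = length(x), metadata = metadata),
            class = "calibration_curve")
}

#' Construct a calibration curve from known coefficients
#'
#' Useful for forward simulation and for curves published without raw data,
#' e.g. intercept 26.36 HU and slope 29.89 HU per mg/mL.
#'
#' @param intercept_m intercept in HU (0 if `forced_zero`).
#' @param slope_b slope in HU per (mg/mL); > 0.
#' @param forced_zero logical.
#' @param metadata named list.
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(intercept_m, slope_b, forced_zero = FALSE,
                              metadata = list()) {
  if (slope_b <= 0) stop("slope must be positive")
  if (forced_zero && intercept_m != 0) stop("forced-zero curve must have intercept 0")
  structure(list(intercept_m = intercept_m, slope_b = slope_b,
                 forced_zero = forced_zero,
                 r_squared = NA_real_, f_stat = NA_real_,
                 std_error_m = NA_real_, std_error_b = NA_real_,
                 p_value = NA_real_, n_points = NA_integer_,
                 metadata = metadata),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: HU = %.4g + %.4g * c(mg/mL)%s\n",
              x$intercept_m, x$slope_b,
              if (x$forced_zero) "  [forced through zero]" else ""))
  if (!is.na(x$r_squared))
    cat(sprintf("  R^2 = %.4f, F = %.4g, SE(m) = %.3g, SE(b) = %.3g, p = %.3g, n = %d\n",
                x$r_squared, x$f_stat, x$std_error_m, x$std_error_b,
                x$p_value, x$n_points))
  invisible(x)
}

#' Predict HU from a Ho concentration
#' @param curve a `calibration_curve`.
#' @param concentration mg Ho/mL; must be >= 0.
#' @return HU value(s) `m + b * c`.
#' @export
predict_hu <- function(curve, concentration) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  curve$intercept_m + curve$slope_b * concentration
}

#' Invert the calibration: HU to concentration
#'
#' Returns `(hu - m) / b`; the result may be negative and callers decide
#' whether to clamp (the quantification operators do so per method).
#'
#' @param curve a `calibration_curve`.
#' @param hu HU value(s).
#' @return mg Ho/mL.
#' @export
hu_to_concentration <- function(curve, hu) {
  (hu - curve$intercept_m) / curve$slope_b
}

#' Calibration table and curve I/O
#'
#' Tables are CSV with columns `concentration_mg_per_ml`, `mean_hu`,
#' `sd_hu`, `max_hu`; curves are JSON carrying coefficients, diagnostics
#' and metadata. Metadata matters: calibration parameters are not
#' interchangeable between scanners, and [run_pipeline] refuses to apply a
#' curve whose scanner metadata conflicts with the volume's unless
#' overridden.
#'
#' @param points a `calibration_points` data.frame.
#' @param path file path.
#' @return `read_calibration_table` returns a `calibration_points`
#'   data.frame; `read_calibration_curve` a `calibration_curve`; writers
#'   return `path` invisibly.
#' @name calibration_io
#' @export
write_calibration_table <- function(points, path) {
  utils::write.csv(as.data.frame(points)[, c("concentration_mg_per_ml", "mean_hu",
                                             "sd_hu", "max_hu")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("concentration_mg_per_ml", "mean_hu")
  if (!all(need %in% names(df)))
    stop("calibration CSV must contain columns: ", paste(need, collapse = ", "))
  calibration_points(df$concentration_mg_per_ml, df$mean_hu,
                     sd_hu = if ("sd_hu" %in% names(df)) df$sd_hu else NA_real_,
                     max_hu = if ("max_hu" %in% names(df)) df$max_hu else NA_real_)
}

#' @rdname calibration_io
#' @param curve a `calibration_curve`.
#' @export
write_calibration_curve <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_calibration_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cv <- calibration_curve(x$intercept_m, x$slope_b, isTRUE(x$forced_zero),
                          metadata = as.list(x$metadata))
  for (f in c("r_squared", "f_stat", "std_error_m", "std_error_b", "p_value"))
    if (!is.null(x[[f]])) cv[[f]] <- as.numeric(x[[f]])
  if (!is.null(x$n_points)) cv$n_points <- as.integer(x$n_points)
  cv
}
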