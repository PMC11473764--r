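#' Physical decay constants for 166Ho
#'
#' The half-life is 26.82 h; the decay constant follows as
#' `log(2) / t_half` = 7.179e-6 s^-1 (commonly printed rounded to
#' 7.18e-6 s^-1).
#'
#' @param half_life_h half-life in hours.
#' @return `ho166_half_life_h()` the half-life in hours;
#'   `ho166_lambda_per_s()` the decay constant in s^-1.
#' @export
ho166_half_life_h <- function() 26.82

#' @rdname ho166_half_life_h
#' @export
ho166_lambda_per_s <- function(half_life_h = ho166_half_life_h()) {
  log(2) / (half_life_h * 3600)
}

#' Correct an activity for radioactive decay
#'
#' `forward` propagates an activity to a later time (`A * exp(-lambda t)`),
#' `back` to an earlier time (`A * exp(+lambda t)`). Dose-calibrator
#' measurements are referred to the CT scan time this way.
#'
#' @param activity_bq activity in Bq.
#' @param elapsed_s elapsed time in seconds; >= 0.
#' @param direction `"forward"` or `"back"`.
#' @param lambda_per_s decay constant (s^-1).
#' @return Decay-corrected activity in Bq.
#' @examples
#' decay_correct(1, 26.82 * 3600, "forward")  # exactly 0.5
#' @export
decay_correct <- function(activity_bq, elapsed_s, direction = c("forward", "back"),
                          lambda_per_s = ho166_lambda_per_s()) {
  direction <- match.arg(direction)
  if (any(elapsed_s < 0)) stop("elapsed time must be >= 0")
  sgn <- if (direction == "forward") -1 else 1
  activity_bq * exp(sgn * lambda_per_s * elapsed_s)
}

#' Injection record
#'
#' Dose-calibrator measurements before and after injection, their
#' measurement times, the CT scan time, and the microsphere specific
#' activity at its stated reference time. Times may be `POSIXct` or plain
#' numeric seconds; only differences are used.
#'
#' @param activity_before_bq,activity_after_bq measured activities (Bq).
#' @param time_before,time_after,scan_time timestamps of the two
#'   measurements and of the CT scan.
#' @param specific_activity_bq_per_mg microsphere specific activity
#'   (Bq per mg Ho-MS) at `specific_activity_time`.
#' @param specific_activity_time reference time of the specific activity;
#'   defaults to `scan_time`.
#' @param ho_content_fraction elemental-Ho mass fraction of the
#'   microspheres; 0.197 for the 19.7 % Ho poly(L-lactic acid) product.
#' @return An object of class `injection_record`.
#' @export
injection_record <- function(activity_before_bq, activity_after_bq,
                             time_before, time_after, scan_time,
                             specific_activity_bq_per_mg,
                             specific_activity_time = scan_time,
                             ho_content_fraction = 0.197) {
  if (ho_content_fraction <= 0 || ho_content_fraction > 1)
    stop("ho_content_fraction must be in (0, 1]")
  if (activity_before_bq < activity_after_bq)
    stop("activity before injection must be >= activity after")
  if (activity_after_bq < 0) stop("activities must be >= 0")
  if (specific_activity_bq_per_mg <= 0) stop("specific activity must be positive")
  structure(list(activity_before_bq = activity_before_bq,
                 activity_after_bq = activity_after_bq,
                 time_before = time_before, time_after = time_after,
                 scan_time = scan_time,
                 specific_activity_bq_per_mg = specific_activity_bq_per_mg,
                 specific_activity_time = specific_activity_time,
                 ho_content_fraction = ho_content_fraction),
            class = "injection_record")
}

elapsed_seconds <- function(from, to) as.numeric(to) - as.numeric(from)

# specific activity referred to the scan time (mass is stable, activity decays)
specific_activity_at_scan <- function(record, lambda_per_s = ho166_lambda_per_s()) {
  dt <- elapsed_seconds(record$specific_activity_time, record$scan_time)
  record$specific_activity_bq_per_mg * exp(-lambda_per_s * dt)
}

#' Injected amount from an injection record
#'
#' Both dose-calibrator measurements are decay-corrected to the scan time
#' and subtracted; the injected microsphere mass follows from the specific
#' activity referred to the scan time.
#'
#' @param record an [injection_record].
#' @param lambda_per_s decay constant (s^-1).
#' @return List with `injected_bq` (at scan time), `injected_ms_mg`
#'   (microsphere mass) and `injected_ho_mg` (elemental Ho mass).
#' @export
injected_amount <- function(record, lambda_per_s = ho166_lambda_per_s()) {
  before <- decay_correct(record$activity_before_bq,
                          abs(elapsed_seconds(record$time_before, record$scan_time)),
                          if (elapsed_seconds(record$time_before, record$scan_time) >= 0)
                            "forward" else "back",
                          lambda_per_s)
  after <- decay_correct(record$activity_after_bq,
                         abs(elapsed_seconds(record$time_after, record$scan_time)),
                         if (elapsed_seconds(record$time_after, record$scan_time) >= 0)
                           "forward" else "back",
                         lambda_per_s)
  inj <- before - after
  if (inj < 0) stop("negative injected activity after decay correction; ",
                    "inconsistent measurements")
  sa <- specific_activity_at_scan(record, lambda_per_s)
  ms_mg <- inj / sa
  list(injected_bq = inj, injected_ms_mg = ms_mg,
       injected_ho_mg = ms_mg * record$ho_content_fraction)
}

#' Reference-tissue statistics
#'
#' Baseline radiodensity of tissue without microspheres, measured in a
#' reference VOI on the pre-injection scan (or, when the baselines differ
#' significantly between scans, on microsphere-free tissue of the
#' post-injection scan).
#'
#' @param mean_hu,sd_hu reference VOI mean and SD (HU).
#' @param source `"pre"` or `"post"`: which scan the reference VOI was
#'   measured on.
#' @return An object of class `reference_stats`.
#' @export
reference_stats <- function(mean_hu, sd_hu, source = c("pre", "post")) {
  source <- match.arg(source)
  if (sd_hu < 0) stop("sd must be >= 0")
  structure(list(hu_reference = mean_hu, sd = sd_hu, source = source),
            class = "reference_stats")
}

#' Reference stats from a volume and VOI
#' @param volume a [ct_volume].
#' @param mask a [voi_mask].
#' @inheritParams reference_stats
#' @return A `reference_stats`.
#' @export
reference_stats_from_voi <- function(volume, mask, source = c("pre", "post")) {
  st <- voi_stats(volume, mask)
  reference_stats(st$mean_hu, st$sd_hu, source)
}

new_quant_result <- function(grid, huho, contributing, method, variant,
                             effective_threshold = NA_real_) {
  structure(list(grid = grid, huho_map = huho, contributing = contributing,
                 method = method, variant = variant,
                 effective_threshold = effective_threshold,
                 concentration_map = NULL, activity_map = NULL,
                 total_ho_mg = NA_real_, total_ms_mg = NA_real_,
                 total_bq = NA_real_),
            class = "quant_result")
}

#' Subtraction quantification
#'
#' Per VOI voxel, `HU_Ho = Post HU_voxel - HU_reference`. Variants:
#' \describe{
#'   \item{`"s-minus"`}{all voxels contribute, negative `HU_Ho` included;}
#'   \item{`"s"`}{post values below 0 HU are set to 0 before subtraction
#'     (so `HU_Ho >= -HU_reference`); all voxels contribute;}
#'   \item{`"s-plus"`}{voxels with `HU_Ho < 0` are removed from the
#'     contributing mask.}
#' }
#'
#' @param post post-injection [ct_volume].
#' @param voi quantification [voi_mask].
#' @param ref a [reference_stats].
#' @param variant `"s-minus"`, `"s"` or `"s-plus"`.
#' @return A `quant_result` with the `HU_Ho` map (NA outside the
#'   contributing mask) and the contributing [voi_mask].
#' @export
quantify_subtraction <- function(post, voi, ref, variant = c("s-minus", "s", "s-plus")) {
  variant <- match.arg(variant)
  stop_if_grid_mismatch(post$grid, voi$grid, "post volume and VOI")
  if (!any(voi$included)) stop("quantification VOI is empty")
  pv <- post$values
  if (variant == "s") pv <- pmax(pv, 0)
  huho <- array(NA_real_, post$grid$shape)
  huho[voi$included] <- pv[voi$included] - ref$hu_reference
  contributing <- voi$included
  if (variant == "s-plus") {
    drop <- voi$included & !is.na(huho) & huho < 0
    contributing <- contributing & !drop
    huho[drop] <- NA_real_
  }
  new_quant_result(post$grid, huho, voi_mask(contributing, post$grid),
                   method = "subtraction", variant = variant)
}

threshold_kinds <- c("t", "t1sd", "t2sd", "t3sd", "t50", "t100")

#' Threshold quantification
#'
#' Voxels whose post-injection HU strictly exceeds the threshold
#' contribute, and their `HU_Ho` is the full post voxel value. Thresholds:
#' `"t"` the reference mean; `"t1sd"`..`"t3sd"` the reference mean plus
#' 1-3 SD; `"t50"`/`"t100"` fixed 50 or 100 HU. When the calibration
#' intercept is applied (curve not forced through zero), the effective
#' threshold is raised to at least the intercept so that no voxel can map
#' to a negative concentration.
#'
#' @param post post-injection [ct_volume].
#' @param voi quantification [voi_mask].
#' @param kind one of `"t"`, `"t1sd"`, `"t2sd"`, `"t3sd"`, `"t50"`, `"t100"`.
#' @param ref a [reference_stats]; required for the reference-based kinds.
#' @param curve a `calibration_curve`; its intercept sets the minimal
#'   threshold unless forced through zero.
#' @return A `quant_result` with `effective_threshold` recorded.
#' @export
quantify_threshold <- function(post, voi, kind = threshold_kinds, ref = NULL,
                               curve = NULL) {
  kind <- match.arg(kind)
  stop_if_grid_mismatch(post$grid, voi$grid, "post volume and VOI")
  if (!any(voi$included)) stop("quantification VOI is empty")
  thr <- switch(kind,
                t = ref$hu_reference,
                t1sd = ref$hu_reference + 1 * ref$sd,
                t2sd = ref$hu_reference + 2 * ref$sd,
                t3sd = ref$hu_reference + 3 * ref$sd,
                t50 = 50,
                t100 = 100)
  if (is.null(thr)) stop("reference stats required for threshold kind ", kind)
  eff <- thr
  if (!is.null(curve) && !curve$forced_zero)
    eff <- max(thr, curve$intercept_m)
  contributing <- voi$included & post$values > eff
  huho <- array(NA_real_, post$grid$shape)
  huho[contributing] <- post$values[contributing]
  new_quant_result(post$grid, huho, voi_mask(contributing, post$grid),
                   method = "threshold", variant = kind,
                   effective_threshold = eff)
}

#' Convert a quantification result to concentrations
#'
#' Threshold results convert the full voxel HU through the calibration,
#' `c = (HU_Ho - m) / b` (`m = 0` for forced-zero curves). Subtraction
#' results have the baseline already removed by the measured reference, so
#' only the slope applies, `c = HU_Ho / b`; subtracting the fitted
#' intercept as well would remove baseline twice. Negative concentrations
#' can occur (and are kept) only under the `s-minus`/`s` variants.
#'
#' @param result a `quant_result`.
#' @param curve a `calibration_curve`.
#' @return The result with `concentration_map` (mg Ho/mL, NA outside the
#'   contributing mask) and `total_ho_mg` filled in.
#' @export
concentration_map <- function(result, curve) {
  conc <- array(NA_real_, result$grid$shape)
  inc <- result$contributing$included
  if (result$method == "threshold") {
    conc[inc] <- (result$huho_map[inc] - curve$intercept_m) / curve$slope_b
  } else {
    conc[inc] <- result$huho_map[inc] / curve$slope_b
  }
  result$concentration_map <- conc
  result$total_ho_mg <- sum(conc[inc]) * voxel_volume_ml(result$grid)
  result$curve_used <- list(intercept_m = curve$intercept_m, slope_b = curve$slope_b,
                            forced_zero = curve$forced_zero)
  result
}

#' Convert concentrations to a radioactivity map
#'
#' Per voxel: elemental-Ho mass is `c * V_voxel` (mL), microsphere mass
#' follows by dividing by the Ho content fraction, and activity by
#' multiplying with the specific activity referred to the scan time.
#'
#' @param result a `quant_result` that already has a concentration map.
#' @param record an [injection_record].
#' @param lambda_per_s decay constant used to refer the specific activity
#'   to the scan time.
#' @return The result with `activity_map` (Bq per voxel), `total_ms_mg` and
#'   `total_bq` filled in.
#' @export
activity_map <- function(result, record, lambda_per_s = ho166_lambda_per_s()) {
  if (is.null(result$concentration_map))
    stop("call concentration_map() before activity_map()")
  sa <- specific_activity_at_scan(record, lambda_per_s)
  vml <- voxel_volume_ml(result$grid)
  inc <- result$contributing$included
  act <- array(NA_real_, result$grid$shape)
  act[inc] <- result$concentration_map[inc] * vml / record$ho_content_fraction * sa
  result$activity_map <- act
  result$total_ms_mg <- result$total_ho_mg / record$ho_content_fraction
  result$total_bq <- result$total_ms_mg * sa
  result
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("quant_result: %s (%s)\n", x$method, x$variant))
  if (!is.na(x$effective_threshold))
    cat(sprintf("  effective threshold: %.2f HU\n", x$effective_threshold))
  cat(sprintf("  contributing voxels: %d\n", mask_n_voxels(x$contributing)))
  if (!is.na(x$total_ho_mg))
    cat(sprintf("  total: %.4g mg Ho", x$total_ho_mg))
  if (!is.na(x$total_ms_mg))
    cat(sprintf(" = %.4g mg Ho-MS, %.4g Bq", x$total_ms_mg, x$total_bq))
  if (!is.na(x$total_ho_mg)) cat("\n")
  invisible(x)
}

#' Ho recovery
#'
#' Quantified over injected amount in percent; recoveries between 70 and
#' 130% are deemed sufficient for further analysis.
#'
#' @param result a `quant_result` with totals filled in (after
#'   [concentration_map]; microsphere mass requires [activity_map] or
#'   `ho_content_fraction`).
#' @param injected_ms_mg injected microsphere mass (mg); > 0.
#' @param ho_content_fraction used to derive microsphere mass if
#'   [activity_map] has not been applied.
#' @return List with `recovery_percent` and logical `sufficient`.
#' @export
recovery <- function(result, injected_ms_mg, ho_content_fraction = 0.197) {
  if (injected_ms_mg <= 0) stop("injected amount must be positive")
  ms <- result$total_ms_mg
  if (is.na(ms)) {
    if (is.na(result$total_ho_mg))
      stop("result has no totals; call concentration_map() first")
    ms <- result$total_ho_mg / ho_content_fraction
  }
  pct <- 100 * ms / injected_ms_mg
  list(recovery_percent = pct, sufficient = pct >= 70 && pct <= 130)
}

#' Ho volume fraction
#'
#' Percentage of quantification-VOI voxels contributing to the recovery.
#' All voxels contribute under `s-minus` (100%); thresholds select a
#' fraction.
#'
#' @param result a `quant_result`.
#' @param voi the quantification [voi_mask] the result was computed over.
#' @return Percentage in `[0, 100]`.
#' @export
volume_fraction <- function(result, voi) {
  n <- mask_n_voxels(voi)
  if (n == 0L) stop("quantification VOI is empty")
  100 * mask_n_voxels(result$contributing) / n
}

#' Ellipsoid tumor volume from orthogonal diameters
#'
#' `V = pi/6 * length * width * height`, the standard ellipsoid estimate
#' from the largest diameters measured on pretreatment CT.
#'
#' @param length_cm,width_cm,height_cm diameters in cm; all > 0.
#' @return Volume in cm^3.
#' @examples
#' ellipsoid_volume(2, 2, 2)  # sphere of diameter 2 cm: 4.19 cm^3
#' @export
ellipsoid_volume <- function(length_cm, width_cm, height_cm) {
  if (any(c(length_cm, width_cm, height_cm) <= 0))
    stop("all dimensions must be positive")
  pi / 6 * length_cm * width_cm * height_cm
}
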