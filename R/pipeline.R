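#' Run the quantification-dosimetry pipeline
#'
#' Executes the full chain: read volumes and masks, measure the reference
#' VOI, quantify microspheres in the quantification VOI (subtraction or
#' thresholding), convert to concentration and activity maps, compute
#' recovery and volume fraction, and optionally convolve with a dose point
#' kernel to produce a cumulative dose map and DVH. Outputs are written to
#' `out_dir` as NIfTI maps, a DVH CSV and a JSON summary whose field names
#' carry units (`_mg`, `_bq`, `_gy`).
#'
#' Calibration curves are scanner-specific; if both the curve metadata and
#' the post volume metadata name a scanner and they differ, the run is
#' refused unless `allow_metadata_mismatch` is set.
#'
#' @param config named list (or path to a JSON/YAML-free JSON config file)
#'   with elements:
#'   \describe{
#'     \item{pre, post}{[ct_volume] objects or NIfTI/DICOM paths (pre is
#'       optional when `ref_stats` is given).}
#'     \item{voi, ref_voi}{[voi_mask] objects or NIfTI label paths.}
#'     \item{ref_stats}{optional precomputed [reference_stats].}
#'     \item{ref_source}{`"pre"` (default) or `"post"`: which scan the
#'       reference VOI is measured on.}
#'     \item{curve}{`calibration_curve` or JSON path.}
#'     \item{method}{one of `s-minus`, `s`, `s-plus`, `t`, `t1sd`, `t2sd`,
#'       `t3sd`, `t50`, `t100`.}
#'     \item{injection}{[injection_record], or list of its fields.}
#'     \item{kernel}{optional `dose_point_kernel` or kernel base path;
#'       enables dose estimation.}
#'     \item{dvh_mask}{optional [voi_mask] or path; defaults to `voi`.}
#'     \item{out_dir}{optional output directory; no files written if `NULL`.}
#'     \item{allow_metadata_mismatch}{logical, default `FALSE`.}
#'     \item{seed}{optional RNG seed set before any stochastic stage.}
#'   }
#' @return A list with the `quant_result`, `summary` (named scalars),
#'   and, when a kernel is supplied, `dose` and `dvh`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  as_volume <- function(x) if (inherits(x, "ct_volume")) x else read_ct_volume(x)
  as_mask <- function(x, grid) {
    if (inherits(x, "voi_mask")) x else read_voi_mask(x, grid)
  }
  method <- match.arg(config$method,
                      c("s-minus", "s", "s-plus", threshold_kinds))
  post <- stage("read post volume", as_volume(config$post))
  voi <- stage("read quantification VOI", as_mask(config$voi, post$grid))
  curve <- stage("read calibration curve", {
    if (inherits(config$curve, "calibration_curve")) config$curve
    else read_calibration_curve(config$curve)
  })
  cs <- curve$metadata$scanner
  vs <- post$metadata$scanner
  if (!is.null(cs) && !is.null(vs) && !identical(cs, vs) &&
      !isTRUE(config$allow_metadata_mismatch))
    stop("calibration curve was fitted on scanner '", cs,
         "' but the volume is from '", vs,
         "'; calibration parameters are not interchangeable between scanners ",
         "(set allow_metadata_mismatch to override)")

  ref <- config$ref_stats
  if (is.null(ref)) {
    src <- if (is.null(config$ref_source)) "pre" else config$ref_source
    ref_vol <- if (src == "pre") stage("read pre volume", as_volume(config$pre))
               else post
    ref_voi <- stage("read reference VOI", as_mask(config$ref_voi, ref_vol$grid))
    ref <- stage("reference statistics",
                 reference_stats_from_voi(ref_vol, ref_voi, src))
  }

  result <- stage("quantification", {
    if (method %in% c("s-minus", "s", "s-plus"))
      quantify_subtraction(post, voi, ref, method)
    else
      quantify_threshold(post, voi, method, ref, curve)
  })
  result <- stage("concentration conversion", concentration_map(result, curve))

  record <- config$injection
  if (!is.null(record) && !inherits(record, "injection_record"))
    record <- do.call(injection_record, record)
  summary <- list(method = method,
                  reference_hu = ref$hu_reference,
                  reference_sd_hu = ref$sd,
                  reference_source = ref$source,
                  effective_threshold_hu = result$effective_threshold,
                  curve_intercept_hu = curve$intercept_m,
                  curve_slope_hu_per_mg_ml = curve$slope_b,
                  curve_forced_zero = curve$forced_zero,
                  n_voi_voxels = mask_n_voxels(voi),
                  n_contributing_voxels = mask_n_voxels(result$contributing),
                  volume_fraction_percent = volume_fraction(result, voi),
                  total_ho_mg = result$total_ho_mg)
  if (!is.null(record)) {
    result <- stage("activity conversion", activity_map(result, record))
    inj <- stage("injected amount", injected_amount(record))
    rec <- recovery(result, inj$injected_ms_mg)
    summary <- c(summary,
                 list(total_ms_mg = result$total_ms_mg,
                      total_bq = result$total_bq,
                      injected_ms_mg = inj$injected_ms_mg,
                      injected_bq = inj$injected_bq,
                      recovery_percent = rec$recovery_percent,
                      recovery_sufficient = rec$sufficient))
  }

  out <- list(result = result, summary = summary, reference = ref)

  if (!is.null(config$kernel)) {
    if (is.null(result$activity_map))
      stop("dose estimation requires an injection record (activity map)")
    kernel <- stage("load kernel", {
      if (inherits(config$kernel, "dose_point_kernel")) config$kernel
      else load_dpk(config$kernel)
    })
    act <- result$activity_map
    act[is.na(act)] <- 0
    act_map <- list(values = act, grid = result$grid)
    act_k <- stage("match activity to kernel grid",
                   match_to_kernel_grid(act_map, kernel))
    erate <- stage("dose-rate convolution", convolve_dose_rate(act_k, kernel))
    dose <- stage("cumulative dose",
                  cumulative_dose_map(erate, kernel$medium_density))
    dvh_mask <- if (!is.null(config$dvh_mask))
      as_mask(config$dvh_mask, post$grid) else voi
    # express the DVH mask on the dose grid
    dmask <- stage("DVH", {
      mk <- resample_trilinear(list(values = dvh_mask$included * 1,
                                    grid = dvh_mask$grid), dose$grid)
      dvh(dose, voi_mask(mk$values > 0.5, dose$grid))
    })
    summary$mean_dose_gy <- mean(dose$dose_gy[
      resample_trilinear(list(values = dvh_mask$included * 1,
                              grid = dvh_mask$grid), dose$grid)$values > 0.5])
    summary$kernel_total_ev <- sum(kernel$energy_ev)
    out$dose <- dose
    out$dvh <- dmask
    out$summary <- summary
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wd <- function(v, name) write_nifti_volume(
      list(values = v, grid = result$grid), file.path(config$out_dir, name))
    hu <- result$huho_map; hu[is.na(hu)] <- 0
    wd(hu, "huho_map.nii.gz")
    cm <- result$concentration_map; cm[is.na(cm)] <- 0
    wd(cm, "concentration_mg_per_ml.nii.gz")
    write_nifti_volume(result$contributing,
                       file.path(config$out_dir, "contributing_mask.nii.gz"))
    if (!is.null(result$activity_map)) {
      am <- result$activity_map; am[is.na(am)] <- 0
      wd(am, "activity_bq.nii.gz")
    }
    if (!is.null(out$dose)) {
      write_nifti_volume(list(values = out$dose$dose_gy, grid = out$dose$grid),
                         file.path(config$out_dir, "dose_gy.nii.gz"))
      utils::write.csv(out$dvh, file.path(config$out_dir, "dvh.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
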