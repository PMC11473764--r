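#' Synthetic calibration tube phantom
#'
#' Generates a CT volume of parallel tubes (axis z) with known Ho
#' concentrations on a linear HU response: voxel HU is
#' `m + b * c + N(0, noise_sd)` inside a tube and
#' `background_hu + N(0, noise_sd)` outside, clipped to the scanner's
#' representable range. Defaults mirror a HoCl tube phantom: 19
#' concentrations from 0 to 129 mg/mL in 17 mm tubes of 30 mm length,
#' analysed through 11 mm cylindrical masks, on a 12-bit scanner
#' (saturation at 3071 HU).
#'
#' @param concentrations mg Ho/mL per tube.
#' @param curve forward-model `calibration_curve`.
#' @param noise_sd Gaussian HU noise SD per voxel.
#' @param background_hu HU outside the tubes (air-like by default).
#' @param tube_diameter_mm,tube_length_mm physical tube geometry.
#' @param mask_diameter_mm diameter of the analysis masks.
#' @param spacing_mm voxel spacing.
#' @param hu_limits representable HU range; values are clipped to it.
#' @param seed optional RNG seed.
#' @return List with `volume` (a [ct_volume]), `masks` (one [voi_mask] per
#'   tube, the analysis cylinders), and `truth` (data.frame of tube
#'   concentrations, expected HU and a `saturated` flag marking tubes whose
#'   noise-free HU exceeds the upper limit).
#' @export
simulate_calibration_phantom <- function(concentrations = c(0, 0.5, 1, 2, 3, 4.6,
                                                            6, 9.7, 13, 17, 21.8,
                                                            27, 33, 43.6, 54, 66,
                                                            80, 104, 129),
                                         curve = calibration_curve(26.36, 29.89),
                                         noise_sd = 15,
                                         background_hu = -1000,
                                         tube_diameter_mm = 17,
                                         tube_length_mm = 30,
                                         mask_diameter_mm = 11,
                                         spacing_mm = c(0.5, 0.5, 1),
                                         hu_limits = c(-1024, 3071),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(concentrations)
  pitch <- tube_diameter_mm + 4
  ncol_t <- ceiling(sqrt(n))
  nrow_t <- ceiling(n / ncol_t)
  fov_x <- ncol_t * pitch + 8
  fov_y <- nrow_t * pitch + 8
  shape <- c(ceiling(fov_x / spacing_mm[1]), ceiling(fov_y / spacing_mm[2]),
             ceiling(tube_length_mm / spacing_mm[3]))
  grid <- voxel_grid(spacing_mm, shape)
  centers <- lapply(seq_len(n) - 1L, function(i) {
    cx <- (i %% ncol_t) * pitch + pitch / 2 + 4
    cy <- (i %/% ncol_t) * pitch + pitch / 2 + 4
    c(cx, cy, (shape[3] - 1) * spacing_mm[3] / 2)
  })
  # overlap guard (centres are laid out on a pitch > diameter, but the
  # arguments allow overriding geometry)
  if (pitch < tube_diameter_mm)
    stop("tubes overlap: pitch smaller than tube diameter")
  vals <- array(background_hu, shape)
  expected <- predict_hu(curve, concentrations)
  for (i in seq_len(n)) {
    tube <- make_cylinder_mask(grid, centers[[i]], tube_diameter_mm,
                               tube_length_mm, axis = "z")
    vals[tube$included] <- expected[i]
  }
  if (noise_sd > 0)
    vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd), shape)
  vals <- pmin(pmax(vals, hu_limits[1]), hu_limits[2])
  vol <- ct_volume(vals, grid, hu_limits,
                   metadata = list(phantom = "calibration_tubes",
                                   noise_sd = noise_sd))
  masks <- lapply(centers, function(cc)
    make_cylinder_mask(grid, cc, mask_diameter_mm, tube_length_mm, axis = "z"))
  truth <- data.frame(tube = seq_len(n),
                      concentration_mg_per_ml = concentrations,
                      expected_hu = expected,
                      saturated = expected > hu_limits[2])
  list(volume = vol, masks = masks, truth = truth)
}

#' Synthetic injection-sample phantom
#'
#' Emulates a 5 x 5 x 4 cm tissue sample before and after a localized
#' microsphere injection. The pre-injection volume is uniform background
#' tissue plus noise; the post-injection volume adds the deposit's HU
#' (concentration mapped through the calibration slope, additive over the
#' baseline) inside a uniform sphere of the stated injected volume. An
#' optional baseline shift emulates radiodensity differences between
#' scans. Defaults correspond to injecting 7.5 mg of 19.7 % Ho
#' microspheres in 0.3 mL.
#'
#' @param injected_ms_mg injected microsphere mass (mg); > 0.
#' @param deposit_volume_ml injected volume (mL) forming a uniform sphere.
#' @param ho_content_fraction elemental-Ho mass fraction of the spheres.
#' @param curve forward-model `calibration_curve` (slope converts
#'   concentration to HU above baseline).
#' @param background_hu baseline tissue HU.
#' @param baseline_shift_hu HU added to the post-injection background
#'   (0 = stable baseline).
#' @param noise_sd Gaussian HU noise SD.
#' @param sample_size_mm sample dimensions (x, y, z) in mm.
#' @param spacing_mm voxel spacing.
#' @param deposit_center_mm deposit centre; default the sample centre.
#' @param hu_limits representable range for clipping.
#' @param smooth_sigma_mm optional isotropic Gaussian blur of the deposit
#'   edge (0 = sharp partial-volume-free edges).
#' @param seed optional RNG seed.
#' @return List with `pre`, `post` ([ct_volume]s), `voi` (sample-wide
#'   quantification [voi_mask]), `deposit_mask`, and `truth` (injected
#'   masses, deposit concentration, per-voxel truth concentration map).
#' @export
simulate_injection_phantom <- function(injected_ms_mg = 7.5,
                                       deposit_volume_ml = 0.3,
                                       ho_content_fraction = 0.197,
                                       curve = calibration_curve(26.36, 29.89),
                                       background_hu = 40,
                                       baseline_shift_hu = 0,
                                       noise_sd = 10,
                                       sample_size_mm = c(50, 50, 40),
                                       spacing_mm = c(1, 1, 1),
                                       deposit_center_mm = NULL,
                                       hu_limits = c(-1024, 3071),
                                       smooth_sigma_mm = 0,
                                       seed = NULL) {
  if (injected_ms_mg <= 0) stop("deposit mass must be positive")
  if (!is.null(seed)) set.seed(seed)
  shape <- as.integer(ceiling(sample_size_mm / spacing_mm))
  grid <- voxel_grid(spacing_mm, shape)
  if (is.null(deposit_center_mm))
    deposit_center_mm <- (shape - 1) / 2 * spacing_mm
  r_mm <- (3 * deposit_volume_ml * 1000 / (4 * pi))^(1 / 3)
  ax <- lapply(1:3, function(k) grid_axis_mm(grid, k) - deposit_center_mm[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  inside <- r2 <= r_mm^2
  if (!any(inside)) stop("deposit smaller than one voxel at this spacing")
  ho_mg <- injected_ms_mg * ho_content_fraction
  # uniform concentration chosen so the voxelised deposit integrates to the
  # injected mass exactly
  conc <- ho_mg / (sum(inside) * voxel_volume_ml(grid))
  conc_map <- array(0, shape)
  conc_map[inside] <- conc
  if (smooth_sigma_mm > 0)
    conc_map <- gaussian_blur3(conc_map, smooth_sigma_mm / spacing_mm)
  pre_vals <- array(background_hu, shape)
  post_vals <- background_hu + baseline_shift_hu + curve$slope_b * conc_map
  if (noise_sd > 0) {
    pre_vals <- pre_vals + array(stats::rnorm(length(pre_vals), 0, noise_sd), shape)
    post_vals <- post_vals + array(stats::rnorm(length(post_vals), 0, noise_sd), shape)
  }
  pre_vals <- pmin(pmax(pre_vals, hu_limits[1]), hu_limits[2])
  post_vals <- pmin(pmax(post_vals, hu_limits[1]), hu_limits[2])
  md <- list(phantom = "injection_sample", noise_sd = noise_sd)
  voi <- voi_mask(array(TRUE, shape), grid)
  list(pre = ct_volume(pre_vals, grid, hu_limits, md),
       post = ct_volume(post_vals, grid, hu_limits, md),
       voi = voi,
       deposit_mask = voi_mask(inside, grid),
       truth = list(injected_ms_mg = injected_ms_mg,
                    injected_ho_mg = ho_mg,
                    deposit_concentration_mg_per_ml = conc,
                    deposit_volume_ml = sum(inside) * voxel_volume_ml(grid),
                    background_hu = background_hu,
                    baseline_shift_hu = baseline_shift_hu,
                    concentration_map = conc_map))
}

#' Synthetic patient-like phantom
#'
#' An ellipsoidal tumor in soft-tissue background with hyperdense
#' (bone-like) distractor structures outside the quantification VOI and
#' multifocal Gaussian microsphere deposits inside the tumor. The planned
#' amount follows the dosing rule of 5.0 mg microspheres per cm^3 tumor.
#'
#' @param tumor_diameters_cm tumor (length, width, height) in cm.
#' @param ms_mg_per_cm3 planned microsphere mass per cm^3 tumor volume.
#' @param n_foci number of injection foci.
#' @param focus_sigma_mm Gaussian spatial SD of each focus.
#' @param curve,background_hu,noise_sd,spacing_mm,hu_limits as in
#'   [simulate_injection_phantom].
#' @param bone_hu HU of the distractor structures.
#' @param ho_content_fraction elemental-Ho fraction of the microspheres.
#' @param seed optional RNG seed.
#' @return List with `pre`, `post`, `voi` (the tumor ellipsoid), `truth`
#'   (tumor volume cm^3, planned and actual mg, concentration map), and
#'   `distractor_mask`.
#' @export
simulate_patient_like <- function(tumor_diameters_cm = c(2, 2, 2),
                                  ms_mg_per_cm3 = 5.0,
                                  n_foci = 3,
                                  focus_sigma_mm = 3,
                                  curve = calibration_curve(26.36, 29.89),
                                  background_hu = 40,
                                  noise_sd = 10,
                                  spacing_mm = c(1, 1, 1),
                                  hu_limits = c(-1024, 3071),
                                  bone_hu = 1000,
                                  ho_content_fraction = 0.197,
                                  seed = NULL) {
  if (any(tumor_diameters_cm <= 0)) stop("tumor diameters must be positive")
  if (!is.null(seed)) set.seed(seed)
  d_mm <- tumor_diameters_cm * 10
  fov <- d_mm + 30
  shape <- as.integer(ceiling(fov / spacing_mm))
  grid <- voxel_grid(spacing_mm, shape)
  center <- (shape - 1) / 2 * spacing_mm
  ax <- lapply(1:3, function(k) (grid_axis_mm(grid, k) - center[k]) / (d_mm[k] / 2))
  e2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  tumor <- e2 <= 1
  tumor_vol_cm3 <- ellipsoid_volume(tumor_diameters_cm[1], tumor_diameters_cm[2],
                                    tumor_diameters_cm[3])
  planned_ms_mg <- ms_mg_per_cm3 * tumor_vol_cm3
  # multifocal deposits: equal-mass isotropic Gaussian blobs inside the tumor
  conc_map <- array(0, shape)
  foci <- replicate(n_foci, center + (stats::runif(3) - 0.5) * d_mm * 0.4)
  per_focus_ho_mg <- planned_ms_mg * ho_content_fraction / n_foci
  for (i in seq_len(n_foci)) {
    fc <- foci[, i]
    dx <- lapply(1:3, function(k) grid_axis_mm(grid, k) - fc[k])
    g2 <- outer(outer(dx[[1]]^2, dx[[2]]^2, "+"), dx[[3]]^2, "+")
    blob <- exp(-g2 / (2 * focus_sigma_mm^2))
    blob[!tumor] <- 0
    blob <- blob / (sum(blob) * voxel_volume_ml(grid)) * per_focus_ho_mg
    conc_map <- conc_map + blob
  }
  # bone-like distractors in a corner, outside the tumor VOI
  bone <- array(FALSE, shape)
  nb <- pmax(2L, as.integer(shape * 0.08))
  bone[seq_len(nb[1]), seq_len(nb[2]), ] <- TRUE
  bone[tumor] <- FALSE
  pre_vals <- array(background_hu, shape)
  pre_vals[bone] <- bone_hu
  post_vals <- pre_vals + curve$slope_b * conc_map
  if (noise_sd > 0) {
    pre_vals <- pre_vals + array(stats::rnorm(length(pre_vals), 0, noise_sd), shape)
    post_vals <- post_vals + array(stats::rnorm(length(post_vals), 0, noise_sd), shape)
  }
  pre_vals <- pmin(pmax(pre_vals, hu_limits[1]), hu_limits[2])
  post_vals <- pmin(pmax(post_vals, hu_limits[1]), hu_limits[2])
  md <- list(phantom = "patient_like", noise_sd = noise_sd)
  list(pre = ct_volume(pre_vals, grid, hu_limits, md),
       post = ct_volume(post_vals, grid, hu_limits, md),
       voi = voi_mask(tumor, grid),
       distractor_mask = voi_mask(bone, grid),
       truth = list(tumor_volume_cm3 = tumor_vol_cm3,
                    planned_ms_mg = planned_ms_mg,
                    injected_ms_mg = planned_ms_mg,
                    injected_ho_mg = planned_ms_mg * ho_content_fraction,
                    concentration_map = conc_map))
}

## Separable Gaussian blur; sigma in voxels per axis.
gaussian_blur3 <- function(x, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    x <- apply_conv_axis(x, k, axis)
  }
  x
}

apply_conv_axis <- function(x, k, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dm <- dim(xp)
  m <- matrix(xp, nrow = dm[1])
  r <- (length(k) - 1L) / 2L
  pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * pad[(i - 1) + seq_len(nrow(m)), , drop = FALSE]
  dim(out) <- dm
  aperm(out, order(perm))
}
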