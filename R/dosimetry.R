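#' 166Ho emission spectrum
#'
#' Default decay data for the dose-point-kernel generator: the two
#' high-energy beta branches (endpoint 1.77 MeV at 49.9 % and 1.85 MeV at
#' 48.8 % per decay), the 0.08 MeV gamma line at 6.6 %, the erbium K
#' x-ray line populated by internal conversion, and a lumped
#' conversion/Auger electron component deposited locally at the source
#' voxel (sub-voxel ranges at this grid). Transport cuts off at 1 keV.
#'
#' @param beta_branches two-column matrix: endpoint energy (MeV), yield per
#'   decay.
#' @param photon_lines two-column matrix: energy (MeV), yield per decay.
#' @param local_mean_energy_mev,local_yield lumped locally-deposited
#'   electron component (mean energy per decay when multiplied by yield).
#' @param cutoff_kev transport energy cutoff; >= 1 keV.
#' @return An object of class `emission_spectrum`.
#' @export
ho166_spectrum <- function(beta_branches = cbind(endpoint_mev = c(1.77, 1.85),
                                                 yield = c(0.499, 0.488)),
                           photon_lines = cbind(energy_mev = c(0.0806, 0.0482),
                                                yield = c(0.066, 0.118)),
                           local_mean_energy_mev = 0.0215, local_yield = 1.0,
                           cutoff_kev = 1) {
  emission_spectrum(beta_branches, photon_lines, local_mean_energy_mev,
                    local_yield, cutoff_kev)
}

#' @rdname ho166_spectrum
#' @export
emission_spectrum <- function(beta_branches, photon_lines = NULL,
                              local_mean_energy_mev = 0, local_yield = 0,
                              cutoff_kev = 1) {
  beta_branches <- matrix(as.numeric(beta_branches), ncol = 2,
                          dimnames = list(NULL, c("endpoint_mev", "yield")))
  if (is.null(photon_lines) || length(photon_lines) == 0)
    photon_lines <- matrix(numeric(0), ncol = 2)
  photon_lines <- matrix(as.numeric(photon_lines), ncol = 2,
                         dimnames = list(NULL, c("energy_mev", "yield")))
  if (any(beta_branches[, 2] < 0) || any(photon_lines[, 2] < 0) || local_yield < 0)
    stop("yields must be >= 0")
  if (cutoff_kev < 1) stop("energy cutoff must be >= 1 keV")
  structure(list(beta_branches = beta_branches, photon_lines = photon_lines,
                 local_mean_energy_mev = local_mean_energy_mev,
                 local_yield = local_yield, cutoff_kev = cutoff_kev),
            class = "emission_spectrum")
}

#' Total emitted energy per decay of a spectrum
#'
#' Mean beta energies are integrated over the sampled (Fermi-corrected
#' allowed) spectral shapes; photon and lumped components contribute
#' energy times yield.
#'
#' @param spectrum an `emission_spectrum`.
#' @return Energy in MeV per decay.
#' @export
spectrum_total_energy_mev <- function(spectrum) {
  beta <- 0
  for (i in seq_len(nrow(spectrum$beta_branches))) {
    q <- spectrum$beta_branches[i, 1]
    y <- spectrum$beta_branches[i, 2]
    if (q > 0 && y > 0) {
      E <- seq(1e-4, q - 1e-4, length.out = 2000)
      w <- beta_spectrum_shape(E, q)
      beta <- beta + y * sum(w * E) / sum(w)
    }
  }
  photons <- sum(spectrum$photon_lines[, 1] * spectrum$photon_lines[, 2])
  beta + photons + spectrum$local_mean_energy_mev * spectrum$local_yield
}

## Allowed beta shape with the relativistic Fermi function (daughter Z = 68).
## Energies in MeV (kinetic).
beta_spectrum_shape <- function(E, endpoint_mev, Z = 68, A_mass = 166) {
  me <- 0.51099895
  alpha <- 1 / 137.035999
  W <- (E + me) / me
  p <- sqrt(pmax(W^2 - 1, 0))
  gam <- sqrt(1 - (alpha * Z)^2)
  eta <- alpha * Z * W / p
  # |Gamma(gam + i eta)|^2 / Gamma(gam)^2 via the product representation
  gmod <- vapply(eta, function(y) {
    k <- 0:4000
    exp(sum(-log1p((y / (gam + k))^2)))
  }, 0)
  Rnuc <- 1.2e-15 * A_mass^(1 / 3) / 3.8616e-13  # nuclear radius / (hbar/me c)
  Ferm <- 2 * (1 + gam) * (2 * p * Rnuc)^(2 * gam - 2) * exp(pi * eta) *
    gmod * gamma(gam)^2 / gamma(2 * gam + 1)^2
  s <- p * W * ((endpoint_mev - E) / me)^2 * Ferm
  s[!is.finite(s) | E <= 0 | E >= endpoint_mev] <- 0
  s
}

## Katz-Penfold CSDA range in g/cm^2 (E in MeV), valid ~0.01-2.5 MeV.
csda_range_g_cm2 <- function(E) 0.412 * E^(1.265 - 0.0954 * log(E))

## NIST mass attenuation of water, cm^2/g (photon energy MeV).
water_mu_rho_table <- function() {
  cbind(energy_mev = c(0.01, 0.015, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.1,
                       0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0, 1.25, 1.5, 2.0),
        mu_rho = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
                   0.1837, 0.1707, 0.1505, 0.137, 0.1186, 0.1061, 0.0969,
                   0.0896, 0.0786, 0.0707, 0.063, 0.0575, 0.0494))
}

#' Default kernel grid
#'
#' 121 x 121 x 61 voxels at 0.5 x 0.5 x 1.0 mm resolution with the source
#' in the central voxel.
#'
#' @return A [voxel_grid] centred on the origin.
#' @export
dpk_default_grid <- function() {
  shape <- c(121L, 121L, 61L)
  spacing <- c(0.5, 0.5, 1.0)
  voxel_grid(spacing, shape, origin_mm = -(shape - 1) / 2 * spacing)
}

new_dpk <- function(energy_ev, grid, density, provenance) {
  structure(list(energy_ev = energy_ev, grid = grid,
                 center_index = (grid$shape + 1L) %/% 2L,
                 medium_density = density, provenance = provenance),
            class = "dose_point_kernel")
}

#' @export
print.dose_point_kernel <- function(x, ...) {
  cat("dose_point_kernel\n")
  print(x$grid)
  cat(sprintf("  total energy per decay: %.4g keV; density %.3g kg/L\n",
              sum(x$energy_ev) / 1e3, x$medium_density))
  cat(sprintf("  energy within 3 mm: %.1f%%\n",
              100 * kernel_radial_fraction(x, 3)))
  invisible(x)
}

#' Generate a 166Ho dose point kernel by Monte Carlo transport
#'
#' Simulates `n_histories` decays of a point source at the centre of an
#' odd-sized voxel grid in a uniform medium and tallies the expected energy
#' deposited per decay in each voxel (eV). Electrons follow a class-II
#' condensed-history transport: energies sampled from Fermi-corrected
#' allowed beta spectra, continuous energy loss along the track from a
#' restricted (Moller-hard-collision-subtracted) range-energy relation,
#' per-step angular deflections from a screened-Rutherford distribution
#' whose mean deflection matches the Highland multiple-scattering variance,
#' and explicit delta electrons above 10 keV. Photons travel an exponential
#' free path with a water-like attenuation coefficient scaled by density
#' and deposit their energy at the first interaction. Conversion/Auger
#' electrons are lumped as local deposition at the source voxel. Transport
#' stops below the spectrum's energy cutoff (default 1 keV); bremsstrahlung
#' is not modelled.
#'
#' Given the same `(seed, n_histories, spectrum, grid)` the kernel is
#' reproduced bit for bit.
#'
#' @param spectrum an [emission_spectrum]; default [ho166_spectrum()].
#' @param grid odd-sized [voxel_grid]; default [dpk_default_grid()].
#' @param density medium density in kg/L (equivalently g/cm^3); 1.06 for
#'   soft tissue.
#' @param n_histories number of simulated decays; >= 1.
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param step_mm condensed-history step length.
#' @return A `dose_point_kernel`.
#' @export
generate_dpk <- function(spectrum = ho166_spectrum(), grid = dpk_default_grid(),
                         density = 1.06, n_histories = 1e6, seed = NULL,
                         step_mm = 0.05) {
  if (any(grid$shape %% 2L == 0L))
    stop("kernel grid must be odd-sized in every dimension (unique centre voxel)")
  if (n_histories < 1) stop("n_histories must be >= 1")
  n_histories <- as.integer(n_histories)
  if (!is.null(seed)) set.seed(seed)
  cutoff <- spectrum$cutoff_kev / 1000

  # primary electron energies (one beta per decay, branch by yield)
  br <- spectrum$beta_branches
  ycum <- cumsum(br[, 2])
  if (ycum[length(ycum)] > 1 + 1e-9) stop("beta yields exceed 1")
  u <- stats::runif(n_histories)
  branch <- findInterval(u, ycum) + 1L  # > nrow -> no beta this decay
  e_energies <- numeric(0)
  for (i in seq_len(nrow(br))) {
    n_i <- sum(branch == i)
    if (n_i == 0 || br[i, 1] <= 0) next
    Egr <- seq(cutoff, br[i, 1] - 1e-6, length.out = 2048)
    w <- beta_spectrum_shape(Egr, br[i, 1])
    e_energies <- c(e_energies, sample(Egr, n_i, replace = TRUE, prob = w))
  }
  # photons, Bernoulli per line per decay
  ph <- spectrum$photon_lines
  p_energies <- numeric(0)
  for (i in seq_len(nrow(ph))) {
    n_i <- stats::rbinom(1, n_histories, min(ph[i, 2], 1))
    p_energies <- c(p_energies, rep(ph[i, 1], n_i))
  }

  tab <- transport_tables(density, cutoff)
  dep <- dpk_transport(grid$shape, grid$spacing_mm, e_energies, p_energies,
                       tab$e_of_r, tab$r_max, tab$r_of_e, tab$loge_min,
                       tab$loge_max, tab$a_of_logv, tab$logv_min, tab$logv_max,
                       tab$kcol_mm, tab$wc, tab$x0_mm,
                       tab$mu_loge, tab$mu_logmu, cutoff, step_mm)
  dep <- dep / n_histories * 1e6  # MeV summed -> eV per decay
  ci <- (grid$shape + 1L) %/% 2L
  dep[ci[1], ci[2], ci[3]] <- dep[ci[1], ci[2], ci[3]] +
    spectrum$local_mean_energy_mev * spectrum$local_yield * 1e6
  new_dpk(dep, grid, density,
          provenance = list(generator = "hoquant condensed-history MC",
                            n_histories = n_histories,
                            seed = if (is.null(seed)) NA else seed,
                            step_mm = step_mm, cutoff_kev = spectrum$cutoff_kev,
                            beta_branches = unname(spectrum$beta_branches),
                            photon_lines = unname(spectrum$photon_lines),
                            local_mev = spectrum$local_mean_energy_mev *
                              spectrum$local_yield))
}

## Precomputed lookup tables for the compiled transport.
transport_tables <- function(density, cutoff) {
  za <- 0.5551                      # Z/A of water
  kcol_mm <- 0.1535 * za * density / 10   # MeV/mm (times 1/beta^2)
  wc <- 0.010                       # delta-ray threshold, MeV
  x0_mm <- 36.08 / density * 10     # radiation length of water, mm
  nE <- 3000
  loge_min <- log(cutoff); loge_max <- log(2.0)
  Eg <- exp(seq(loge_min, loge_max, length.out = nE))
  Rg <- csda_range_g_cm2(Eg) / density * 10  # mm
  Stot <- diff(Eg) / diff(Rg)
  Stot <- c(Stot, Stot[length(Stot)])
  me <- 0.51099895
  beta2 <- Eg * (Eg + 2 * me) / (Eg + me)^2
  Shard <- ifelse(Eg / 2 > wc, kcol_mm / beta2 * log(Eg / 2 / wc), 0)
  Sres <- pmax(Stot - Shard, 0.2 * Stot)
  Rres <- cumsum(c(Rg[1], diff(Eg) * 2 / (Sres[-1] + Sres[-nE])))
  r_max <- Rres[nE]
  # E as a function of restricted range on a uniform range grid
  nR <- 8192
  rg <- seq(0, r_max, length.out = nR)
  e_of_r <- stats::approx(c(0, Rres), c(0, Eg), xout = rg, rule = 2)$y
  # restricted range on the uniform log-energy grid
  r_of_e <- Rres
  # screened-Rutherford screening parameter a(v) with <1 - cos> = v
  nV <- 512
  logv_min <- log(1e-6); logv_max <- log(0.95)
  vs <- exp(seq(logv_min, logv_max, length.out = nV))
  a_of_logv <- vapply(vs, function(v) {
    f <- function(a) {
      N <- 1 / (2 * a) - 1 / (2 + 2 * a)
      I <- (log(2 + 2 * a) + 2 * a / (2 + 2 * a)) - (log(2 * a) + 1)
      I / N - v
    }
    log(stats::uniroot(f, c(1e-14, 50), tol = 1e-13)$root)
  }, 0)
  mu <- water_mu_rho_table()
  list(e_of_r = e_of_r, r_max = r_max, r_of_e = r_of_e,
       loge_min = loge_min, loge_max = loge_max,
       a_of_logv = a_of_logv, logv_min = logv_min, logv_max = logv_max,
       kcol_mm = kcol_mm, wc = wc, x0_mm = x0_mm,
       mu_loge = log(mu[, 1]), mu_logmu = log(mu[, 2] * density / 10))  # 1/mm
}

#' Kernel file I/O
#'
#' A kernel is stored as a NIfTI volume of per-decay energies (eV) plus a
#' JSON sidecar (`<base>.json`) holding grid, medium density and
#' provenance. Loading requires the sidecar density; a kernel without a
#' stated medium density is rejected rather than defaulted.
#'
#' @param kernel a `dose_point_kernel`.
#' @param path base path; `.nii.gz` and `.json` extensions are added.
#' @return `load_dpk` returns a `dose_point_kernel`; `save_dpk` returns
#'   `path` invisibly.
#' @export
save_dpk <- function(kernel, path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  write_nifti_volume(list(values = kernel$energy_ev, grid = kernel$grid),
                     paste0(base, ".nii.gz"))
  side <- list(grid = list(spacing_mm = kernel$grid$spacing_mm,
                           origin_mm = kernel$grid$origin_mm,
                           shape = kernel$grid$shape),
               medium_density_kg_per_l = kernel$medium_density,
               units = "eV per decay per voxel",
               provenance = kernel$provenance)
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dpk
#' @export
load_dpk <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  side_path <- paste0(base, ".json")
  if (!file.exists(side_path)) stop("kernel sidecar not found: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (is.null(side$medium_density_kg_per_l))
    stop("kernel sidecar lacks the medium density; refusing to default it")
  vol <- read_nifti_volume(paste0(base, ".nii.gz"), hu_limits = c(-1e30, 1e30))
  grid <- voxel_grid(side$grid$spacing_mm, side$grid$shape, side$grid$origin_mm)
  if (!all(dim(vol$values) == grid$shape))
    stop("kernel array shape does not match its sidecar metadata")
  new_dpk(vol$values, grid, side$medium_density_kg_per_l,
          provenance = as.list(side$provenance))
}

#' Match an activity map to the kernel grid
#'
#' Resamples a per-voxel activity map to the kernel's resolution with
#' trilinear interpolation, rescaled so the total activity is conserved
#' exactly. Both finer and coarser targets are supported.
#'
#' @param activity a map list with `values` (Bq per voxel) and `grid`.
#' @param kernel a `dose_point_kernel`.
#' @return The activity map on a grid with the kernel's spacing covering
#'   the source extent.
#' @export
match_to_kernel_grid <- function(activity, kernel) {
  sp_a <- activity$grid$spacing_mm
  sp_k <- kernel$grid$spacing_mm
  if (all(abs(sp_a - sp_k) < 1e-9)) return(activity)
  ext <- activity$grid$shape * sp_a
  shape <- pmax(1L, as.integer(ceiling(ext / sp_k - 1e-9)))
  lo <- activity$grid$origin_mm - sp_a / 2
  center <- lo + ext / 2
  origin <- center - (shape - 1) / 2 * sp_k
  target <- voxel_grid(sp_k, shape, origin)
  resample_trilinear(activity, target, conserve_total = TRUE)
}

#' Convolve an activity map with a dose point kernel
#'
#' Linear (zero-padded) convolution in the spectral domain: the energy
#' deposition rate is `E(eV/s) = A(Bq) (x) DPK(eV)`, evaluated on the
#' activity grid. The activity must already be on the kernel's resolution
#' ([match_to_kernel_grid]) and must be non-negative: maps produced by the
#' all-negatives subtraction variant are refused, since negative activities
#' have no dose interpretation.
#'
#' @param activity map list with non-negative `values` (Bq) and `grid`
#'   matching the kernel spacing.
#' @param kernel a `dose_point_kernel`.
#' @return A map list with `values` in eV/s on the activity grid.
#' @export
convolve_dose_rate <- function(activity, kernel) {
  if (any(abs(activity$grid$spacing_mm - kernel$grid$spacing_mm) > 1e-9))
    stop("activity resolution differs from the kernel; run match_to_kernel_grid() first")
  av <- activity$values
  if (anyNA(av)) { av[is.na(av)] <- 0 }
  if (any(av < 0))
    stop("negative activity voxels; dose convolution requires a non-negative map ",
         "(use a threshold or s-plus quantification)")
  kv <- kernel$energy_ev
  na <- dim(av); nk <- dim(kv)
  nfull <- na + nk - 1L
  npad <- vapply(nfull, function(n) stats::nextn(n, c(2, 3, 5)), 0L)
  A <- array(0, npad); A[seq_len(na[1]), seq_len(na[2]), seq_len(na[3])] <- av
  K <- array(0, npad); K[seq_len(nk[1]), seq_len(nk[2]), seq_len(nk[3])] <- kv
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / prod(npad)
  cc <- kernel$center_index
  out <- conv[cc[1] - 1 + seq_len(na[1]),
              cc[2] - 1 + seq_len(na[2]),
              cc[3] - 1 + seq_len(na[3])]
  out[out < 0 & out > -1e-9 * max(abs(out))] <- 0  # FFT round-off
  list(values = out, grid = activity$grid, units = "eV/s")
}

#' Cumulative absorbed-dose map
#'
#' Scales an energy deposition rate to the dose absorbed over complete
#' physical decay: `D = E / lambda * q / (rho * V_voxel)` with
#' `q = 1.602176634e-19 J/eV`, density in kg/L and the voxel volume in
#' litres. `integration_time_s` restricts the integral to a finite time by
#' the factor `1 - exp(-lambda t)`.
#'
#' @param energy_rate map list in eV/s (from [convolve_dose_rate]).
#' @param density tissue density in kg/L; 1.06 for liver-like soft tissue.
#' @param lambda_per_s decay constant (s^-1).
#' @param integration_time_s `Inf` (default) for full decay.
#' @return A `dose_map`: list with `dose_gy`, `grid`, `density`.
#' @export
cumulative_dose_map <- function(energy_rate, density = 1.06,
                                lambda_per_s = ho166_lambda_per_s(),
                                integration_time_s = Inf) {
  if (density <= 0) stop("density must be positive")
  if (lambda_per_s <= 0) stop("decay constant must be positive")
  v_l <- voxel_volume_ml(energy_rate$grid) / 1000
  fac <- if (is.finite(integration_time_s))
    (1 - exp(-lambda_per_s * integration_time_s)) else 1
  dose <- energy_rate$values / lambda_per_s * fac * 1.602176634e-19 / (density * v_l)
  structure(list(dose_gy = dose, grid = energy_rate$grid, density = density),
            class = "dose_map")
}

#' Cumulative dose-volume histogram
#'
#' `volume_percent(d)` is the percentage of mask voxels receiving at least
#' dose `d`; bin edges span `[0, max dose]`. The curve starts at 100 % and
#' is non-increasing.
#'
#' @param dose a `dose_map`.
#' @param mask a [voi_mask] on the dose grid.
#' @param n_bins number of bin edges; >= 2.
#' @return A data.frame of class `dvh_curve` with `dose_gy` and
#'   `volume_percent`.
#' @export
dvh <- function(dose, mask, n_bins = 200) {
  stop_if_grid_mismatch(dose$grid, mask$grid, "dose map and mask")
  if (!any(mask$included)) stop("DVH mask is empty")
  if (n_bins < 2) stop("n_bins must be >= 2")
  d <- dose$dose_gy[mask$included]
  edges <- seq(0, max(d), length.out = n_bins)
  surv <- vapply(edges, function(e) 100 * mean(d >= e), 0)
  out <- data.frame(dose_gy = edges, volume_percent = surv)
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' Mean dose implied by a DVH
#'
#' Trapezoidal integral of the cumulative DVH over dose, which equals the
#' mean dose up to binning resolution.
#'
#' @param curve a `dvh_curve`.
#' @return Mean dose in Gy.
#' @export
dvh_mean_dose <- function(curve) {
  x <- curve$dose_gy; y <- curve$volume_percent / 100
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Radial energy fraction of a kernel
#'
#' Fraction of the kernel's total deposited energy in voxels whose centres
#' lie within `radius_mm` of the source centre. For the generated 166Ho
#' kernel in soft tissue this is the "energy within the first 3 mm"
#' diagnostic.
#'
#' @param kernel a `dose_point_kernel`.
#' @param radius_mm radius in mm; >= 0.
#' @return Fraction in `[0, 1]`.
#' @export
kernel_radial_fraction <- function(kernel, radius_mm) {
  if (radius_mm < 0) stop("radius must be >= 0")
  g <- kernel$grid
  ci <- kernel$center_index
  ax <- lapply(1:3, function(k) (seq_len(g$shape[k]) - ci[k]) * g$spacing_mm[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  tot <- sum(kernel$energy_ev)
  if (tot == 0) return(NA_real_)
  sum(kernel$energy_ev[r2 <= radius_mm^2 + 1e-12]) / tot
}
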