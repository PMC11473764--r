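test_that("a unit point source reproduces the kernel itself", {
  k <- small_test_kernel()
  g <- voxel_grid(c(1, 1, 1), c(31, 31, 31))
  av <- array(0, c(31, 31, 31)); av[16, 16, 16] <- 1
  out <- convolve_dose_rate(list(values = av, grid = g), k)
  expect_equal(out$values[16 + (-10:10), 16 + (-10:10), 16 + (-10:10)],
               k$energy_ev, tolerance = 1e-9)
})

test_that("convolution is linear: two sources give the sum of shifted kernels", {
  k <- small_test_kernel()
  g <- voxel_grid(c(1, 1, 1), c(31, 31, 31))
  a1 <- array(0, c(31, 31, 31)); a1[12, 15, 16] <- 2
  a2 <- array(0, c(31, 31, 31)); a2[20, 17, 14] <- 5
  o1 <- convolve_dose_rate(list(values = a1, grid = g), k)$values
  o2 <- convolve_dose_rate(list(values = a2, grid = g), k)$values
  o12 <- convolve_dose_rate(list(values = a1 + a2, grid = g), k)$values
  expect_equal(o12, o1 + o2, tolerance = 1e-9)
})

test_that("FFT convolution matches the direct-summation oracle on a 21^3 grid", {
  k <- small_test_kernel()
  g <- voxel_grid(c(1, 1, 1), c(21, 21, 21))
  set.seed(20)
  av <- array(stats::rpois(21^3, 0.1) * runif(21^3), c(21, 21, 21))
  act <- list(values = av, grid = g)
  fftv <- convolve_dose_rate(act, k)$values
  direct <- direct_convolve(act, k)
  expect_lt(max(abs(fftv - direct)) / max(direct), 1e-9)
})

test_that("energy is conserved when all activity is far from the field edge", {
  k <- small_test_kernel()
  g <- voxel_grid(c(1, 1, 1), c(41, 41, 41))
  set.seed(21)
  av <- array(0, c(41, 41, 41))
  av[16:26, 16:26, 16:26] <- runif(11^3)  # >= kernel half-width from edges
  out <- convolve_dose_rate(list(values = av, grid = g), k)
  expect_equal(sum(out$values), sum(av) * sum(k$energy_ev), tolerance = 1e-9)
  # with activity at the edge, zero padding loses energy
  av2 <- array(0, c(41, 41, 41)); av2[1, 1, 1] <- 1
  out2 <- convolve_dose_rate(list(values = av2, grid = g), k)
  expect_lt(sum(out2$values), sum(k$energy_ev) * (1 - 1e-6))
})

test_that("convolution refuses mismatched resolution and negative activity", {
  k <- small_test_kernel()
  g2 <- voxel_grid(c(2, 2, 2), c(11, 11, 11))
  expect_error(convolve_dose_rate(list(values = array(1, c(11, 11, 11)), grid = g2), k),
               "match_to_kernel_grid")
  g <- voxel_grid(c(1, 1, 1), c(11, 11, 11))
  neg <- array(0, c(11, 11, 11)); neg[5, 5, 5] <- -1
  expect_error(convolve_dose_rate(list(values = neg, grid = g), k), "negative")
})

test_that("matching an activity map to the kernel grid conserves total activity", {
  k <- small_test_kernel()
  g <- voxel_grid(c(2.5, 2.5, 2.5), c(9, 9, 9))
  av <- array(0, c(9, 9, 9)); av[5, 5, 5] <- 3.7e6
  m <- match_to_kernel_grid(list(values = av, grid = g), k)
  expect_equal(m$grid$spacing_mm, k$grid$spacing_mm)
  expect_lt(abs(sum(m$values) - 3.7e6) / 3.7e6, 1e-12)
  # identity when already on kernel resolution
  gk <- voxel_grid(c(1, 1, 1), c(5, 5, 5))
  act <- list(values = array(2, c(5, 5, 5)), grid = gk)
  expect_identical(match_to_kernel_grid(act, k), act)
})

test_that("cumulative dose follows the decay-integral scaling", {
  g <- voxel_grid(c(0.5, 0.5, 1), c(3, 3, 3))  # voxel 0.25 mm^3 = 0.25e-6 L
  er <- list(values = array(1, c(3, 3, 3)), grid = g)
  d <- cumulative_dose_map(er, density = 1.06, lambda_per_s = 7.18e-6)
  expected <- (1 / 7.18e-6) * 1.602176634e-19 / (1.06 * 0.25e-6)
  expect_equal(d$dose_gy[1, 1, 1], expected, tolerance = 1e-12)
  # linearity and the zero map
  er2 <- list(values = array(2, c(3, 3, 3)), grid = g)
  expect_equal(cumulative_dose_map(er2, 1.06, 7.18e-6)$dose_gy,
               2 * d$dose_gy, tolerance = 1e-12)
  er0 <- list(values = array(0, c(3, 3, 3)), grid = g)
  expect_true(all(cumulative_dose_map(er0, 1.06, 7.18e-6)$dose_gy == 0))
  # finite integration time scales by 1 - exp(-lambda t)
  dh <- cumulative_dose_map(er, 1.06, 7.18e-6,
                            integration_time_s = log(2) / 7.18e-6)
  expect_equal(dh$dose_gy[1, 1, 1], expected * 0.5, tolerance = 1e-12)
})

test_that("interior voxels of a uniform activity field match the closed-form dose", {
  k <- small_test_kernel()
  g <- voxel_grid(c(1, 1, 1), c(41, 41, 41))
  a_vox <- 1000
  av <- array(a_vox, c(41, 41, 41))
  out <- convolve_dose_rate(list(values = av, grid = g), k)
  d <- cumulative_dose_map(out, density = k$medium_density)
  lam <- ho166_lambda_per_s()
  v_l <- voxel_volume_ml(g) / 1000
  closed <- a_vox / lam * sum(k$energy_ev) * 1.602176634e-19 /
    (k$medium_density * v_l)
  expect_lt(abs(d$dose_gy[21, 21, 21] - closed) / closed, 0.01)
})

test_that("the DVH is a non-increasing curve that integrates to the mean dose", {
  g <- voxel_grid(c(1, 1, 1), c(10, 10, 2))
  mask <- voi_mask(array(TRUE, c(10, 10, 2)), g)
  # uniform dose: 100% up to D, then 0
  du <- structure(list(dose_gy = array(5, c(10, 10, 2)), grid = g, density = 1.06),
                  class = "dose_map")
  cu <- dvh(du, mask, n_bins = 11)
  expect_equal(cu$volume_percent[1], 100)
  expect_true(all(cu$volume_percent == 100))  # max dose is 5, all voxels >= every edge
  # half at 2D, half at 0: 50% at any positive dose level
  half <- array(0, c(10, 10, 2)); half[, , 1] <- 10
  dh <- structure(list(dose_gy = half, grid = g, density = 1.06),
                  class = "dose_map")
  ch <- dvh(dh, mask, n_bins = 21)
  expect_equal(ch$volume_percent[1], 100)
  expect_true(all(abs(ch$volume_percent[-1] - 50) < 1e-12))
  expect_equal(dvh_mean_dose(ch), mean(half), tolerance = 0.06)
  # random dose map: monotone and mean-consistent
  set.seed(22)
  dr <- structure(list(dose_gy = array(rexp(200, 1 / 30), c(10, 10, 2)),
                       grid = g, density = 1.06), class = "dose_map")
  cr <- dvh(dr, mask, n_bins = 400)
  expect_true(all(diff(cr$volume_percent) <= 0))
  expect_equal(dvh_mean_dose(cr), mean(dr$dose_gy), tolerance = 0.02)
  expect_error(dvh(dr, voi_mask(array(FALSE, c(10, 10, 2)), g)), "empty")
})

test_that("kernel generation is deterministic given seed, histories and grid", {
  g <- voxel_grid(c(1, 1, 1), c(11, 11, 11), -c(5, 5, 5))
  k1 <- generate_dpk(grid = g, n_histories = 5000, seed = 7)
  k2 <- generate_dpk(grid = g, n_histories = 5000, seed = 7)
  expect_identical(k1$energy_ev, k2$energy_ev)
  k3 <- generate_dpk(grid = g, n_histories = 5000, seed = 8)
  expect_false(identical(k1$energy_ev, k3$energy_ev))
  expect_error(generate_dpk(grid = voxel_grid(c(1, 1, 1), c(10, 11, 11))),
               "odd")
})

test_that("kernel energy respects the emission budget and radial bookkeeping", {
  k <- small_test_kernel()
  emitted_ev <- spectrum_total_energy_mev(ho166_spectrum()) * 1e6
  expect_lt(sum(k$energy_ev), emitted_ev)           # photon escape keeps it below
  expect_gt(sum(k$energy_ev), 0.9 * emitted_ev)     # most energy is local
  expect_equal(kernel_radial_fraction(k, 1000), 1)
  f0 <- kernel_radial_fraction(k, 0)
  ci <- k$center_index
  expect_equal(f0, k$energy_ev[ci[1], ci[2], ci[3]] / sum(k$energy_ev))
  expect_true(all(k$energy_ev >= 0))
  # a spectrum carrying no energy produces an all-zero kernel
  z <- emission_spectrum(cbind(0, 0.5), cbind(0, 1))
  kz <- generate_dpk(z, voxel_grid(c(1, 1, 1), c(5, 5, 5), -c(2, 2, 2)),
                     n_histories = 100, seed = 1)
  expect_true(all(kz$energy_ev == 0))
})

test_that("kernels round-trip through the NIfTI + sidecar format", {
  k <- small_test_kernel()
  base <- tempfile("kern")
  save_dpk(k, base)
  k2 <- load_dpk(base)
  expect_identical(k2$energy_ev, k$energy_ev)
  expect_equal(k2$medium_density, k$medium_density)
  expect_equal(k2$center_index, k$center_index)
  # a sidecar without density is rejected, not defaulted
  side <- jsonlite::read_json(paste0(base, ".json"))
  side$medium_density_kg_per_l <- NULL
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE)
  expect_error(load_dpk(base), "density")
  expect_error(load_dpk(tempfile("nokern")), "sidecar")
})
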