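test_that("subtraction variants treat negative values as specified", {
  fx <- toy_post()  # post voxels {30, 50, 100, 160}
  ref <- reference_stats(40, 10)
  sm <- quantify_subtraction(fx$post, fx$voi, ref, "s-minus")
  expect_setequal(sm$huho_map[sm$contributing$included], c(-10, 10, 60, 120))
  expect_equal(mask_n_voxels(sm$contributing), 4L)

  s <- quantify_subtraction(fx$post, fx$voi, ref, "s")
  expect_equal(sort(s$huho_map[s$contributing$included]),
               sort(sm$huho_map[sm$contributing$included]))  # clamp inactive: post >= 0

  sp <- quantify_subtraction(fx$post, fx$voi, ref, "s-plus")
  expect_setequal(sp$huho_map[sp$contributing$included], c(10, 60, 120))
  expect_equal(mask_n_voxels(sp$contributing), 3L)

  # the S clamp acts when post values drop below zero
  fx2 <- toy_post(c(-80, 30, 50, 160))
  s2 <- quantify_subtraction(fx2$post, fx2$voi, ref, "s")
  expect_setequal(s2$huho_map[s2$contributing$included], c(-40, -10, 10, 120))
  expect_equal(min(s2$huho_map, na.rm = TRUE), -ref$hu_reference)
})

test_that("thresholding keeps voxels strictly above the effective threshold", {
  fx <- toy_post()
  ref <- reference_stats(40, 10)
  t0 <- quantify_threshold(fx$post, fx$voi, "t", ref)
  expect_equal(t0$effective_threshold, 40)
  expect_setequal(t0$huho_map[t0$contributing$included], c(50, 100, 160))

  t2 <- quantify_threshold(fx$post, fx$voi, "t2sd", ref)
  expect_equal(t2$effective_threshold, 60)
  expect_setequal(t2$huho_map[t2$contributing$included], c(100, 160))
  expect_equal(volume_fraction(t2, fx$voi), 50)

  # voxel exactly at the threshold is excluded (strict >)
  fx3 <- toy_post(c(60, 60.0001, 100, 160))
  t3 <- quantify_threshold(fx3$post, fx3$voi, "t2sd", ref)
  expect_equal(mask_n_voxels(t3$contributing), 3L)

  # low reference: the calibration intercept becomes the minimal threshold
  lo <- reference_stats(10, 0)
  fx4 <- toy_post(c(12, 20, 26.36, 30))
  t4 <- quantify_threshold(fx4$post, fx4$voi, "t", lo, eq8_curve())
  expect_equal(t4$effective_threshold, 26.36)
  expect_setequal(t4$huho_map[t4$contributing$included], 30)
  # a forced-zero curve does not raise the threshold
  fz <- calibration_curve(0, 29.89, forced_zero = TRUE)
  t5 <- quantify_threshold(fx4$post, fx4$voi, "t", lo, fz)
  expect_equal(t5$effective_threshold, 10)
})

test_that("concentration conversion applies the intercept only to threshold results", {
  fx <- toy_post(c(325.26, 26.36, 100, 160))
  ref <- reference_stats(20, 0)
  tt <- quantify_threshold(fx$post, fx$voi, "t", ref, eq8_curve())
  tt <- concentration_map(tt, eq8_curve())
  conc <- tt$concentration_map
  expect_equal(conc[1, 1, 1], 10, tolerance = 1e-12)      # (325.26 - m) / b
  expect_false(tt$contributing$included[2, 1, 1])          # exactly at m: not > 26.36? (26.36 > 20 but == m)
  sm <- quantify_subtraction(fx$post, fx$voi, reference_stats(295.37, 0), "s-minus")
  sm <- concentration_map(sm, eq8_curve())
  expect_equal(sm$concentration_map[1, 1, 1], 29.89 / 29.89, tolerance = 1e-9) # slope-only
  # totals match a per-voxel summation oracle
  inc <- tt$contributing$included
  expect_equal(tt$total_ho_mg,
               sum(tt$concentration_map[inc]) * voxel_volume_ml(fx$grid))
})

test_that("threshold voxels exactly at the intercept map to zero concentration", {
  g <- voxel_grid(c(1, 1, 1), c(2, 1, 1))
  post <- ct_volume(array(c(26.36 + 1e-9, 60), c(2, 1, 1)), g)
  voi <- voi_mask(array(TRUE, c(2, 1, 1)), g)
  tt <- quantify_threshold(post, voi, "t", reference_stats(5, 0), eq8_curve())
  tt <- concentration_map(tt, eq8_curve())
  expect_equal(tt$concentration_map[1, 1, 1], 0, tolerance = 1e-6)
})

test_that("activity conversion follows the mass and specific-activity arithmetic", {
  g <- voxel_grid(c(1, 1, 1), c(2, 1, 1))  # 0.001 mL voxels
  post <- ct_volume(array(c(26.36 + 29.89, 26.36), c(2, 1, 1)), g)
  voi <- voi_mask(array(TRUE, c(2, 1, 1)), g)
  tt <- quantify_threshold(post, voi, "t", reference_stats(5, 0), eq8_curve())
  tt <- concentration_map(tt, eq8_curve())
  rec <- injection_record(2e6, 1e6, 0, 0, 0, specific_activity_bq_per_mg = 1e6,
                          ho_content_fraction = 0.197)
  tt <- activity_map(tt, rec)
  # c = 1 mg/mL, V = 0.001 mL, Ho content 19.7%, 1 MBq/mg -> ~5076 Bq
  expect_equal(tt$activity_map[1, 1, 1], 1 * 0.001 / 0.197 * 1e6, tolerance = 1e-12)
  expect_equal(round(tt$activity_map[1, 1, 1]), 5076)
  expect_equal(tt$total_bq, tt$total_ms_mg * 1e6, tolerance = 1e-12)
})

test_that("decay correction halves activity over one half-life and inverts exactly", {
  expect_equal(decay_correct(1, 26.82 * 3600, "forward"), 0.5, tolerance = 1e-12)
  expect_equal(decay_correct(123, 0), 123)
  a <- decay_correct(decay_correct(77, 1e5, "forward"), 1e5, "back")
  expect_equal(a, 77, tolerance = 1e-12)
  expect_equal(signif(ho166_lambda_per_s(), 3), 7.18e-6)
})

test_that("injected amounts are decay-corrected to scan time before subtracting", {
  r0 <- injection_record(100e6, 40e6, 0, 0, 0, specific_activity_bq_per_mg = 1e6)
  inj <- injected_amount(r0)
  expect_equal(inj$injected_bq, 60e6)
  expect_equal(inj$injected_ms_mg, 60)
  expect_equal(inj$injected_ho_mg, 60 * 0.197)

  req <- injection_record(5e6, 5e6, 0, 0, 0, specific_activity_bq_per_mg = 1e6)
  expect_equal(injected_amount(req)$injected_bq, 0)

  # measured one half-life before the scan: corrected by 0.5 first
  hl <- 26.82 * 3600
  r1 <- injection_record(100e6, 40e6, 0, hl, hl,
                         specific_activity_bq_per_mg = 1e6)
  inj1 <- injected_amount(r1)
  expect_equal(inj1$injected_bq, 100e6 * 0.5 - 40e6, tolerance = 1e-9)
})

test_that("recovery reports percent of injected with the 70-130% sufficiency band", {
  res <- list(total_ms_mg = 100, total_ho_mg = 19.7)
  class(res) <- "quant_result"
  expect_equal(recovery(res, 100)$recovery_percent, 100)
  expect_true(recovery(res, 100)$sufficient)
  expect_equal(recovery(res, 100 / 0.94)$recovery_percent, 94)
  expect_true(recovery(res, 100 / 0.94)$sufficient)
  r65 <- recovery(res, 100 / 0.65)
  expect_equal(r65$recovery_percent, 65)
  expect_false(r65$sufficient)
  expect_error(recovery(res, 0), "positive")
})

test_that("ellipsoid volume follows pi/6 times the three diameters", {
  expect_equal(ellipsoid_volume(2, 2, 2), pi / 6 * 8)
  expect_equal(round(ellipsoid_volume(2, 2, 2), 2), 4.19)
  expect_equal(ellipsoid_volume(1, 1, 1), pi / 6)
  expect_equal(ellipsoid_volume(3, 1, 1), 3 * ellipsoid_volume(1, 1, 1))
  expect_error(ellipsoid_volume(0, 1, 1), "positive")
})

test_that("subtraction totals are monotone S- <= S <= S+ and thresholds are monotone", {
  for (seed in 1:5) {
    ph <- simulate_injection_phantom(noise_sd = 30, background_hu = 20, seed = seed)
    ref <- reference_stats_from_voi(ph$pre, ph$voi, "pre")
    cv <- eq8_curve()
    tot <- sapply(c("s-minus", "s", "s-plus"), function(v) {
      r <- concentration_map(quantify_subtraction(ph$post, ph$voi, ref, v), cv)
      r$total_ho_mg
    })
    expect_true(tot["s-minus"] <= tot["s"] + 1e-9)
    expect_true(tot["s"] <= tot["s-plus"] + 1e-9)

    kinds <- c("t", "t1sd", "t2sd", "t3sd")
    th <- lapply(kinds, function(k)
      concentration_map(quantify_threshold(ph$post, ph$voi, k, ref, cv), cv))
    tot_t <- sapply(th, `[[`, "total_ho_mg")
    vf_t <- sapply(th, volume_fraction, voi = ph$voi)
    expect_true(all(diff(tot_t) <= 1e-9))  # raising threshold never adds mass
    expect_true(all(diff(vf_t) <= 1e-9))
  }
})
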