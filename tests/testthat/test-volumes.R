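test_that("voxel grid validates geometry and reports voxel volume", {
  g <- voxel_grid(c(0.5, 0.5, 1), c(10, 12, 5), c(1, 2, 3))
  expect_equal(voxel_volume_mm3(g), 0.25)
  expect_equal(voxel_volume_ml(g), 0.25 / 1000)
  expect_equal(grid_axis_mm(g, 3), 3 + 0:4)
  expect_error(voxel_grid(c(0, 1, 1), c(2, 2, 2)), "positive")
  expect_error(ct_volume(array(0, c(2, 2, 2)), g), "shape")
})

test_that("cylinder mask cross-section matches the analytic disc area", {
  g <- voxel_grid(c(0.5, 0.5, 0.5), c(60, 60, 70))
  m <- make_cylinder_mask(g, c(15, 15, 17.5), diameter_mm = 11, length_mm = 30)
  n_slices <- 30 / 0.5
  area_per_slice <- mask_n_voxels(m) * 0.25 / n_slices
  expect_lt(abs(area_per_slice - pi * 5.5^2), 1)          # discretisation
  expect_lt(abs(area_per_slice - 100), 10)                # nominal 100 mm^2 label
})

test_that("sub-voxel cylinder centred on a voxel centre selects one voxel per slice", {
  g <- voxel_grid(c(1, 1, 1), c(9, 9, 9))
  m <- make_cylinder_mask(g, c(4, 4, 4), diameter_mm = 0.5, length_mm = 9)
  expect_equal(mask_n_voxels(m), 9L)
  expect_error(make_cylinder_mask(g, c(100, 100, 4), 2, 4), "outside")
})

test_that("cylinder mask volume converges to pi r^2 L as spacing shrinks", {
  vol_true <- pi * 5.5^2 * 30
  err <- sapply(c(0.5, 0.25), function(sp) {
    n <- ceiling(c(16 / sp, 16 / sp, 34 / sp))
    g <- voxel_grid(rep(sp, 3), n)
    m <- make_cylinder_mask(g, c(8, 8, 17), 11, 30)
    abs(mask_n_voxels(m) * sp^3 - vol_true) / vol_true
  })
  expect_lt(err[2], 0.02)
  expect_lt(err[2], err[1] + 1e-12)
})

test_that("slice exclusion trims the volume and shifts the origin", {
  g <- voxel_grid(c(1, 1, 0.5), c(4, 4, 60))
  set.seed(1)
  v <- ct_volume(array(rnorm(4 * 4 * 60, 0, 50), c(4, 4, 60)), g)
  expect_equal(exclude_slices(v, c(1, 60))$values, v$values)
  t2 <- exclude_slices(v, c(16, 45))  # 30 slices at 0.5 mm = 15 mm extent
  expect_equal(t2$grid$shape[3], 30L)
  expect_equal(t2$grid$origin_mm[3], g$origin_mm[3] + 15 * 0.5)
  expect_error(exclude_slices(v, integer(0)), "empty")
  expect_error(exclude_slices(v, c(50, 70)), "bounds")
})

test_that("stats after trimming equal stats of the mask restricted to kept slices", {
  g <- voxel_grid(c(1, 1, 1), c(6, 6, 20))
  set.seed(2)
  v <- ct_volume(array(rnorm(720, 40, 20), c(6, 6, 20)), g)
  m <- make_cylinder_mask(g, c(2.5, 2.5, 9.5), 4, 20)
  keep <- 5:14
  trimmed <- exclude_slices(v, range(keep))
  mt <- voi_mask(m$included[, , keep, drop = FALSE], trimmed$grid)
  restr <- m$included
  restr[, , setdiff(1:20, keep)] <- FALSE
  mr <- voi_mask(restr, g)
  expect_equal(voi_stats(trimmed, mt), voi_stats(v, mr))
})

test_that("VOI statistics use the sample-SD convention and pool correctly", {
  g <- voxel_grid(c(1, 1, 1), c(2, 1, 1))
  v50 <- ct_volume(array(50, c(2, 1, 1)), g)
  s <- voi_stats(v50, voi_mask(array(TRUE, c(2, 1, 1)), g))
  expect_equal(s$mean_hu, 50)
  expect_equal(s$sd_hu, 0)
  expect_equal(c(s$min_hu, s$max_hu), c(50, 50))

  v <- ct_volume(array(c(30, 50), c(2, 1, 1)), g)
  s2 <- voi_stats(v, voi_mask(array(TRUE, c(2, 1, 1)), g))
  expect_equal(s2$mean_hu, 40)
  expect_equal(s2$sd_hu, sqrt((100 + 100) / 1))  # n - 1 denominator
  expect_equal(s2$ci95, 40 + c(-1, 1) * 1.96 * s2$sd_hu / sqrt(2))

  # pooling: stats over a union equal stats over the pooled voxels
  g3 <- voxel_grid(c(1, 1, 1), c(4, 4, 2))
  set.seed(3)
  vv <- ct_volume(array(rnorm(32, 0, 30), c(4, 4, 2)), g3)
  a <- array(FALSE, c(4, 4, 2)); a[1:2, , 1] <- TRUE
  b <- array(FALSE, c(4, 4, 2)); b[3:4, , 2] <- TRUE
  su <- voi_stats(vv, voi_mask(a | b, g3))
  pooled <- c(vv$values[a], vv$values[b])
  expect_equal(su$mean_hu, mean(pooled))
  expect_equal(su$sd_hu, sd(pooled))
  expect_equal(su$n_voxels, length(pooled))
  expect_error(voi_stats(vv, voi_mask(array(TRUE, c(2, 1, 1)), g)), "mismatch")
})

test_that("trilinear resampling is exact on identity and constant fields", {
  g <- voxel_grid(c(1, 1, 1), c(8, 8, 4))
  set.seed(4)
  v <- list(values = array(runif(256), c(8, 8, 4)), grid = g)
  expect_equal(resample_trilinear(v, g)$values, v$values)
  cst <- list(values = array(7, c(8, 8, 4)), grid = g)
  fine <- voxel_grid(c(0.25, 0.25, 0.5), c(20, 20, 6), c(1, 1, 0.5))
  rf <- resample_trilinear(cst, fine)
  expect_true(all(abs(rf$values - 7) < 1e-12))
  far <- voxel_grid(c(1, 1, 1), c(4, 4, 4), c(100, 100, 100))
  expect_error(resample_trilinear(v, far), "overlap")
})

test_that("conserve_total resampling preserves summed activity to machine precision", {
  g <- voxel_grid(c(1, 1, 1), c(10, 10, 6))
  set.seed(5)
  act <- list(values = array(runif(600), c(10, 10, 6)), grid = g)
  fine <- voxel_grid(c(0.5, 0.5, 0.5), c(20, 20, 12), c(-0.25, -0.25, -0.25))
  rc <- resample_trilinear(act, fine, conserve_total = TRUE)
  expect_lt(abs(sum(rc$values) - sum(act$values)) / sum(act$values), 1e-12)
  rn <- resample_trilinear(act, fine, conserve_total = FALSE)
  expect_gt(abs(sum(rn$values) - sum(act$values)), 1e-9)
})

test_that("NIfTI write/read round-trips values exactly and geometry to float precision", {
  g <- voxel_grid(c(0.7, 0.8, 1.2), c(5, 6, 4), c(3, -4, 5))
  set.seed(6)
  v <- ct_volume(array(rnorm(120, 0, 300), c(5, 6, 4)), g)
  f <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(v, f)
  v2 <- read_ct_volume(f, "nifti")
  expect_identical(v2$values, v$values)
  expect_equal(v2$grid$spacing_mm, g$spacing_mm, tolerance = 1e-6)
  expect_equal(v2$grid$origin_mm, g$origin_mm, tolerance = 1e-6)
  # mask round trip through a label image
  m <- voi_mask(v$values > 0, g)
  fm <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(m, fm)
  m2 <- read_voi_mask(fm)
  expect_identical(m2$included, m$included)
})
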