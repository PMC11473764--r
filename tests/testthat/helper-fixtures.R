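# Shared fixtures: tiny grids, the published calibration line, and a
# quick small kernel cached per session.

eq8_curve <- function() calibration_curve(26.36, 29.89)

toy_post <- function(values = c(30, 50, 100, 160)) {
  g <- voxel_grid(c(1, 1, 1), c(2, 2, 1))
  list(post = ct_volume(array(values, c(2, 2, 1)), g),
       voi = voi_mask(array(TRUE, c(2, 2, 1)), g),
       grid = g)
}

small_kernel_env <- new.env()
small_test_kernel <- function() {
  if (is.null(small_kernel_env$k)) {
    g <- voxel_grid(c(1, 1, 1), c(21, 21, 21), -c(10, 10, 10))
    small_kernel_env$k <- generate_dpk(grid = g, n_histories = 30000, seed = 42)
  }
  small_kernel_env$k
}

# Direct-summation convolution oracle (independent of the FFT path).
direct_convolve <- function(activity, kernel) {
  av <- activity$values
  kv <- kernel$energy_ev
  cc <- kernel$center_index
  na <- dim(av); nk <- dim(kv)
  out <- array(0, na)
  nz <- which(av != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    p <- nz[r, ]
    a <- av[p[1], p[2], p[3]]
    lo <- pmax(p - (cc - 1L), 1L)
    hi <- pmin(p + (nk - cc), na)
    klo <- lo - p + cc
    khi <- hi - p + cc
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
      a * kv[klo[1]:khi[1], klo[2]:khi[2], klo[3]:khi[3]]
  }
  out
}

# Ordinary-least-squares normal-equations oracle with standard errors.
ols_oracle <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(XtX)))
  list(m = unname(beta[1]), b = unname(beta[2]),
       se_m = unname(se[1]), se_b = unname(se[2]))
}
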