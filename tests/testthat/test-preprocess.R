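test_that("discarding initial volumes shortens T and rejects bad k", {
  vol <- noise_volume(c(4, 4, 4), nt = 240)
  expect_equal(dim(discard_initial_volumes(vol, 10)$data)[4], 230)
  expect_identical(discard_initial_volumes(vol, 0), vol)
  expect_error(discard_initial_volumes(vol, 240), "discard")
  out <- discard_initial_volumes(vol, 10)
  expect_equal(out$data[2, 2, 2, 1], vol$data[2, 2, 2, 11])
})

test_that("framewise displacement follows the Power formulation", {
  motion <- matrix(0, 20, 6)
  expect_equal(framewise_displacement(motion), rep(0, 20))
  motion[5:20, 1] <- 1                           # 1 mm step in tx at t = 5
  fd <- framewise_displacement(motion)
  expect_equal(fd[5], 1)
  expect_equal(fd[-5], rep(0, 19))
  motion2 <- matrix(0, 10, 6)
  motion2[3:10, 5] <- 0.01                       # 0.01 rad rotation step
  expect_equal(framewise_displacement(motion2)[3], 0.5)  # 50 mm * 0.01
  expect_error(framewise_displacement(matrix(0, 10, 5)), "6 columns")
})

test_that("motion exclusion flags outliers beyond 2.5 cohort SD", {
  expect_false(any(flag_motion_exclusions(rep(0.2, 10))))
  fd <- c(rep(0.1, 19) + seq(0, 0.018, length.out = 19), 2.0)
  flags <- flag_motion_exclusions(fd)
  expect_identical(which(flags), 20L)
  expect_error(flag_motion_exclusions(c(0.1, 0.2)), "3 subjects")
})

test_that("Friston-24 block matches element-wise construction", {
  expect_true(all(build_friston24(matrix(0, 30, 6)) == 0))
  const <- matrix(2, 15, 6)
  b <- build_friston24(const)
  expect_equal(unname(b[2, 7:12]), rep(4, 6))     # squares
  expect_equal(unname(b[1, 13:18]), rep(0, 6))    # lag zero-padded
  expect_equal(unname(b[2, 13:18]), rep(2, 6))
  set.seed(4)
  m <- matrix(rnorm(20 * 6), 20, 6)
  b <- build_friston24(m)
  lag <- rbind(0, m[-20, ])
  expect_equal(unname(b), unname(cbind(m, m^2, lag, lag^2)))
  expect_lte(qr(b)$rank, 24)
})

test_that("ideal band-pass keeps the band and removes the rest", {
  tr <- 2; nt <- 230
  t <- seq_len(nt) * tr
  inband <- sin(2 * pi * 0.04 * t)
  out <- bandpass_filter(matrix(inband), 0.01, 0.08, tr = tr)
  expect_gt(sd(out) / sd(inband), 0.99)
  stopb <- sin(2 * pi * 0.2 * t)
  out2 <- bandpass_filter(matrix(stopb), 0.01, 0.08, tr = tr)
  expect_lt(sd(out2) / sd(stopb), 0.01)
  # Parseval: white-noise variance scales with the retained bandwidth
  set.seed(7)
  wn <- matrix(rnorm(nt * 200), nt)
  outw <- bandpass_filter(wn, 0.01, 0.08, tr = tr)
  ratio <- mean(apply(outw, 2, var)) / mean(apply(wn, 2, var))
  expect_lt(abs(ratio - (0.08 - 0.01) / 0.25), 0.02)
  expect_error(bandpass_filter(wn, 0.01, 0.3, tr = tr), "Nyquist")
})

test_that("nuisance regression yields exact least-squares residuals", {
  set.seed(11)
  y <- matrix(rnorm(50 * 2), 50, 2)
  # confound equal to the series itself -> residual ~ 0
  out <- regress_nuisance(y[, 1, drop = FALSE], y[, 1, drop = FALSE])
  expect_lt(max(abs(out)), 1e-10)
  # all-zero confounds + intercept -> demeaned series
  out2 <- regress_nuisance(y, matrix(0, 50, 1))
  expect_equal(out2, sweep(y, 2, colMeans(y)), ignore_attr = TRUE)
  # two-voxel toy against the normal-equations solution
  x <- cbind(1, rnorm(50))
  beta <- solve(crossprod(x), crossprod(x, y))
  expect_equal(regress_nuisance(y, x[, 2, drop = FALSE]),
               y - x %*% beta, ignore_attr = TRUE)
  # residuals orthogonal to every confound column
  conf <- matrix(rnorm(50 * 5), 50, 5)
  res <- regress_nuisance(y, conf)
  expect_lt(max(abs(cor(res, conf))), 1e-8)
  # rank-deficient design errors and names the dependent column
  bad <- cbind(a = conf[, 1], b = conf[, 2], c = conf[, 1] + conf[, 2])
  expect_error(regress_nuisance(y, bad), "rank-deficient")
})

test_that("Gaussian smoothing has the right kernel and preserves DC", {
  m <- stat_map(array(rnorm(12^3), c(12, 12, 12)),
                array(TRUE, c(12, 12, 12)))
  expect_identical(smooth_gaussian(m, 0), m)
  # delta impulse reproduces the kernel with sigma = FWHM / 2.3548
  delta <- array(0, c(21, 21, 21)); delta[11, 11, 11] <- 1
  dm <- stat_map(delta, array(TRUE, c(21, 21, 21)))
  sm <- smooth_gaussian(dm, fwhm_mm = 6, voxel_size_mm = 3)
  prof <- sm$values[, 11, 11]
  sigma_vox <- 6 / (2 * sqrt(2 * log(2))) / 3
  expected <- exp(-((1:21) - 11)^2 / (2 * sigma_vox^2))
  expect_equal(prof / max(prof), expected, tolerance = 1e-6)
  # constant in-mask map unchanged (mask-normalised convolution)
  cm <- stat_map(array(5, c(12, 12, 12)), array(TRUE, c(12, 12, 12)))
  expect_equal(smooth_gaussian(cm, 6, 3)$values, cm$values, tolerance = 1e-9)
  expect_error(smooth_gaussian(cm, -1), "non-negative")
})

test_that("tissue signal is the plain mean over the tissue mask", {
  vol <- noise_volume(c(5, 5, 5), nt = 30, seed = 2)
  m1 <- array(FALSE, c(5, 5, 5)); m1[2, 3, 4] <- TRUE
  expect_equal(extract_tissue_signal(vol, m1), vol$data[2, 3, 4, ])
  set.seed(3)
  m10 <- array(FALSE, c(5, 5, 5)); m10[sample(125, 10)] <- TRUE
  manual <- colMeans(t(apply(which(m10, arr.ind = TRUE), 1, function(ijk)
    vol$data[ijk[1], ijk[2], ijk[3], ])))
  expect_equal(extract_tissue_signal(vol, m10), manual)
  expect_error(extract_tissue_signal(vol, array(FALSE, c(5, 5, 5))), "empty")
})

test_that("filtering confounds before regression keeps residuals in-band", {
  set.seed(5)
  nt <- 120; tr <- 2
  y <- matrix(rnorm(nt * 10), nt)
  conf <- matrix(rnorm(nt * 3), nt, 3)
  yf <- bandpass_filter(y, tr = tr)
  cf <- bandpass_filter(conf, tr = tr)
  # filtered confounds: residuals are a fixed point of the band-pass
  r1 <- regress_nuisance(yf, cf)
  expect_equal(bandpass_filter(r1, tr = tr), r1, tolerance = 1e-8)
  # raw confounds would reintroduce out-of-band variance
  r_raw <- regress_nuisance(yf, conf)
  oob <- r_raw - bandpass_filter(r_raw, tr = tr)
  expect_gt(max(abs(oob)), 1e-3)
})
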