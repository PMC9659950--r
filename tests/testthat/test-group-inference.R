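make_maps <- function(n, gen, dims = c(8, 8, 8), mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dims)
  lapply(seq_len(n), function(i) stat_map(gen(i), mask))
}

test_that("voxelwise t-test matches the pooled closed form", {
  dims <- c(6, 6, 6)
  set.seed(1)
  maps <- make_maps(4, function(i) array(rnorm(216), dims), dims)
  # same data in both groups -> t = 0 everywhere
  t0 <- voxelwise_ttest(maps, maps)
  expect_true(all(t0$tmap$values == 0))
  # antisymmetry under group swap
  set.seed(2)
  ma <- make_maps(5, function(i) array(rnorm(216), dims), dims)
  mb <- make_maps(7, function(i) array(rnorm(216, 0.3), dims), dims)
  tab <- voxelwise_ttest(ma, mb)
  tba <- voxelwise_ttest(mb, ma)
  expect_equal(tab$tmap$values, -tba$tmap$values)
  expect_equal(tab$df, 10)
  # constructed voxel: means 1 vs 0, SD 1, n = 20/20 -> t ~ 3.16
  base <- qnorm(seq(0.5 / 20, 1 - 0.5 / 20, length.out = 20))
  base <- base / sd(base)                      # exact unit SD
  va <- make_maps(20, function(i) array(1 + base[i], dims), dims)
  vb <- make_maps(20, function(i) array(base[i], dims), dims)
  tt <- voxelwise_ttest(va, vb)
  expect_equal(tt$tmap$values[1, 1, 1], 1 / sqrt(2 / 20), tolerance = 1e-10)
  expect_error(voxelwise_ttest(ma[1], mb), "2 subjects")
  # per-voxel t agrees with stats::t.test on a sampled voxel
  xa <- vapply(ma, function(m) m$values[2, 3, 4], 1)
  xb <- vapply(mb, function(m) m$values[2, 3, 4], 1)
  expect_equal(tab$tmap$values[2, 3, 4],
               unname(t.test(xa, xb, var.equal = TRUE)$statistic))
})

test_that("smoothness estimation recovers the planted kernel", {
  dims <- c(20, 20, 20)
  mask <- array(TRUE, dims)
  kerns <- lapply(dims, function(n)
    rehoflow:::gauss_kernel_matrix(n, 6 / 2.3548 / 3))
  set.seed(3)
  sm_maps <- lapply(1:12, function(i)
    rehoflow:::conv_separable(array(rnorm(prod(dims)), dims), kerns))
  sm_maps <- lapply(sm_maps, function(m) m / sd(m))
  est <- estimate_smoothness(sm_maps, mask, 3)
  expect_lt(max(abs(est$fwhm_mm - 6)), 1)
  # independent noise: FWHM about one voxel
  wn <- lapply(1:12, function(i) array(rnorm(prod(dims)), dims))
  est2 <- estimate_smoothness(wn, mask, 3)
  expect_lt(max(abs(est2$fwhm_vox - 1.18)), 0.1)
  expect_error(estimate_smoothness(wn[1:2], mask, 3), "3 residual")
  # resels scale with voxel volume for a fixed kernel in mm
  est3 <- estimate_smoothness(wn, mask, 6)
  expect_equal(est3$resels, est2$resels)     # defined in voxel units
})

test_that("connected components honour the connectivity definition", {
  dims <- c(10, 10, 10)
  supra <- array(FALSE, dims)
  supra[2:3, 2:3, 2:3] <- TRUE               # cube of 8
  supra[7:8, 7:8, 7:8] <- TRUE               # disjoint cube of 8
  stat <- array(1, dims); stat[2, 2, 2] <- 5
  cl <- extract_clusters(supra, stat)
  expect_length(cl, 2)
  expect_equal(vapply(cl, `[[`, 1L, "extent"), c(8L, 8L))
  expect_equal(cl[[1]]$peak_stat, 5)
  expect_equal(cl[[1]]$peak_mm, c(1, 1, 1) * 3)   # voxel (2,2,2), 0-based mm
  single <- array(FALSE, dims); single[5, 5, 5] <- TRUE
  expect_equal(extract_clusters(single, stat)[[1]]$extent, 1L)
  # diagonal-touching voxels: one component at 26, two at 6
  diag2 <- array(FALSE, dims)
  diag2[4, 4, 4] <- TRUE; diag2[5, 5, 5] <- TRUE
  expect_length(extract_clusters(diag2, stat, connectivity = 26), 1)
  expect_length(extract_clusters(diag2, stat, connectivity = 6), 2)
  expect_length(extract_clusters(array(FALSE, dims), stat), 0)
})

test_that("GRF thresholding behaves monotonically and handles extremes", {
  set.seed(4)
  dims <- c(16, 16, 16)
  mask <- array(TRUE, dims)
  kerns <- lapply(dims, function(n)
    rehoflow:::gauss_kernel_matrix(n, 6 / 2.3548 / 3))
  gen <- function(mu) {
    a <- rehoflow:::conv_separable(array(rnorm(prod(dims)), dims), kerns)
    a <- a / sd(a)
    a[6:10, 6:10, 6:10] <- a[6:10, 6:10, 6:10] + mu
    stat_map(a, mask)
  }
  ma <- lapply(1:10, function(i) gen(1.5))
  mb <- lapply(1:10, function(i) gen(0))
  tt <- voxelwise_ttest(ma, mb)
  res <- grf_cluster_threshold(tt, voxel_size_mm = 3)
  expect_gt(length(res$clusters), 0)
  expect_true(all(res$table$cluster_p < 0.05))
  # stricter voxel p never increases suprathreshold voxel count
  n_supra <- function(p) sum(abs(tt$tmap$values) > qt(1 - p / 2, tt$df))
  expect_gte(n_supra(0.01), n_supra(0.001))
  # extreme threshold empties the result without error
  res2 <- grf_cluster_threshold(tt, voxel_p = 1e-9, voxel_size_mm = 3)
  expect_length(res2$clusters, 0)
  expect_equal(nrow(res2$table), 0)
})

test_that("cluster p decreases with extent at fixed smoothness", {
  p_of <- function(k) rehoflow:::grf_cluster_p(k, u = qt(1 - 0.0025, 18),
                                               df = 18, resels = 500,
                                               n_voxels = 13824)
  ps <- vapply(c(5, 20, 80, 320), p_of, 1)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("cluster ROIs round-trip through the time-series extractor", {
  dims <- c(8, 8, 8)
  supra <- array(FALSE, dims); supra[3:4, 3:4, 3] <- TRUE
  stat <- array(2, dims)
  cl <- extract_clusters(supra, stat)[[1]]
  roi <- define_roi_from_cluster(cl, dims)
  expect_equal(sum(roi), cl$extent)
  vol <- noise_volume(dims, nt = 20, seed = 7)
  manual <- colMeans(matrix(vol$data, prod(dims))[which(roi), ])
  expect_equal(extract_roi_timeseries(vol, roi), manual)
  expect_error(define_roi_from_cluster(list(voxels = integer(0)), dims),
               "empty")
})
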