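#' Discard initial volumes for signal stabilisation
#'
#' Scanner signal needs several TRs to reach steady state; the standard
#' remedy is to drop the first `k` volumes before any further
#' processing.
#'
#' @param vol A [bold_volume].
#' @param k Number of leading volumes to drop (default 10).
#' @return A [bold_volume] with `T - k` time points.
#' @export
discard_initial_volumes <- function(vol, k = 10) {
  stopifnot(inherits(vol, "bold_volume"))
  d <- dim(vol$data)
  if (k < 0 || k != round(k)) stop("`k` must be a non-negative integer")
  if (k >= d[4] - 1) stop(sprintf("cannot discard k = %d of T = %d volumes", k, d[4]))
  if (k == 0) return(vol)
  bold_volume(vol$data[, , , (k + 1):d[4], drop = FALSE],
              vol$affine, vol$tr, vol$mask)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus the three rotations (rad) scaled by a nominal
#' head radius, giving one scalar per volume. `FD[1] = 0` by convention.
#'
#' @param motion `T x 6` matrix: columns tx, ty, tz (mm), rx, ry, rz (rad).
#' @param head_radius_mm Radius converting rotations to arc length
#'   (default 50 mm).
#' @return Numeric vector of length `T` (mm).
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns (3 translations, 3 rotations)")
  if (nrow(motion) < 2L) stop("`motion` must have T >= 2 rows")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Flag subjects with excessive head motion
#'
#' A subject is excluded when their mean FD exceeds the cohort mean by
#' more than `n_sd` cohort standard deviations.
#'
#' @param mean_fd Numeric vector of per-subject mean FD (mm), length >= 3.
#' @param n_sd Exclusion threshold in cohort SD units (default 2.5).
#' @return Logical vector: `TRUE` = exclude.
#' @export
flag_motion_exclusions <- function(mean_fd, n_sd = 2.5) {
  if (length(mean_fd) < 3L) stop("need at least 3 subjects to define a cohort threshold")
  s <- stats::sd(mean_fd)
  if (s == 0) return(rep(FALSE, length(mean_fd)))
  mean_fd > mean(mean_fd) + n_sd * s
}

#' Friston 24-parameter motion regressor block
#'
#' Expands the six rigid-body parameters R into
#' `[R, R^2, R_{t-1}, R_{t-1}^2]` (24 columns); the lagged terms are
#' zero-padded at the first time point.
#'
#' @param motion `T x 6` motion-parameter matrix.
#' @return `T x 24` matrix with descriptive column names.
#' @export
build_friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns")
  if (nrow(motion) < 2L) stop("`motion` must have T >= 2 rows")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag1, lag1^2)
  par6 <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(par6, paste0(par6, "_sq"),
                     paste0(par6, "_lag"), paste0(par6, "_lag_sq"))
  out
}

#' Assemble the default nuisance confound set
#'
#' Friston-24 motion block plus mean white-matter and CSF signals
#' (26 columns). Columns are centred; an intercept is added by
#' [regress_nuisance()] itself.
#'
#' @param motion `T x 6` motion trace.
#' @param wm,csf Length-`T` tissue mean series (optional; dropped if `NULL`).
#' @return `T x C` confound matrix with column names.
#' @export
build_confounds <- function(motion, wm = NULL, csf = NULL) {
  x <- build_friston24(motion)
  if (!is.null(wm)) x <- cbind(x, wm = wm)
  if (!is.null(csf)) x <- cbind(x, csf = csf)
  x
}

#' Ideal frequency-domain band-pass filter
#'
#' Removes the temporal mean, transforms each voxel series to the
#' frequency domain, zeroes all bins with |f| outside `[low_hz, high_hz]`
#' and transforms back (rectangular/ideal filter, the convention of the
#' common resting-state toolboxes).
#'
#' @param x A [bold_volume], or a `T x V` numeric matrix with `tr` given.
#' @param low_hz,high_hz Pass band in Hz (defaults 0.01-0.08).
#' @param tr Sampling interval in seconds (taken from the volume if omitted).
#' @return Same type as `x`, filtered and demeaned.
#' @export
bandpass_filter <- function(x, low_hz = 0.01, high_hz = 0.08, tr = NULL) {
  if (inherits(x, "bold_volume")) {
    mat <- mask_matrix(x)
    out <- bandpass_filter(mat, low_hz, high_hz, tr = x$tr)
    return(set_mask_matrix(x, out))
  }
  mat <- as.matrix(x)
  if (is.null(tr)) stop("`tr` must be supplied for matrix input")
  nt <- nrow(mat)
  nyq <- 1 / (2 * tr)
  if (low_hz < 0 || high_hz <= low_hz || high_hz > nyq)
    stop(sprintf("band [%g, %g] Hz must satisfy 0 <= low < high <= Nyquist (%g Hz)",
                 low_hz, high_hz, nyq))
  mat <- sweep(mat, 2, colMeans(mat))
  freqs <- seq_len(nt) - 1
  freqs <- pmin(freqs, nt - freqs) / (nt * tr)  # |f| for each DFT bin
  keep <- freqs >= low_hz & freqs <= high_hz
  ft <- stats::mvfft(mat)
  ft[!keep, ] <- 0
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / nt
  dimnames(out) <- dimnames(mat)
  out
}

#' Regress nuisance confounds out of every voxel series
#'
#' Ordinary least squares per voxel with an internally added intercept;
#' returns the residuals. The design must be full rank: linearly
#' dependent columns raise an error naming them.
#'
#' @param vol A [bold_volume] (or `T x V` matrix).
#' @param confounds `T x C` confound matrix (e.g. from
#'   [build_confounds()]).
#' @return Residualised object of the same type.
#' @export
regress_nuisance <- function(vol, confounds) {
  confounds <- as.matrix(confounds)
  is_vol <- inherits(vol, "bold_volume")
  y <- if (is_vol) mask_matrix(vol) else as.matrix(vol)
  nt <- nrow(y)
  if (nrow(confounds) != nt) stop("confound rows must match the number of time points")
  if (nt <= ncol(confounds) + 1L)
    stop("need T > C + 1 time points for the nuisance regression")
  # drop constant columns duplicating the intercept before the rank check
  keep <- apply(confounds, 2, function(c) stats::sd(c) > 0)
  x <- cbind(`(intercept)` = 1, confounds[, keep, drop = FALSE])
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient confound design; dependent columns: ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrx, y)
  if (is_vol) set_mask_matrix(vol, res) else res
}

#' Separable Gaussian spatial smoothing
#'
#' Smooths a 3D map or every frame of a 4D volume with an isotropic (in
#' mm) Gaussian kernel of the given full width at half maximum, using
#' mask-normalised convolution: out-of-mask voxels contribute nothing and
#' the kernel weight is renormalised inside the mask, so a constant
#' in-mask map stays constant. The mask is re-applied afterwards.
#'
#' @param x A [bold_volume] or [stat_map].
#' @param fwhm_mm Kernel FWHM in mm (0 = identity). Default 6.
#' @param voxel_size_mm Voxel edge lengths (scalar or length 3); taken
#'   from the affine if omitted.
#' @return Smoothed object of the same type.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 6, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be non-negative")
  if (fwhm_mm == 0) return(x)
  is_vol <- inherits(x, "bold_volume")
  arr <- if (is_vol) x$data else x$values
  mask <- x$mask
  if (is.null(voxel_size_mm))
    voxel_size_mm <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  sig_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  kerns <- lapply(1:3, function(ax) gauss_kernel_matrix(dim(mask)[ax], sig_vox[ax]))
  msk <- array(as.numeric(mask), dim(mask))
  wt <- conv_separable(msk, kerns)
  norm3 <- function(a) {
    out <- conv_separable(a * msk, kerns)
    out <- ifelse(wt > 0, out / pmax(wt, .Machine$double.eps), 0)
    out * msk
  }
  if (is_vol) {
    d <- dim(arr)
    msk4 <- array(msk, d)        # recycle the 3D mask over time
    out <- conv_separable(arr * msk4, kerns)
    wt4 <- array(wt, d)
    out <- ifelse(wt4 > 0, out / pmax(wt4, .Machine$double.eps), 0) * msk4
    bold_volume(out, x$affine, x$tr, mask)
  } else {
    stat_map(norm3(arr), mask, x$affine, x$kind)
  }
}

# dense banded convolution matrix for one axis (truncated at 4 sigma)
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  k <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  k[abs(outer(idx, idx, "-")) > ceiling(4 * sigma)] <- 0
  k / sum(exp(-(-ceiling(4 * sigma):ceiling(4 * sigma))^2 / (2 * sigma^2)))
}

# apply per-axis kernel matrices to the first three axes of a 3D or 4D
# array (a trailing time axis is carried along unchanged)
conv_separable <- function(a, kerns) {
  d <- dim(a)
  a <- array(kerns[[1]] %*% matrix(a, d[1]), d)
  for (ax in 2:3) {
    perm <- c(ax, seq_along(d)[-ax])
    a <- aperm(a, perm)
    a <- array(kerns[[ax]] %*% matrix(a, d[ax]), d[perm])
    a <- aperm(a, order(perm))
  }
  a
}

#' Mean time series over a tissue mask
#'
#' @param vol A [bold_volume].
#' @param tissue_mask Logical 3D array (e.g. eroded WM or CSF mask).
#' @return Numeric vector of length `T`.
#' @export
extract_tissue_signal <- function(vol, tissue_mask) {
  stopifnot(inherits(vol, "bold_volume"))
  tissue_mask <- array(as.logical(tissue_mask), dim(vol$mask))
  if (!any(tissue_mask)) stop("tissue mask is empty")
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  colMeans(m[as.vector(tissue_mask), , drop = FALSE])
}

#' Run the functional preprocessing chain on one subject
#'
#' Fixed stage order: discard leading volumes, band-pass filter, then
#' regress the nuisance set (confounds are themselves band-passed with
#' the same band so that regression cannot reintroduce out-of-band
#' nuisance variance). Smoothing is *not* applied here: regional
#' homogeneity must be computed on unsmoothed residuals.
#'
#' @param vol A [bold_volume].
#' @param motion `T x 6` motion trace matching the undiscarded length.
#' @param wm_mask,csf_mask Optional tissue masks for mean-signal
#'   confounds.
#' @param k_discard Leading volumes to drop (default 10).
#' @param low_hz,high_hz Band-pass edges (defaults 0.01 / 0.08 Hz).
#' @return A residualised, filtered [bold_volume].
#' @export
preprocess_subject <- function(vol, motion, wm_mask = NULL, csf_mask = NULL,
                               k_discard = 10, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(vol, "bold_volume"))
  motion <- as.matrix(motion)
  if (nrow(motion) == dim(vol$data)[4] && k_discard > 0)
    motion <- motion[-seq_len(k_discard), , drop = FALSE]
  vol <- discard_initial_volumes(vol, k_discard)
  if (nrow(motion) != dim(vol$data)[4])
    stop("motion trace length does not match the volume after discarding")
  vol <- bandpass_filter(vol, low_hz, high_hz)
  wm <- if (!is.null(wm_mask)) extract_tissue_signal(vol, wm_mask)
  csf <- if (!is.null(csf_mask)) extract_tissue_signal(vol, csf_mask)
  conf <- build_confounds(motion, wm, csf)
  conf_c <- sweep(conf, 2, colMeans(conf))
  nz <- apply(conf_c, 2, function(x) stats::sd(x) > 0)
  conf_c[, nz] <- bandpass_filter(conf_c[, nz, drop = FALSE],
                                  low_hz, high_hz, tr = vol$tr)
  # filtering projects the confounds onto the pass-band Fourier basis; at
  # short T that subspace has fewer dimensions than columns, so keep an
  # independent subset (the residual space is unchanged)
  qrc <- qr(conf_c)
  conf_c <- conf_c[, qrc$pivot[seq_len(qrc$rank)], drop = FALSE]
  # guard against confound saturation of the filtered subspace: the data
  # live in the retained frequency bins, and regression can only remove
  # dimensions from that subspace
  nt <- dim(vol$data)[4]
  f <- pmin(0:(nt - 1), nt - (0:(nt - 1))) / (nt * vol$tr)
  band_dims <- sum(f >= low_hz & f <= high_hz)
  if (band_dims - qrc$rank < 4)
    stop(sprintf(paste0("confound model (rank %d) saturates the %d-dimensional ",
                        "pass-band subspace; increase T, widen the band, or ",
                        "reduce the confound set"), qrc$rank, band_dims))
  regress_nuisance(vol, conf_c)
}
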