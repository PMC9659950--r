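#' Mean time series over a region of interest
#'
#' @param vol A [bold_volume].
#' @param roi Logical 3D array (an ROI mask, e.g. a significant cluster).
#' @return Numeric vector of length `T`.
#' @export
extract_roi_timeseries <- function(vol, roi) {
  stopifnot(inherits(vol, "bold_volume"))
  roi <- array(as.logical(roi), dim(vol$mask))
  if (!any(roi)) stop("ROI mask is empty")
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  colMeans(m[as.vector(roi), , drop = FALSE])
}

#' Seed-based whole-brain correlation map
#'
#' Pearson correlation between the seed series and every in-mask voxel
#' series. Zero-variance voxels get r = 0 and are recorded in the
#' `"flagged"` attribute.
#'
#' @param vol A [bold_volume].
#' @param seed_series Numeric vector of length `T` with positive SD.
#' @return A [stat_map] of Pearson r (`kind = "r"`).
#' @export
fc_map <- function(vol, seed_series) {
  stopifnot(inherits(vol, "bold_volume"))
  nt <- dim(vol$data)[4]
  if (length(seed_series) != nt) stop("seed series length must equal T")
  if (stats::sd(seed_series) == 0) stop("seed series is constant")
  y <- mask_matrix(vol)                     # T x V
  s <- seed_series - mean(seed_series)
  yc <- sweep(y, 2, colMeans(y))
  denom <- sqrt(sum(s^2)) * sqrt(colSums(yc^2))
  r <- as.vector(crossprod(yc, s))
  zero_var <- denom == 0
  r <- ifelse(zero_var, 0, r / ifelse(zero_var, 1, denom))
  r <- pmin(1, pmax(-1, r))
  vals <- array(0, dim(vol$mask))
  vals[vol$mask] <- r
  out <- stat_map(vals, vol$mask, vol$affine, kind = "r")
  attr(out, "flagged") <- which(zero_var)
  out
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilising transform applied to
#' correlation maps before parametric group tests. Correlations at
#' exactly +/-1 are clipped to `1 - 1e-7` with a warning.
#'
#' @param r Numeric vector/array of correlations, `|r| <= 1`.
#' @return z values of the same shape.
#' @export
fisher_r_to_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| = 1 clipped to 1 - 1e-7 before atanh")
    r <- pmin(1 - 1e-7, pmax(-1 + 1e-7, r))
  }
  atanh(r)
}

#' Seed-based FC maps for a whole cohort
#'
#' For every subject and every ROI: extract the ROI mean series, compute
#' the whole-brain correlation map, and Fisher-transform it. Input
#' volumes should be preprocessed; by convention they are also smoothed
#' (pass `presmoothed = FALSE` to have this function smooth them first).
#'
#' @param volumes List of [bold_volume]s (one per subject).
#' @param rois Named list of logical ROI masks.
#' @param presmoothed If `FALSE`, smooth each volume with `fwhm_mm`
#'   before correlation (default `TRUE`: caller already smoothed).
#' @param fwhm_mm Kernel used when `presmoothed = FALSE`.
#' @return Nested list: `result[[subject]][[roi]]` is a z-FC [stat_map]
#'   (`kind = "zfc"`).
#' @export
fc_pipeline <- function(volumes, rois, presmoothed = TRUE, fwhm_mm = 6) {
  if (length(rois) == 0) stop("no ROIs supplied")
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  lapply(volumes, function(vol) {
    if (!presmoothed) vol <- smooth_gaussian(vol, fwhm_mm)
    lapply(rois, function(roi) {
      if (!identical(dim(roi), dim(vol$mask)))
        stop("ROI grid does not match volume grid")
      rmap <- fc_map(vol, extract_roi_timeseries(vol, roi))
      z <- suppressWarnings(fisher_r_to_z(rmap$values))
      z[!rmap$mask] <- 0
      stat_map(z, rmap$mask, rmap$affine, kind = "zfc")
    })
  })
}
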