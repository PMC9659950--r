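#' Midranks of a time series
#'
#' Ranks 1..T with ties receiving the average of the ranks they span.
#' A constant series (all values tied) is flagged with a warning.
#'
#' @param series Numeric vector, length >= 2.
#' @return Numeric vector of ranks.
#' @export
rank_timeseries <- function(series) {
  if (length(series) < 2L) stop("series must have T >= 2")
  if (stats::sd(series) == 0) warning("constant series: all ranks tied")
  rank(series, ties.method = "average")
}

#' Kendall's coefficient of concordance W
#'
#' Agreement among `K` rankings of `n` items:
#' \deqn{W = \frac{\sum_t R_t^2 - n \bar R^2}{K^2 (n^3 - n)/12},}
#' where \eqn{R_t} is the rank total of item `t` over the `K` rankings
#' and \eqn{\bar R = K(n+1)/2}. `W = 1` for identical tie-free rankings;
#' the expected value under independent rankings is `1/K`. The default
#' follows the classical untied-denominator form (ties in BOLD series
#' are measure-zero); `tie_correction = TRUE` subtracts the usual tie
#' term \eqn{K \sum_j T_j / 12} from the denominator.
#'
#' @param rank_matrix `K x n` matrix: each row one series' ranks over the
#'   `n` time points (midranks allowed).
#' @param tie_correction Apply the tie-corrected denominator?
#' @return W in `[0, 1]`. Degenerate all-constant input returns 0 with a
#'   warning.
#' @export
kendall_w <- function(rank_matrix, tie_correction = FALSE) {
  rank_matrix <- as.matrix(rank_matrix)
  k <- nrow(rank_matrix)
  n <- ncol(rank_matrix)
  if (k < 2L || n < 2L) stop("need K >= 2 series and n >= 2 time points")
  if (all(apply(rank_matrix, 1, function(r) max(r) == min(r)))) {
    warning("degenerate (all-constant) rankings: W undefined, returning 0")
    return(0)
  }
  ri <- colSums(rank_matrix)
  rbar <- k * (n + 1) / 2
  s <- sum(ri^2) - n * rbar^2
  denom <- k^2 * (n^3 - n) / 12
  if (tie_correction) {
    tie_term <- sum(apply(rank_matrix, 1, function(r) {
      tt <- table(r)
      sum(tt^3 - tt)
    }))
    denom <- denom - k * tie_term / 12
  }
  if (denom <= 0) {
    warning("degenerate (all-constant) rankings: W undefined, returning 0")
    return(0)
  }
  max(0, s / denom)
}

#' Voxelwise regional homogeneity (ReHo) map
#'
#' For every in-mask voxel, Kendall's W over the ranked time series of
#' the voxel and its neighbours (27 = faces + edges + corners, 19, or 7),
#' with the neighbourhood restricted to the mask. `K` is the realised
#' in-mask neighbourhood size; voxels with `K < min_k` are zeroed and
#' dropped from the output mask so that boundary voxels with too few
#' neighbours never enter group statistics. Input should be filtered,
#' nuisance-regressed and *unsmoothed*.
#'
#' @param vol A [bold_volume].
#' @param neighborhood Neighbourhood definition: 7, 19 or 27 (default).
#' @param min_k Minimum in-mask neighbourhood size (default 7).
#' @return A [stat_map] with `kind = "reho"`, values in `[0, 1]`.
#' @export
reho_map <- function(vol, neighborhood = 27, min_k = 7) {
  stopifnot(inherits(vol, "bold_volume"))
  if (!neighborhood %in% c(7, 19, 27))
    stop("`neighborhood` must be one of 7, 19, 27")
  d <- dim(vol$data)
  res <- .reho_w_cpp(as.numeric(vol$data), as.logical(vol$mask),
                     as.integer(d), as.integer(neighborhood),
                     as.integer(min_k))
  w <- array(res$w, d[1:3])
  keep <- array(res$keep, d[1:3]) & vol$mask
  w[!keep] <- 0
  stat_map(w, keep, vol$affine, kind = "reho")
}

#' Divide a ReHo map by its in-mask global mean
#'
#' Removes between-subject global level differences; the resulting map
#' (mReHo) has in-mask mean exactly 1.
#'
#' @param map A [stat_map] (raw ReHo).
#' @return A [stat_map] with `kind = "mreho"`.
#' @export
normalize_global_mean <- function(map) {
  stopifnot(inherits(map, "stat_map"))
  g <- mean(map$values[map$mask])
  if (g <= 0) stop("in-mask global mean must be positive")
  v <- map$values / g
  v[!map$mask] <- 0
  stat_map(v, map$mask, map$affine, kind = "mreho")
}

#' Z-standardise a map within its mask
#'
#' Subtract the in-mask mean and divide by the in-mask SD, giving a map
#' with mean 0 and SD 1 inside the mask (the "szReHo" convention when
#' applied to smoothed mReHo; also applicable to any statistic map).
#'
#' @param map A [stat_map].
#' @param kind Output kind tag (default `"szreho"`).
#' @return A standardised [stat_map].
#' @export
standardize_z <- function(map, kind = "szreho") {
  stopifnot(inherits(map, "stat_map"))
  v <- map$values[map$mask]
  s <- sqrt(mean((v - mean(v))^2))   # population SD
  if (s == 0) stop("in-mask SD is zero; cannot standardise")
  out <- (map$values - mean(v)) / s
  out[!map$mask] <- 0
  stat_map(out, map$mask, map$affine, kind = kind)
}

#' Full single-subject ReHo chain
#'
#' Raw voxelwise W, division by the in-mask global mean, Gaussian
#' smoothing, then either z-standardisation (default, the "szReHo" used
#' for group statistics) or Fisher's atanh transform (`z_method =
#' "atanh"`, provided because W is bounded in \[0, 1\]; note W is not a
#' correlation, so atanh here is a variance-stabilising convenience, not
#' the r-to-z transform).
#'
#' @param vol Preprocessed, unsmoothed [bold_volume].
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 6).
#' @param neighborhood,min_k Passed to [reho_map()].
#' @param z_method `"standardize"` (default) or `"atanh"`.
#' @return List with elements `raw`, `m`, `smz` ([stat_map]s).
#' @export
reho_pipeline <- function(vol, fwhm_mm = 6, neighborhood = 27, min_k = 7,
                          z_method = c("standardize", "atanh")) {
  z_method <- match.arg(z_method)
  raw <- reho_map(vol, neighborhood, min_k)
  m <- normalize_global_mean(raw)
  sm <- smooth_gaussian(m, fwhm_mm)
  smz <- if (z_method == "standardize") {
    standardize_z(sm)
  } else {
    v <- pmin(sm$values, 1 - 1e-7)
    out <- atanh(pmax(v, 0))
    out[!sm$mask] <- 0
    stat_map(out, sm$mask, sm$affine, kind = "szreho")
  }
  list(raw = raw, m = m, smz = smz)
}
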