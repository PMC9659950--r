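#' Voxelwise two-sample t-test between group map stacks
#'
#' Pooled-variance t per in-mask voxel, sign convention group A minus
#' group B, `df = nA + nB - 2`. Standardised subject residual maps
#' (subject map minus its group mean, divided by the pooled voxel SD)
#' are returned for field-smoothness estimation.
#'
#' @param maps_a,maps_b Lists of [stat_map]s (one per subject), sharing
#'   one grid.
#' @param mask Optional analysis mask; defaults to the intersection of
#'   all map masks.
#' @param equal_var Pooled-variance t (default `TRUE`; `FALSE` gives
#'   Welch, df by Satterthwaite per voxel).
#' @return A list of class `group_ttest`: `tmap` ([stat_map], kind
#'   `"t"`), `df`, `n_a`, `n_b`, and `residuals` (list of standardised
#'   residual 3D arrays).
#' @export
voxelwise_ttest <- function(maps_a, maps_b, mask = NULL, equal_var = TRUE) {
  na <- length(maps_a); nb <- length(maps_b)
  if (na < 2L || nb < 2L) stop("need at least 2 subjects per group")
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(c(maps_a, maps_b), `[[`, "mask"))
  }
  aff <- maps_a[[1]]$affine
  stack <- function(maps) do.call(cbind, lapply(maps, function(m) m$values[mask]))
  xa <- stack(maps_a); xb <- stack(maps_b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (equal_var) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tv <- ifelse(se > 0, (ma - mb) / se, 0)
  tvals <- array(0, dim(mask)); tvals[mask] <- tv
  pooled_sd <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  pooled_sd[pooled_sd == 0] <- 1
  resid <- c(
    lapply(seq_len(na), function(i) {
      r <- array(0, dim(mask)); r[mask] <- (xa[, i] - ma) / pooled_sd; r
    }),
    lapply(seq_len(nb), function(i) {
      r <- array(0, dim(mask)); r[mask] <- (xb[, i] - mb) / pooled_sd; r
    })
  )
  structure(list(tmap = stat_map(tvals, mask, aff, kind = "t"),
                 df = df, n_a = na, n_b = nb, residuals = resid),
            class = "group_ttest")
}

#' Estimate field smoothness from standardised residuals
#'
#' Per-axis FWHM from the variance of spatial first differences of the
#' standardised residual maps: for a unit-variance Gaussian-autocorrelated
#' field the difference variance `v` gives `FWHM = 2 sqrt(ln 2 / v)`
#' voxels, so independent noise (`v = 2`) yields roughly one voxel.
#' RESELs = in-mask voxel count / product of per-axis FWHM (in voxels).
#'
#' @param residuals List of >= 3 standardised residual 3D arrays (from
#'   [voxelwise_ttest()]).
#' @param mask Logical analysis mask.
#' @param voxel_size_mm Voxel edge lengths (scalar or length 3).
#' @return List: `fwhm_mm` (length 3), `fwhm_vox`, `resels`, `n_voxels`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size_mm = 3) {
  if (length(residuals) < 3L) stop("need at least 3 residual maps")
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  num <- den <- numeric(3)
  for (r in residuals) {
    rv <- r[mask]
    s2 <- mean(rv^2)
    if (s2 == 0) next
    for (ax in 1:3) {
      d <- dim(mask)
      idx_lo <- slice_index(d, ax, 1, d[ax] - 1)
      idx_hi <- slice_index(d, ax, 2, d[ax])
      ok <- mask[idx_lo] & mask[idx_hi]
      if (!any(ok)) next
      dif <- (r[idx_hi][ok] - r[idx_lo][ok])
      num[ax] <- num[ax] + sum(dif^2)
      den[ax] <- den[ax] + length(dif) * s2
    }
  }
  v <- ifelse(den > 0, num / den, 2)
  fwhm_vox <- 2 * sqrt(log(2) / pmax(v, 1e-12))
  fwhm_mm <- fwhm_vox * voxel_size_mm
  nvox <- sum(mask)
  list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_vox,
       resels = nvox / prod(fwhm_vox), n_voxels = nvox)
}

# linear indices of the sub-array spanning positions from..to on axis ax
slice_index <- function(d, ax, from, to) {
  idx <- lapply(seq_along(d), function(i) seq_len(d[i]))
  idx[[ax]] <- from:to
  arr <- array(seq_len(prod(d)), d)
  do.call(`[`, c(list(arr), idx))
}

#' Connected suprathreshold components of a map
#'
#' Labels the connected components of a binary suprathreshold mask under
#' 6-, 18- or 26-connectivity and reports each cluster's extent, peak
#' |statistic| voxel and its mm coordinate through the affine.
#'
#' @param supra Logical 3D array of suprathreshold voxels.
#' @param stat_values 3D array of the underlying statistic (for peaks).
#' @param affine 4x4 voxel-to-mm affine.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List of clusters, each a list with `voxels` (linear indices),
#'   `extent`, `peak_ijk`, `peak_mm`, `peak_stat`.
#' @export
extract_clusters <- function(supra, stat_values, affine = diag(c(3, 3, 3, 1)),
                             connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) stop("`connectivity` must be 6, 18 or 26")
  d <- dim(supra)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  man <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[man > 0 & man <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ]
  off_lin <- offs$dx + d[1] * (offs$dy + d[2] * offs$dz)
  vox <- which(supra)
  if (length(vox) == 0) return(list())
  in_set <- logical(prod(d)); in_set[vox] <- TRUE
  visited <- logical(prod(d))
  coords <- arrayInd(vox, d)
  coord_of <- matrix(0L, prod(d), 3)
  coord_of[vox, ] <- coords
  clusters <- list()
  for (v0 in vox) {
    if (visited[v0]) next
    queue <- v0; visited[v0] <- TRUE
    members <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      cij <- coord_of[cur, ]
      nb_ij <- cbind(cij[1] + offs$dx, cij[2] + offs$dy, cij[3] + offs$dz)
      ok <- nb_ij[, 1] >= 1 & nb_ij[, 1] <= d[1] &
            nb_ij[, 2] >= 1 & nb_ij[, 2] <= d[2] &
            nb_ij[, 3] >= 1 & nb_ij[, 3] <= d[3]
      nb <- nb_ij[ok, 1] + d[1] * (nb_ij[ok, 2] - 1 + d[2] * (nb_ij[ok, 3] - 1))
      nb <- nb[in_set[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    pk <- members[which.max(abs(stat_values[members]))]
    clusters[[length(clusters) + 1]] <- list(
      voxels = sort(members),
      extent = length(members),
      peak_ijk = coord_of[pk, ],
      peak_mm = drop(voxel_to_mm(coord_of[pk, ], affine)),
      peak_stat = stat_values[pk])
  }
  clusters[order(vapply(clusters, `[[`, 1L, "extent"), decreasing = TRUE)]
}

# Euler-characteristic density (D = 3) at threshold u: Gaussian field
# (df = Inf) or unit-variance t field with df degrees of freedom
ec_density_3d <- function(u, df = Inf) {
  c0 <- (4 * log(2))^(3 / 2) / (2 * pi)^2
  if (is.infinite(df)) return(c0 * (u^2 - 1) * exp(-u^2 / 2))
  c0 * ((df - 1) / df * u^2 - 1) * (1 + u^2 / df)^(-(df - 1) / 2)
}

# cluster-level p for extent k (voxels) at t threshold u with df:
# expected cluster count from the t-field EC density over the mask
# RESELs, extent tail by the exponential approximation
grf_cluster_p <- function(k, u, df, resels, n_voxels) {
  em <- max(resels * ec_density_3d(u, df), 1e-12)  # expected cluster count
  en <- n_voxels * stats::pt(u, df, lower.tail = FALSE) / em
  beta <- (gamma(5 / 2) / max(en, 1e-12))^(2 / 3)
  p_ext <- exp(-beta * k^(2 / 3))
  1 - exp(-em * p_ext)
}

#' Gaussian-random-field cluster-level thresholding of a t-map
#'
#' Classical RFT cluster inference: the t-field is thresholded at the
#' voxel-level quantile (two-tailed by default, i.e. `voxel_p/2` per
#' tail), suprathreshold components are formed, and each cluster's
#' family-wise p-value is computed from the expected cluster count (the
#' t-field Euler-characteristic density at the threshold, integrated
#' over the mask RESELs) and the exponential approximation to the
#' cluster-extent distribution. Clusters with `p < cluster_alpha`
#' survive.
#'
#' @param ttest A `group_ttest` object (or a [stat_map] t-map with `df`
#'   supplied).
#' @param smoothness Result of [estimate_smoothness()]; estimated from
#'   the t-test residuals if omitted.
#' @param voxel_p Cluster-forming voxel-level p (default 0.005).
#' @param cluster_alpha Cluster-level familywise alpha (default 0.05).
#' @param two_tailed Split `voxel_p` over both tails (default `TRUE`).
#' @param connectivity Component connectivity (default 26).
#' @param df Degrees of freedom when `ttest` is a bare [stat_map].
#' @param voxel_size_mm Used when smoothness must be estimated.
#' @return A list of class `grf_result`: `clusters` (surviving clusters,
#'   each with `sign`, `extent`, `peak_mm`, `peak_stat`, `p`), `table`
#'   (data frame), `threshold_t`, `smoothness`, plus grid metadata.
#' @export
grf_cluster_threshold <- function(ttest, smoothness = NULL, voxel_p = 0.005,
                                  cluster_alpha = 0.05, two_tailed = TRUE,
                                  connectivity = 26, df = NULL,
                                  voxel_size_mm = 3) {
  if (inherits(ttest, "group_ttest")) {
    tmap <- ttest$tmap; df <- ttest$df
    if (is.null(smoothness))
      smoothness <- estimate_smoothness(ttest$residuals, tmap$mask,
                                        voxel_size_mm)
  } else {
    tmap <- ttest
    if (is.null(df)) stop("`df` required when passing a bare t-map")
    if (is.null(smoothness)) stop("`smoothness` required when passing a bare t-map")
  }
  if (voxel_p <= 0 || voxel_p >= 1) stop("`voxel_p` must be in (0,1)")
  p_tail <- if (two_tailed) voxel_p / 2 else voxel_p
  u_t <- stats::qt(1 - p_tail, df)
  tails <- if (two_tailed) c(1, -1) else 1
  out <- list()
  for (sgn in tails) {
    supra <- (sgn * tmap$values > u_t) & tmap$mask
    if (!any(supra)) next
    cl <- extract_clusters(supra, tmap$values, tmap$affine, connectivity)
    for (c1 in cl) {
      p <- grf_cluster_p(c1$extent, u_t, df, smoothness$resels,
                         smoothness$n_voxels)
      if (p < cluster_alpha) {
        c1$sign <- sgn; c1$p <- p
        out[[length(out) + 1]] <- c1
      }
    }
  }
  tab <- if (length(out)) {
    data.frame(
      cluster = seq_along(out),
      sign = vapply(out, `[[`, 1, "sign"),
      peak_x_mm = vapply(out, function(c) c$peak_mm[1], 1),
      peak_y_mm = vapply(out, function(c) c$peak_mm[2], 1),
      peak_z_mm = vapply(out, function(c) c$peak_mm[3], 1),
      extent = vapply(out, `[[`, 1L, "extent"),
      peak_t = vapply(out, `[[`, 1, "peak_stat"),
      cluster_p = vapply(out, `[[`, 1, "p"))
  } else {
    data.frame(cluster = integer(), sign = numeric(), peak_x_mm = numeric(),
               peak_y_mm = numeric(), peak_z_mm = numeric(),
               extent = integer(), peak_t = numeric(), cluster_p = numeric())
  }
  structure(list(clusters = out, table = tab, threshold_t = u_t,
                 smoothness = smoothness, mask = tmap$mask,
                 affine = tmap$affine, df = df),
            class = "grf_result")
}

#' @export
print.grf_result <- function(x, ...) {
  cat(sprintf("<grf_result> %d surviving cluster(s), |t| threshold %.3f (df = %.1f)\n",
              length(x$clusters), x$threshold_t, x$df))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Thresholded t-map restricted to surviving clusters
#'
#' @param grf A `grf_result`.
#' @param ttest The `group_ttest` (or t [stat_map]) it came from.
#' @return A [stat_map] holding t values inside surviving clusters and 0
#'   elsewhere.
#' @export
grf_thresholded_map <- function(grf, ttest) {
  tmap <- if (inherits(ttest, "group_ttest")) ttest$tmap else ttest
  out <- array(0, dim(tmap$values))
  for (cl in grf$clusters) out[cl$voxels] <- tmap$values[cl$voxels]
  stat_map(out, grf$mask, grf$affine, kind = "t")
}

#' Boolean ROI mask from a surviving cluster
#'
#' @param cluster One element of a `grf_result`'s `clusters` list.
#' @param dims Grid dimensions (length 3), e.g. `dim(mask)`.
#' @return Logical 3D array marking the cluster's voxels.
#' @export
define_roi_from_cluster <- function(cluster, dims) {
  if (is.null(cluster$voxels) || length(cluster$voxels) == 0)
    stop("cluster is empty")
  roi <- array(FALSE, dims)
  roi[cluster$voxels] <- TRUE
  roi
}
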