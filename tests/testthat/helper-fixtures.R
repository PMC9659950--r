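# shared fixtures and independent oracles used across test files

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# independent naive ReHo oracle: triple loop over voxels, Kendall's W
# computed directly from the printed formula on the in-mask neighbourhood
naive_reho <- function(vol, neighborhood = 27, min_k = 7) {
  d <- dim(vol$data)
  w <- array(0, d[1:3])
  keep <- array(FALSE, d[1:3])
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man <= switch(as.character(neighborhood),
                             "7" = 1, "19" = 2, "27" = 3), , drop = FALSE]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!vol$mask[x, y, z]) next
    nb <- sweep(offs, 2, c(x, y, z), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    nb <- nb[vol$mask[nb], , drop = FALSE]
    k <- nrow(nb)
    if (k < min_k) next
    ranks <- t(apply(nb, 1, function(ijk)
      rank(vol$data[ijk[1], ijk[2], ijk[3], ])))
    n <- ncol(ranks)
    ri <- colSums(ranks)
    s <- sum(ri^2) - n * (k * (n + 1) / 2)^2
    w[x, y, z] <- max(0, s / (k^2 * (n^3 - n) / 12))
    keep[x, y, z] <- TRUE
  }
  list(w = w, keep = keep)
}

# small volume whose voxel series are iid noise
noise_volume <- function(dims = c(6, 6, 6), nt = 40, seed = 1, tr = 2) {
  set.seed(seed)
  bold_volume(array(rnorm(prod(dims) * nt), c(dims, nt)), tr = tr)
}

# a quickly generated planted-effect cohort spec at test scale
small_test_spec <- function(n1 = 6, n2 = 6, nt = 64, drop = 0.8, seed = 1,
                            grid = c(24L, 24L, 24L)) {
  brain <- rehoflow:::default_brain_mask(grid)
  reg <- rehoflow:::cube_mask(grid, c(0.4, 0.4, 0.5), 2) & brain
  tgt <- rehoflow:::cube_mask(grid, c(0.62, 0.67, 0.55), 2) & brain
  # motion-free: at reduced T the pass band cannot absorb the Friston-24
  # confound model, so scaled-down cohorts regress tissue signals only
  cohort_spec(grid_shape = grid, n_group1 = n1, n_group2 = n2,
              n_timepoints = nt, motion_amplitude = 0,
              effect_regions = list(list(mask = reg, drop = drop)),
              seed_coupling = list(seed = reg, target = tgt, r = c(0.2, 0.6)),
              rng_seed = seed)
}
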