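#' Specification of a synthetic two-group BOLD cohort
#'
#' Captures everything needed to generate a reproducible cohort: grid
#' and acquisition parameters, group sizes, planted local-synchrony
#' effects, planted seed-target coupling, noise structure and clinical
#' summary parameters. Defaults emulate a two-group resting-state study
#' (~48/47 subjects, 240 volumes at TR = 2 s, 3 mm grid) at desk scale.
#'
#' The signal model per voxel is
#' `x = w * latent_region + sqrt(1 - w^2) * noise + drift + motion
#' leakage + global (WM/CSF-like) components`, where `noise` is AR(1)
#' in time and spatially smoothed, and the synchrony weight `w` of an
#' effect region is reduced by the region's `drop` in group 1 — the
#' quantity regional homogeneity measures is manipulated directly.
#'
#' @param grid_shape Voxels per axis (default `c(24, 24, 24)`).
#' @param n_timepoints Volumes per subject (default 240).
#' @param tr Repetition time, seconds (default 2).
#' @param n_group1,n_group2 Subject counts (defaults 48 / 47; group 1 is
#'   the impaired group).
#' @param voxel_size_mm Isotropic voxel size (default 3).
#' @param effect_regions List of `list(mask =, drop =)` entries: logical
#'   3D mask and synchrony drop in `[0, 1]` applied to group 1.
#'   `NULL` (default) plants two 125-voxel cubes with drop 0.5.
#' @param seed_coupling `list(seed =, target =, r = c(r1, r2))`: masks
#'   plus the per-group seed-target correlation. Default couples the
#'   first effect region to a separate 125-voxel target with r = 0.2
#'   (group 1) vs 0.5 (group 2). `NA` disables coupling.
#' @param base_synchrony Latent weight `w` of effect regions in group 2
#'   (default 0.7).
#' @param ar1_phi Temporal AR(1) coefficient of the noise (default 0.3).
#' @param spatial_fwhm_mm Spatial smoothness of the noise field
#'   (default 6).
#' @param motion_amplitude Scale of the random-walk motion traces
#'   (default 1; 0 = motionless).
#' @param rng_seed Master seed (default 1).
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(grid_shape = c(24, 24, 24), n_timepoints = 240,
                        tr = 2, n_group1 = 48, n_group2 = 47,
                        voxel_size_mm = 3, effect_regions = NULL,
                        seed_coupling = NULL, base_synchrony = 0.7,
                        ar1_phi = 0.3, spatial_fwhm_mm = 6,
                        motion_amplitude = 1, rng_seed = 1) {
  spec <- list(grid_shape = as.integer(grid_shape),
               n_timepoints = as.integer(n_timepoints), tr = tr,
               n_group1 = as.integer(n_group1),
               n_group2 = as.integer(n_group2),
               voxel_size_mm = voxel_size_mm,
               effect_regions = effect_regions,
               seed_coupling = seed_coupling,
               base_synchrony = base_synchrony, ar1_phi = ar1_phi,
               spatial_fwhm_mm = spatial_fwhm_mm,
               motion_amplitude = motion_amplitude,
               rng_seed = as.integer(rng_seed))
  spec$mask <- default_brain_mask(spec$grid_shape)
  if (is.null(spec$effect_regions)) {
    spec$effect_regions <- list(
      list(mask = cube_mask(spec$grid_shape, centre_frac = c(0.33, 0.33, 0.5),
                            half = 2), drop = 0.5),
      list(mask = cube_mask(spec$grid_shape, centre_frac = c(0.67, 0.62, 0.42),
                            half = 2), drop = 0.5))
  }
  if (is.null(spec$seed_coupling)) {
    spec$seed_coupling <- list(
      seed = spec$effect_regions[[1]]$mask,
      target = cube_mask(spec$grid_shape, centre_frac = c(0.42, 0.71, 0.62),
                         half = 2),
      r = c(0.2, 0.5))
  }
  # small WM / CSF-like compartments used for tissue-signal confounds
  spec$wm_mask <- cube_mask(spec$grid_shape, centre_frac = c(0.5, 0.5, 0.71),
                            half = 1)
  spec$csf_mask <- cube_mask(spec$grid_shape, centre_frac = c(0.5, 0.29, 0.5),
                             half = 1)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  chk <- function(ok, field, msg) if (!ok) stop(sprintf("invalid `%s`: %s", field, msg))
  chk(length(spec$grid_shape) == 3 && all(spec$grid_shape >= 8),
      "grid_shape", "must be 3 positive extents (>= 8 voxels each)")
  chk(spec$n_timepoints >= 8, "n_timepoints", "must be >= 8")
  chk(spec$tr > 0, "tr", "must be positive seconds")
  chk(spec$n_group1 >= 1, "n_group1", "must be positive")
  chk(spec$n_group2 >= 1, "n_group2", "must be positive")
  chk(spec$voxel_size_mm > 0, "voxel_size_mm", "must be positive")
  chk(spec$base_synchrony >= 0 && spec$base_synchrony <= 1,
      "base_synchrony", "must lie in [0, 1]")
  chk(abs(spec$ar1_phi) < 1, "ar1_phi", "must lie in (-1, 1)")
  chk(spec$spatial_fwhm_mm >= 0, "spatial_fwhm_mm", "must be non-negative")
  chk(spec$motion_amplitude >= 0, "motion_amplitude", "must be non-negative")
  for (i in seq_along(spec$effect_regions)) {
    er <- spec$effect_regions[[i]]
    chk(er$drop >= 0 && er$drop <= 1, "effect_regions",
        sprintf("region %d drop must lie in [0, 1]", i))
    chk(identical(dim(er$mask), as.integer(spec$grid_shape)) &&
          all(!er$mask | spec$mask), "effect_regions",
        sprintf("region %d mask must lie inside the brain mask", i))
  }
  if (!is.null(spec$seed_coupling) && !anyNA(spec$seed_coupling)) {
    sc <- spec$seed_coupling
    chk(all(abs(sc$r) <= 1) && length(sc$r) == 2, "seed_coupling",
        "coupling r must be two values in [-1, 1]")
    chk(all(!sc$target | spec$mask), "seed_coupling",
        "target mask must lie inside the brain mask")
  }
  invisible(spec)
}

#' Ellipsoidal brain mask inscribed in a grid
#'
#' The default synthetic "brain": an ellipsoid leaving a one-voxel
#' margin along each axis.
#'
#' @param grid_shape Voxels per axis (length 3).
#' @return Logical 3D array.
#' @export
default_brain_mask <- function(grid_shape) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  semi <- d / 2 - 1
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  array(r2 <= 1, d)
}

#' Cubic region mask at a fractional grid position
#'
#' Convenience constructor for planted effect regions: a cube of
#' `(2*half+1)^3` voxels centred at `round(centre_frac * grid_shape)`,
#' clipped to the grid.
#'
#' @param grid_shape Voxels per axis (length 3).
#' @param centre_frac Centre as a fraction of each axis (length 3).
#' @param half Half-width in voxels (default 2, i.e. a 5^3 cube).
#' @return Logical 3D array.
#' @export
cube_mask <- function(grid_shape, centre_frac, half = 2) {
  ctr <- round(centre_frac * grid_shape)
  m <- array(FALSE, grid_shape)
  rng <- lapply(1:3, function(ax)
    max(1, ctr[ax] - half):min(grid_shape[ax], ctr[ax] + half))
  m[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  m
}

# unit-variance AR(1) series (vector) or series stack (T x V matrix)
ar1_series <- function(nt, phi, nv = 1) {
  e <- matrix(stats::rnorm(nt * nv), nt, nv)
  if (phi != 0) {
    e <- e * sqrt(1 - phi^2)
    e[1, ] <- e[1, ] / sqrt(1 - phi^2)
    for (t in 2:nt) e[t, ] <- phi * e[t - 1, ] + e[t, ]
  }
  if (nv == 1) drop(e) else e
}

#' Generate one subject's synthetic BOLD volume
#'
#' Implements the cohort signal model for a single subject: spatially
#' smoothed AR(1) noise, region latents mixed with the group-specific
#' synchrony weight, seed-target coupling, linear drift, motion-trace
#' leakage, and WM/CSF-like global components.
#'
#' @param spec A [cohort_spec].
#' @param group 1 (impaired) or 2.
#' @param subject_seed Integer seed for this subject.
#' @param motion Optional `T x 6` motion trace whose columns leak into
#'   the data (generated internally if omitted).
#' @return A [bold_volume].
#' @export
generate_subject_bold <- function(spec, group, subject_seed, motion = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% c(1, 2)) stop("`group` must be 1 or 2")
  set.seed(subject_seed)
  d <- spec$grid_shape; nt <- spec$n_timepoints
  nvox <- prod(d)
  if (is.null(motion))
    motion <- generate_motion_params(nt, spec$motion_amplitude,
                                     derive_seed(subject_seed, 101))
  set.seed(derive_seed(subject_seed, 1))

  # spatially smoothed AR(1) noise field, rescaled to unit variance
  noise <- ar1_series(nt, spec$ar1_phi, nvox)            # T x V
  if (spec$spatial_fwhm_mm > 0) {
    sig_vox <- spec$spatial_fwhm_mm / (2 * sqrt(2 * log(2))) /
      spec$voxel_size_mm
    kerns <- lapply(d, function(n) gauss_kernel_matrix(n, sig_vox))
    sm <- conv_separable(array(t(noise), c(d, nt)), kerns)
    noise <- t(matrix(sm, nvox, nt))
    noise <- noise / stats::sd(as.vector(noise))
  }

  # mix region latents: x = w * latent + sqrt(1 - w^2) * e, with e an
  # independent (unsmoothed) AR(1) noise per member voxel so that the
  # weight w alone sets the within-region concordance, from ~1/K at
  # w = 0 up to 1 at w = 1
  latents <- list()
  for (i in seq_along(spec$effect_regions)) {
    er <- spec$effect_regions[[i]]
    lat <- ar1_series(nt, spec$ar1_phi)
    latents[[i]] <- lat
    w <- spec$base_synchrony * (if (group == 1) 1 - er$drop else 1)
    idx <- which(as.vector(er$mask))
    noise[, idx] <- w * lat +
      sqrt(1 - w^2) * ar1_series(nt, spec$ar1_phi, length(idx))
  }
  sc <- spec$seed_coupling
  if (!is.null(sc) && !anyNA(sc)) {
    seed_lat <- NULL
    for (i in seq_along(spec$effect_regions))
      if (identical(sc$seed, spec$effect_regions[[i]]$mask))
        seed_lat <- latents[[i]]
    if (is.null(seed_lat)) {
      seed_lat <- ar1_series(nt, spec$ar1_phi)
      idx <- which(as.vector(sc$seed))
      w <- spec$base_synchrony
      noise[, idx] <- w * seed_lat +
        sqrt(1 - w^2) * ar1_series(nt, spec$ar1_phi, length(idx))
    }
    r <- sc$r[group]
    idx <- which(as.vector(sc$target))
    noise[, idx] <- r * seed_lat + sqrt(1 - r^2) * noise[, idx, drop = FALSE]
  }

  # WM/CSF compartments carry their own independent voxel noise (no
  # grey-matter field leakage), so their means estimate the global
  # components cleanly
  for (tm in list(spec$wm_mask, spec$csf_mask)) {
    idx <- which(as.vector(tm))
    noise[, idx] <- 0.5 * ar1_series(nt, spec$ar1_phi, length(idx))
  }

  # slow drift, motion leakage and global WM/CSF-like components
  tt <- seq_len(nt) / nt - 0.5
  drift_coef <- stats::rnorm(nvox, sd = 0.3)
  leak <- motion %*% matrix(stats::rnorm(6 * nvox, sd = 0.05), 6, nvox)
  g_wm <- ar1_series(nt, 0.5); g_csf <- ar1_series(nt, 0.5)
  global <- outer(g_wm, 0.1 + 0.9 * as.numeric(as.vector(spec$wm_mask))) +
    outer(g_csf, 0.1 + 0.9 * as.numeric(as.vector(spec$csf_mask)))
  dat <- noise + outer(tt, drift_coef) + leak + global
  bold_volume(array(t(dat), c(d, nt)),
              affine = diag(c(rep(spec$voxel_size_mm, 3), 1)),
              tr = spec$tr, mask = spec$mask)
}

#' Generate a smooth random-walk motion trace
#'
#' Cumulative sums of small Gaussian steps, lightly smoothed, zeroed at
#' the first time point; translations in mm, rotations in rad. The
#' whole trace scales linearly with `amplitude`, so framewise
#' displacement scales linearly too.
#'
#' @param n_timepoints Number of volumes (>= 2).
#' @param amplitude Overall scale (1 = realistic mild motion, 0 = none).
#' @param subject_seed RNG seed.
#' @return `T x 6` matrix, columns `tx ty tz rx ry rz`.
#' @export
generate_motion_params <- function(n_timepoints, amplitude = 1,
                                   subject_seed = 1) {
  if (n_timepoints < 2) stop("need T > 1")
  set.seed(subject_seed)
  step_sd <- c(rep(0.02, 3), rep(4e-4, 3))  # mm, rad per TR
  steps <- matrix(stats::rnorm(n_timepoints * 6), n_timepoints, 6)
  steps <- apply(steps, 2, function(s)
    as.numeric(stats::filter(s, rep(1 / 3, 3), sides = 1, circular = TRUE)))
  trace <- apply(steps, 2, cumsum)
  trace <- sweep(trace, 2, trace[1, ])
  trace <- sweep(trace, 2, step_sd, `*`) * amplitude
  colnames(trace) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  trace
}

# Table-1-style clinical summary parameters: mean and SD per group plus
# truncation bounds (group 1 = impaired).
default_table1_params <- function() {
  p <- rbind(
    age               = c(38.37, 8.06, 35.48, 8.86, 20, 60),
    education         = c(13.06, 2.31, 13.59, 3.13, 0, 25),
    bmi               = c(27.35, 3.08, 26.91, 4.13, 12, 60),
    neck_circumference = c(41.47, 2.92, 40.10, 2.60, 25, 60),
    waistline         = c(99.66, 6.79, 97.59, 18.78, 50, 200),
    ahi               = c(54.38, 23.26, 50.29, 18.78, 15, 150),
    lsao2             = c(70.77, 12.46, 68.00, 12.38, 0, 100),
    msao2             = c(92.21, 3.58, 91.71, 5.13, 0, 100),
    sleep_efficiency  = c(78.91, 22.63, 84.86, 12.04, 0, 100),
    ai                = c(30.52, 17.75, 33.59, 21.78, 0, 150),
    odi               = c(47.40, 23.09, 43.34, 23.43, 0, 150),
    sao2_below_90     = c(24.94, 19.88, 23.67, 16.25, 0, 100),
    moca              = c(22.40, 2.36, 27.27, 1.17, 0, 30))
  colnames(p) <- c("mean1", "sd1", "mean2", "sd2", "lo", "hi")
  as.data.frame(p)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic clinical covariate table
#'
#' Independent truncated-Gaussian draws per variable from per-group
#' means and SDs; MoCA scores are integers constrained by rejection
#' sampling so that group 1 scores fall below the impairment cutoff and
#' group 2 scores at or above it (groups are defined by the cutoff, so
#' labels must be consistent with scores).
#'
#' @param n1,n2 Subjects per group (> 0).
#' @param table1_params Data frame with columns
#'   `mean1, sd1, mean2, sd2, lo, hi` and variables as row names
#'   (default [default_table1_params()]).
#' @param moca_cutoff MoCA impairment cutoff (default 26).
#' @param seed RNG seed.
#' @return Data frame: `id`, `group` (`"MCI"`/`"nMCI"`), one column per
#'   clinical variable.
#' @export
generate_clinical_table <- function(n1, n2, table1_params = default_table1_params(),
                                    moca_cutoff = 26, seed = 1) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  set.seed(seed)
  draw_group <- function(n, which_group, moca_lo, moca_hi) {
    cols <- lapply(rownames(table1_params), function(v) {
      p <- table1_params[v, ]
      m <- if (which_group == 1) p$mean1 else p$mean2
      s <- if (which_group == 1) p$sd1 else p$sd2
      if (v == "moca") {
        round(rtrunc_norm(n, m, s, moca_lo - 0.499, moca_hi + 0.499))
      } else rtrunc_norm(n, m, s, p$lo, p$hi)
    })
    names(cols) <- rownames(table1_params)
    as.data.frame(cols)
  }
  g1 <- draw_group(n1, 1, 0, moca_cutoff - 1)
  g2 <- draw_group(n2, 2, moca_cutoff, 30)
  out <- rbind(g1, g2)
  data.frame(id = sprintf("sub-%03d", seq_len(n1 + n2)),
             group = rep(c("MCI", "nMCI"), c(n1, n2)), out)
}

#' Generate synthetic airflow and SpO2 traces with planted events
#'
#' Baseline oscillatory airflow (0.25 Hz breathing with slow amplitude
#' modulation and additive noise) into which apneas (>= 90% amplitude
#' reduction) and hypopneas (~50-70% reduction with a lagged >= 4% SpO2
#' desaturation) are planted. Candidate onsets arrive at the requested
#' hourly rates and overlapping candidates are thinned, so the realised
#' count is Poisson-like below the nominal rate.
#'
#' @param duration_s Trace length in seconds (>= 60).
#' @param sampling_hz Sampling rate (default 8).
#' @param apnea_rate,hypopnea_rate Planted events per hour (>= 0).
#' @param subject_seed RNG seed.
#' @param event_duration_s Range of planted durations (default 15-30 s).
#' @return List: `airflow`, `spo2` (numeric traces), `events`
#'   (data frame: `kind`, `onset_s`, `duration_s`), `sampling_hz`.
#' @export
generate_respiratory_traces <- function(duration_s, sampling_hz = 8,
                                        apnea_rate = 0, hypopnea_rate = 0,
                                        subject_seed = 1,
                                        event_duration_s = c(15, 30)) {
  if (duration_s < 60) stop("`duration_s` must be >= 60 s")
  if (apnea_rate < 0 || hypopnea_rate < 0) stop("event rates must be >= 0")
  set.seed(subject_seed)
  n <- round(duration_s * sampling_hz)
  t <- seq_len(n) / sampling_hz
  amp <- 1 + 0.1 * sin(2 * pi * t / 120)
  airflow <- amp * sin(2 * pi * 0.25 * t)
  spo2 <- rep(96, n)

  hours <- duration_s / 3600
  n_ap <- stats::rpois(1, apnea_rate * hours)
  n_hy <- stats::rpois(1, hypopnea_rate * hours)
  kinds <- sample(rep(c("apnea", "hypopnea"), c(n_ap, n_hy)))
  events <- data.frame(kind = character(), onset_s = numeric(),
                       duration_s = numeric())
  occupied <- rep(FALSE, n)
  for (kind in kinds) {
    dur <- stats::runif(1, event_duration_s[1], event_duration_s[2])
    onset <- stats::runif(1, 5, duration_s - dur - 45)
    i0 <- round(onset * sampling_hz); i1 <- round((onset + dur) * sampling_hz)
    guard <- round(20 * sampling_hz)   # keep events separated
    lo <- max(1, i0 - guard); hi <- min(n, i1 + guard)
    if (any(occupied[lo:hi])) next     # thinning: drop overlapping candidate
    occupied[lo:hi] <- TRUE
    red <- if (kind == "apnea") 0.97 else stats::runif(1, 0.5, 0.7)
    airflow[i0:i1] <- airflow[i0:i1] * (1 - red)
    depth <- if (kind == "apnea") stats::runif(1, 4.5, 9) else
      stats::runif(1, 4.5, 7)
    ctr <- onset + dur * 0.7 + 5       # desaturation lags event onset
    spo2 <- spo2 - depth * exp(-((t - ctr)^2) / (2 * 6^2))
    events <- rbind(events, data.frame(kind = kind, onset_s = onset,
                                       duration_s = dur))
  }
  airflow <- airflow + stats::rnorm(n, sd = 0.03)
  spo2 <- pmin(100, spo2 + stats::rnorm(n, sd = 0.15))
  list(airflow = airflow, spo2 = spo2,
       events = events[order(events$onset_s), ], sampling_hz = sampling_hz)
}

#' Generate a full synthetic cohort
#'
#' Per-subject BOLD volumes and motion traces, a clinical covariate
#' table consistent with the group labels, and the planted ground
#' truth. Deterministic given `spec$rng_seed`.
#'
#' @param spec A [cohort_spec].
#' @return List of class `synthetic_cohort`: `volumes` (list of
#'   [bold_volume]), `motion` (list of `T x 6` traces), `clinical`
#'   (data frame), `groups` (1/2 per subject), `ground_truth` (planted
#'   effects), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n <- spec$n_group1 + spec$n_group2
  groups <- rep(c(1L, 2L), c(spec$n_group1, spec$n_group2))
  motion <- vector("list", n)
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- derive_seed(spec$rng_seed, i)
    motion[[i]] <- generate_motion_params(spec$n_timepoints,
                                          spec$motion_amplitude,
                                          derive_seed(sseed, 101))
    volumes[[i]] <- generate_subject_bold(spec, groups[i], sseed,
                                          motion[[i]])
  }
  clinical <- generate_clinical_table(spec$n_group1, spec$n_group2,
                                      seed = derive_seed(spec$rng_seed, 9001))
  gt <- list(
    effect_regions = lapply(spec$effect_regions, function(er)
      list(mask = er$mask, drop = er$drop)),
    seed_coupling = spec$seed_coupling,
    groups = groups)
  structure(list(volumes = volumes, motion = motion, clinical = clinical,
                 groups = groups, ground_truth = gt, spec = spec),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' NIfTI volumes and brain mask, per-subject motion TSVs (header
#' `tx ty tz rx ry rz`), the clinical table TSV, and a ground-truth
#' JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  mask_img <- stat_map(array(as.numeric(spec$mask), spec$grid_shape),
                       spec$mask,
                       diag(c(rep(spec$voxel_size_mm, 3), 1)))
  write_nifti_volume(mask_img, file.path(dir, "mask.nii.gz"))
  for (i in seq_along(cohort$volumes)) {
    id <- sprintf("sub-%03d", i)
    write_nifti_volume(cohort$volumes[[i]],
                       file.path(dir, paste0(id, "_bold.nii.gz")))
    utils::write.table(cohort$motion[[i]],
                       file.path(dir, paste0(id, "_motion.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gt <- list(groups = cohort$groups,
             effect_drops = vapply(cohort$ground_truth$effect_regions,
                                   `[[`, 1, "drop"),
             coupling_r = cohort$ground_truth$seed_coupling$r)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
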