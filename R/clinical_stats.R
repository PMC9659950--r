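#' Required sample size for a two-sample t-test
#'
#' Smallest per-group n such that a two-sided two-sample t-test reaches
#' the requested power at effect size Cohen's d and level alpha,
#' computed by iterating the noncentral-t power expression
#' (`ncp = d * sqrt(n/2)`, `df = 2n - 2` for 1:1 allocation).
#'
#' @param effect_size_d Cohen's d (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power 1 - beta (default 0.8).
#' @param ratio Allocation ratio n2/n1 (default 1).
#' @return List: `n_per_group` (n1), `n2`, `total`, `achieved_power`.
#' @export
required_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.8,
                                 ratio = 1) {
  if (effect_size_d <= 0) stop("`effect_size_d` must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("`alpha` and `power` must lie in (0, 1)")
  power_at <- function(n1) {
    n2 <- ceiling(ratio * n1)
    df <- n1 + n2 - 2
    ncp <- effect_size_d / sqrt(1 / n1 + 1 / n2)
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp)
  }
  n1 <- 2
  while (power_at(n1) < power && n1 < 1e6) n1 <- n1 + 1
  n2 <- ceiling(ratio * n1)
  list(n_per_group = n1, n2 = n2, total = n1 + n2,
       achieved_power = power_at(n1))
}

#' Normality test with estimated parameters (Lilliefors)
#'
#' One-sample Kolmogorov-Smirnov distance of the sample against
#' `Normal(mean(x), sd(x))` with the Lilliefors correction for the
#' estimated parameters (the convention of common clinical-statistics
#' software). `exact = TRUE` instead returns the naive KS p-value
#' against the fitted normal, which is conservative.
#'
#' @param x Numeric sample, n >= 4, non-constant.
#' @param exact Use the uncorrected KS distribution (default `FALSE`).
#' @return List: `statistic` (D), `p`.
#' @export
ks_normality_test <- function(x, exact = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need n >= 4 for the normality test")
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  if (exact) {
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    list(statistic = unname(ks$statistic), p = ks$p.value)
  } else {
    lt <- nortest::lillie.test(x)
    list(statistic = unname(lt$statistic), p = lt$p.value)
  }
}

#' Two-sample pooled t-test from printed summaries
#'
#' Recomputes the Student t-test from group means, SDs and sizes alone
#' (as printed in a demographics table): pooled variance,
#' `df = n1 + n2 - 2`, two-sided p.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return List: `t`, `df`, `p`.
#' @export
student_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (s1 <= 0 || s2 <= 0) stop("SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Two-sample Student t-test on raw data
#'
#' Pooled-variance two-sided t-test (`stats::t.test` with
#' `var.equal = TRUE`, or Welch via `equal_var = FALSE`).
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @param equal_var Pooled variance (default `TRUE`).
#' @return List: `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(x, y, equal_var = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per sample")
  tt <- stats::t.test(x, y, var.equal = equal_var)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when both samples are small and tie-free, otherwise the normal
#' approximation with tie correction (`stats::wilcox.test`).
#'
#' @param x,y Numeric samples (non-empty).
#' @return List: `u` (U statistic for `x`), `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @return List: `r`, `p` (two-sided, t distribution with n - 2 df).
#' @export
pearson_corr_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors with n >= 3")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-sided p-value from a printed correlation coefficient
#'
#' `t = r sqrt(n-2) / sqrt(1-r^2)` with `df = n - 2`: recovers the
#' p-value belonging to a reported r at a known sample size.
#'
#' @param r Correlation coefficient, |r| < 1.
#' @param n Sample size, n >= 3.
#' @return Two-sided p-value.
#' @export
pearson_p_from_r <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) >= 1) stop("|r| must be < 1")
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), n - 2)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with the family size `m` stated explicitly
#' (defaults to the number of p-values supplied).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Classify cognitive status from a MoCA score
#'
#' Montreal Cognitive Assessment total below the cutoff (default 26)
#' indicates mild cognitive impairment.
#'
#' @param score MoCA total(s), 0-30.
#' @param cutoff Impairment cutoff (default 26).
#' @return Character vector: `"MCI"` or `"nMCI"`.
#' @export
classify_moca <- function(score, cutoff = 26) {
  if (any(score < 0 | score > 30)) stop("MoCA scores must lie in [0, 30]")
  ifelse(score < cutoff, "MCI", "nMCI")
}

#' Score apneas and hypopneas from airflow and SpO2 traces
#'
#' A rolling-baseline amplitude envelope of the airflow signal is
#' compared against reduction thresholds: spans with >= 90% amplitude
#' reduction sustained >= 10 s are apneas; spans with reduction in
#' \[30%, 90%) sustained >= 10 s qualify as hypopneas only when SpO2
#' drops >= 4% below its rolling baseline within a lag window after
#' event onset. Events are non-overlapping by construction.
#'
#' @param airflow Numeric airflow trace.
#' @param spo2 SpO2 trace (percent), same length and sampling.
#' @param sampling_hz Sampling rate of both traces.
#' @param apnea_reduction,hypopnea_reduction Fractional amplitude
#'   reduction thresholds (defaults 0.9 / 0.3).
#' @param min_duration_s Minimum event duration (default 10 s).
#' @param desat_threshold Required SpO2 drop for hypopneas (default 4).
#' @param desat_lag_s Window after event onset in which the
#'   desaturation must occur (default 30 s).
#' @return Data frame of events: `kind`, `onset_s`, `duration_s`,
#'   `min_spo2`.
#' @export
detect_respiratory_events <- function(airflow, spo2, sampling_hz,
                                      apnea_reduction = 0.9,
                                      hypopnea_reduction = 0.3,
                                      min_duration_s = 10,
                                      desat_threshold = 4,
                                      desat_lag_s = 30) {
  if (length(airflow) != length(spo2))
    stop("airflow and SpO2 traces must be aligned (equal length)")
  n <- length(airflow)
  if (n / sampling_hz < 60) stop("traces must cover at least 60 s")
  env <- amplitude_envelope(airflow, sampling_hz)
  base <- rolling_quantile(env, sampling_hz, window_s = 180, q = 0.8)
  reduction <- 1 - env / pmax(base, .Machine$double.eps)
  spo2_base <- rolling_quantile(spo2, sampling_hz, window_s = 120, q = 0.8)

  events <- data.frame(kind = character(), onset_s = numeric(),
                       duration_s = numeric(), min_spo2 = numeric())
  spans <- contiguous_spans(reduction >= hypopnea_reduction)
  for (k in seq_len(nrow(spans))) {
    i0 <- spans$from[k]; i1 <- spans$to[k]
    dur <- (i1 - i0 + 1) / sampling_hz
    if (dur < min_duration_s) next
    onset <- (i0 - 1) / sampling_hz
    apnea_frac <- mean(reduction[i0:i1] >= apnea_reduction)
    win_end <- min(n, i1 + round(desat_lag_s * sampling_hz))
    min_spo2 <- min(spo2[i0:win_end])
    desat <- (spo2_base[i0] - min_spo2) >= desat_threshold
    # apnea if the >=90% criterion itself holds for >= min duration
    ap_spans <- contiguous_spans(reduction[i0:i1] >= apnea_reduction)
    ap_ok <- nrow(ap_spans) > 0 &&
      max(ap_spans$to - ap_spans$from + 1) / sampling_hz >= min_duration_s
    if (ap_ok) {
      events <- rbind(events, data.frame(kind = "apnea", onset_s = onset,
                                         duration_s = dur,
                                         min_spo2 = min_spo2))
    } else if (desat) {
      events <- rbind(events, data.frame(kind = "hypopnea", onset_s = onset,
                                         duration_s = dur,
                                         min_spo2 = min_spo2))
    }
  }
  events
}

# moving-average magnitude envelope over one breathing period
amplitude_envelope <- function(x, sampling_hz, period_s = 4) {
  w <- max(1L, round(period_s * sampling_hz))
  k <- rep(1 / w, w)
  as.numeric(stats::filter(abs(x), k, sides = 2, circular = FALSE)) ->
    env
  # fill filter NAs at the edges with nearest valid value
  ok <- which(!is.na(env))
  env[seq_len(ok[1] - 1)] <- env[ok[1]]
  env[seq(ok[length(ok)] + 1, length.out = length(env) - ok[length(ok)])] <-
    env[ok[length(ok)]]
  env * pi / 2   # mean |sin| -> amplitude
}

# rolling upper-quantile baseline, computed on a decimated grid
rolling_quantile <- function(x, sampling_hz, window_s, q) {
  n <- length(x)
  step <- max(1L, round(sampling_hz))      # one support point per second
  half <- round(window_s * sampling_hz / 2)
  at <- seq(1L, n, by = step)
  vals <- vapply(at, function(i) {
    stats::quantile(x[max(1, i - half):min(n, i + half)], q, names = FALSE)
  }, 1)
  stats::approx(at, vals, xout = seq_len(n), rule = 2)$y
}

contiguous_spans <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(from = starts[r$values], to = ends[r$values])
}

#' Apnea-hypopnea index and severity class
#'
#' AHI = scored events per hour of sleep; severity bands are the
#' conventional half-open intervals: < 5 normal, \[5, 15) mild,
#' \[15, 30) moderate, >= 30 severe.
#'
#' @param events Event data frame (from [detect_respiratory_events()])
#'   or an event count.
#' @param sleep_hours Hours of sleep (> 0).
#' @return List: `ahi`, `severity`.
#' @export
compute_ahi <- function(events, sleep_hours) {
  if (sleep_hours <= 0) stop("`sleep_hours` must be positive")
  n_ev <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  ahi <- n_ev / sleep_hours
  list(ahi = ahi, severity = classify_ahi_severity(ahi))
}

#' @rdname compute_ahi
#' @param ahi Apnea-hypopnea index (events/hour).
#' @export
classify_ahi_severity <- function(ahi) {
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe")) |> as.character()
}

#' Group comparison table for clinical variables
#'
#' For each variable: normality is assessed in both groups
#' ([ks_normality_test()]); normal variables are compared with the
#' pooled Student t-test, non-normal ones with the Mann-Whitney U test.
#' A Bonferroni-adjusted p column over the tested family is appended.
#'
#' @param clinical Data frame with a `group` column and numeric
#'   variables.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param variables Variables to compare (default: all numeric columns).
#' @param normality_alpha Threshold below which a variable is deemed
#'   non-normal (default 0.05).
#' @return Data frame: variable, per-group mean and SD, test used, p,
#'   Bonferroni-adjusted p.
#' @export
clinical_group_table <- function(clinical, group_col = "group",
                                 variables = NULL, normality_alpha = 0.05) {
  g <- factor(clinical[[group_col]])
  if (nlevels(g) != 2L) stop("`group` must have exactly two levels")
  if (is.null(variables))
    variables <- names(clinical)[vapply(clinical, is.numeric, TRUE) &
                                   names(clinical) != group_col]
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]][g == levels(g)[1]]
    y <- clinical[[v]][g == levels(g)[2]]
    normal <- tryCatch(
      ks_normality_test(x)$p > normality_alpha &&
        ks_normality_test(y)$p > normality_alpha,
      error = function(e) FALSE)
    res <- if (normal) two_sample_ttest(x, y) else mann_whitney_u(x, y)
    data.frame(variable = v,
               mean1 = mean(x), sd1 = stats::sd(x),
               mean2 = mean(y), sd2 = stats::sd(y),
               test = if (normal) "student_t" else "mann_whitney",
               p = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p, m = nrow(out))
  out
}
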