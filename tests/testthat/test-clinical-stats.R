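test_that("noncentral-t sample size reproduces reference values", {
  ps <- required_sample_size(0.8, 0.05, 0.8)
  expect_equal(ps$n_per_group, 26)
  expect_equal(ps$total, 52)
  expect_equal(required_sample_size(0.5, 0.05, 0.8)$n_per_group, 64)
  # agrees with stats::power.t.test as an independent oracle
  for (d in c(0.3, 0.6, 1.0)) {
    oracle <- ceiling(stats::power.t.test(delta = d, power = 0.8)$n)
    expect_equal(required_sample_size(d)$n_per_group, oracle)
  }
  # floor and monotonicity
  expect_equal(required_sample_size(5, power = 0.05)$n_per_group, 2)
  n_by_d <- vapply(c(0.2, 0.5, 0.8), function(d)
    required_sample_size(d)$n_per_group, 1)
  expect_true(all(diff(n_by_d) < 0))
  n_by_pow <- vapply(c(0.5, 0.8, 0.95), function(p)
    required_sample_size(0.5, power = p)$n_per_group, 1)
  expect_true(all(diff(n_by_pow) > 0))
  expect_error(required_sample_size(-1), "positive")
})

test_that("normality test accepts Gaussians and rejects exponentials", {
  set.seed(1)
  rej <- mean(replicate(60, ks_normality_test(rnorm(100))$p < 0.05))
  expect_lt(rej, 0.15)                     # near-nominal type I error
  set.seed(2)
  pow <- mean(replicate(30, ks_normality_test(rexp(200))$p < 0.05))
  expect_gt(pow, 0.9)
  expect_error(ks_normality_test(c(1, 2, 3)), "n >= 4")
  expect_error(ks_normality_test(rep(1, 10)), "constant")
})

test_that("summary t-test reproduces the printed demographics p-values", {
  age <- student_t_from_summary(38.37, 8.06, 48, 35.48, 8.86, 47)
  expect_lt(abs(age$p - 0.100), 0.0005)
  ahi <- student_t_from_summary(54.38, 23.26, 48, 50.29, 18.78, 47)
  expect_lt(abs(ahi$p - 0.349), 0.0005)
  same <- student_t_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(student_t_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("raw-data t-test equals the summary version", {
  set.seed(3)
  x <- rnorm(20, 1); y <- rnorm(25)
  raw <- two_sample_ttest(x, y)
  summ <- student_t_from_summary(mean(x), sd(x), 20, mean(y), sd(y), 25)
  expect_equal(raw$t, summ$t, tolerance = 1e-10)
  expect_equal(raw$p, summ$p, tolerance = 1e-10)
  expect_equal(two_sample_ttest(x, x)$p, 1)
})

test_that("Mann-Whitney matches exhaustive enumeration on a toy", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5))
  expect_equal(res$u, 0)
  # all C(5,2) = 10 assignments equally likely; both extreme -> p = 0.2
  expect_equal(res$p, 0.2)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  sep <- mann_whitney_u(1:10, 11:20)
  expect_lt(sep$p, 2e-4)
  expect_equal(sep$u, 0)
})

test_that("Pearson p-values from printed r match the reported values", {
  expect_lt(abs(pearson_p_from_r(0.272, 95) - 0.008), 0.0005)
  expect_lt(abs(pearson_p_from_r(-0.243, 95) - 0.018), 0.0005)
  expect_equal(pearson_p_from_r(0, 20), 1)
  set.seed(4)
  x <- rnorm(30); y <- x + rnorm(30)
  ct <- pearson_corr_test(x, y)
  expect_equal(ct$p, pearson_p_from_r(ct$r, 30), tolerance = 1e-10)
  expect_error(pearson_p_from_r(1, 30), "< 1")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04), 2), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.9, 5), 1)
  expect_equal(bonferroni_adjust(c(0.3, 0.7), 1), c(0.3, 0.7))
  p <- c(0.001, 0.02, 0.3)
  expect_equal(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
})

test_that("MoCA cutoff and AHI severity bands are half-open as documented", {
  expect_equal(classify_moca(25), "MCI")
  expect_equal(classify_moca(26), "nMCI")
  expect_equal(classify_moca(30), "nMCI")
  expect_error(classify_moca(31), "0, 30")
  expect_equal(classify_ahi_severity(c(0, 4.9, 5, 14.9, 15, 29.9, 30, 80)),
               c("normal", "normal", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_equal(compute_ahi(120, 6)$ahi, 20)
  expect_equal(compute_ahi(120, 6)$severity, "moderate")
  expect_equal(compute_ahi(data.frame(), 7)$ahi, 0)
  expect_error(compute_ahi(10, 0), "positive")
})

test_that("respiratory scorer honours the definition branches", {
  base <- generate_respiratory_traces(180, 8, 0, 0, subject_seed = 5)
  expect_equal(nrow(detect_respiratory_events(base$airflow, base$spo2, 8)), 0)
  plant <- function(red, dur_s, desat, onset_s = 60) {
    tr <- generate_respiratory_traces(180, 8, 0, 0, subject_seed = 5)
    i <- seq(onset_s * 8, (onset_s + dur_s) * 8)
    tr$airflow[i] <- tr$airflow[i] * (1 - red)
    if (desat > 0) {
      t <- seq_along(tr$spo2) / 8
      tr$spo2 <- tr$spo2 - desat * exp(-((t - (onset_s + dur_s)) / 6)^2 / 2)
    }
    detect_respiratory_events(tr$airflow, tr$spo2, 8)
  }
  ap <- plant(0.95, 15, 0)
  expect_equal(ap$kind, "apnea")
  hy <- plant(0.5, 14, 5)
  expect_equal(hy$kind, "hypopnea")
  expect_equal(nrow(plant(0.5, 14, 0)), 0)     # no desaturation -> no event
  expect_equal(nrow(plant(0.95, 9, 0)), 0)     # under 10 s -> no event
  expect_error(detect_respiratory_events(rnorm(100), rnorm(99), 8),
               "aligned")
})

test_that("planted events are recovered at the planted rate", {
  tr <- generate_respiratory_traces(2 * 3600, 8, 10, 20, subject_seed = 9)
  ev <- detect_respiratory_events(tr$airflow, tr$spo2, 8)
  expect_gte(nrow(ev), 0.95 * nrow(tr$events))
  expect_lte(nrow(ev), 1.05 * nrow(tr$events) + 1)
  ahi <- compute_ahi(ev, 2)$ahi
  planted_rate <- nrow(tr$events) / 2
  expect_equal(ahi, planted_rate, tolerance = 0.1)
})

test_that("clinical comparison table picks tests by normality", {
  set.seed(6)
  clin <- data.frame(
    group = rep(c("MCI", "nMCI"), each = 30),
    normalvar = c(rnorm(30, 10), rnorm(30, 12)),
    skewvar = rexp(60) + rep(c(0, 1), each = 30))
  tab <- clinical_group_table(clin)
  expect_equal(tab$test[tab$variable == "normalvar"], "student_t")
  expect_equal(tab$test[tab$variable == "skewvar"], "mann_whitney")
  expect_true(all(tab$p_bonferroni >= tab$p))
  expect_true(all(tab$p_bonferroni <= 1))
})
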