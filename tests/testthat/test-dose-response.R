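test_that("percent change follows its definition and exclusion rules", {
  expect_equal(percent_change(200, 200), 0)
  expect_equal(percent_change(250, 200), 25)
  expect_equal(percent_change(150, 200), -25)
  # undefined pre-phase values exclude the well rather than contribute 0
  expect_true(is.na(percent_change(250, NA)))
  expect_true(is.na(percent_change(250, 0)))
  expect_equal(percent_change(c(220, 180), c(200, 200)), c(10, -10))
})

test_that("dose-response recovers an injected Hill effect on PWD80cF", {
  m <- drug_effect_model("apdstretch", list(
    list(target = "apd_scale", direction = "increase",
         emax = 1 / 3, ec50 = 1, hill = 1)))
  # c = 9*EC50: scale 1 + (1/3)(0.9) = 1.30, i.e. +30 % on all durations
  cfg <- plate_config(paste0("D", 1:6), group = "CT", drug = "apdstretch",
                      concentration_uM = 9, seeds = 1:6)
  sim <- generate_plate(cfg, drug_models = list(apdstretch = m))
  pa <- analyze_plate(as_plate_recording(sim))
  dr <- pa$dose_response
  row <- dr[dr$parameter == "pwd80cF", ]
  expect_equal(row$n, 6L)
  sem <- row$sd_pct / sqrt(row$n)
  expect_lt(abs(row$mean_pct - 30), max(2 * sem, 2))
  # beat rate untouched by the model
  rate_row <- dr[dr$parameter == "beat_rate", ]
  expect_lt(abs(rate_row$mean_pct), 2 * max(rate_row$sd_pct / sqrt(6), 0.5))
})

test_that("a zero-effect model produces changes consistent with zero", {
  cfg <- plate_config(paste0("Z", 1:6), group = "AM", drug = "vehicle",
                      concentration_uM = 1, seeds = 11:16)
  pa <- analyze_plate(as_plate_recording(generate_plate(cfg)))
  dr <- pa$dose_response
  for (p in c("beat_rate", "pwd50cF", "pwd80cF")) {
    row <- dr[dr$parameter == p, ]
    sem <- row$sd_pct / sqrt(row$n)
    expect_lt(abs(row$mean_pct), max(2 * sem, 1.5))
  }
})

test_that("arrested wells leave parameter means but keep incidence denominators", {
  cfg <- plate_config(paste0("R", 1:4), group = "CT", drug = "killer",
                      concentration_uM = 100, seeds = 1:4,
                      events = "arrest", arrest_onset = 0)
  pa <- analyze_plate(as_plate_recording(generate_plate(cfg)))
  expect_equal(pa$incidence$n_arrest, 4L)
  expect_equal(pa$incidence$n, 4L)
  dr <- pa$dose_response
  expect_true(all(dr$n == 0L))
  expect_true(all(is.na(dr$mean_pct)))
})

test_that("two-sample comparison selects its branch from the variance gate", {
  set.seed(21)
  a <- rnorm(20)
  b <- rnorm(20, mean = 2)
  res <- compare_groups(a, b)
  expect_lt(res$p, 0.01)
  expect_true(res$sig01)
  # identical samples: t = 0, p = 1
  same <- compare_groups(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # gross variance mismatch routes to Welch
  set.seed(22)
  het <- compare_groups(rnorm(15, sd = 1), rnorm(15, sd = 5))
  expect_identical(het$test, "welch_t")
  hom <- compare_groups(rnorm(15, sd = 1), rnorm(15, sd = 1))
  expect_identical(hom$test, "student_t")
  # insufficient n
  expect_identical(compare_groups(1:2, 1:5)$test, "not_evaluable")
})

test_that("t-test p-values agree with a permutation oracle", {
  set.seed(31)
  a <- rnorm(8, 0)
  b <- rnorm(8, 1.2)
  res <- compare_groups(a, b)
  # permutation distribution of the mean difference
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(4000, {
    idx <- sample(16, 8)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(res$p - p_perm), 0.05)
})

test_that("multi-group comparison runs ANOVA with Tukey follow-up", {
  set.seed(41)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 3))
  res <- compare_multi(g)
  expect_identical(res$test, "anova_tukey")
  expect_lt(res$p, 0.01)
  sig_pairs <- res$tukey$comparison[res$tukey$sig05]
  expect_setequal(sig_pairs, c("c-a", "c-b"))
  # near-identical groups: F small, Tukey p near 1
  set.seed(42)
  null <- compare_multi(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  expect_gt(min(null$tukey$p_adj), 0.2)
  # two groups are redirected to the two-sample path
  expect_error(compare_multi(list(a = rnorm(5), b = rnorm(5))),
               "compare_groups")
})

test_that("ANOVA p-value agrees with a permutation oracle", {
  set.seed(51)
  g <- list(a = rnorm(7), b = rnorm(7, 1), c = rnorm(7, 0.5))
  res <- compare_multi(g)
  vals <- unlist(g, use.names = FALSE)
  lab <- rep(1:3, each = 7)
  fstat <- function(lbl) {
    summary(stats::aov(vals ~ factor(lbl)))[[1]][["F value"]][1]
  }
  obs <- fstat(lab)
  perm <- replicate(2000, fstat(sample(lab)))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(res$p - p_perm), 0.06)
})
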