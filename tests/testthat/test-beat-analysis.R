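test_that("triangle beat yields its analytic durations and slopes", {
  tr <- triangle_trace(t0 = 0.3, A = 1, decay_s = 0.1)
  beats <- detect_beats(tr)
  expect_equal(nrow(beats), 1L)
  expect_equal(beats$t_activation, 0.3, tolerance = 1e-9)
  expect_equal(beats$amplitude, 1, tolerance = 1e-9)
  # PWD_x = x ms on a linear 100-ms decay, to interpolation tolerance 0.1 ms
  expect_equal(beats$pwd30, 30, tolerance = 0.1 / 30)
  expect_equal(beats$pwd50, 50, tolerance = 0.1 / 50)
  expect_equal(beats$pwd80, 80, tolerance = 0.1 / 80)
  expect_equal(beats$pwd80 - beats$pwd30, 50, tolerance = 0.01)
  # falling slope of the linear decay: A / 0.1 s
  expect_equal(beats$v_down_max, 10, tolerance = 1e-6)
  # equal 10-ms intervals on a linear decay: plateau ratio exactly 1
  expect_equal(plateau_ratio(beats), 1, tolerance = 0.01)
})

test_that("detrending removes linear photobleaching drift", {
  # pure drift, no beats: -10 %/min on the baseline
  dt <- 0.005
  t <- seq(0, 30, by = dt)
  x <- 10 * (1 - 0.10 * t / 60)
  tr <- new_trace("D", t, x, 5)
  out <- detrend_trace(tr)
  core <- t > 2 & t < 28   # away from window edges
  fit0 <- stats::lm.fit(cbind(1, t), x)$coefficients[2]
  fit1 <- stats::lm.fit(cbind(1, t[core]), out$signal[core])$coefficients[2]
  expect_lt(abs(fit1), 0.01 * abs(fit0))
})

test_that("detrending a clean flat-baseline trace only removes the offset", {
  p <- clean_preset("CT")
  tr <- gen(p, 20, 5, seed = 1)
  out <- detrend_trace(tr)
  core <- tr$time > 2 & tr$time < 18
  shifted <- tr$signal - p$baseline_level
  expect_equal(out$signal[core], shifted[core], tolerance = 0.02)
})

test_that("amplitudes on a drifting trace are recovered within 2 percent", {
  p <- ct_preset(noise_sd = 0, rate_jitter_cv = 0)   # drift on
  tr <- gen(p, 30, 5, seed = 2)
  beats <- detect_beats(detrend_trace(tr))
  gt <- attr(tr, "ground_truth")
  expect_true(all(abs(beats$amplitude - gt$amplitude) / gt$amplitude < 0.02))
})

test_that("beat detection is exact on noise-free traces and null on noise", {
  for (g in c("CT", "AM")) {
    tr <- gen(clean_preset(g), 30, 5, seed = 1)
    beats <- detect_beats(detrend_trace(tr))
    expect_equal(nrow(beats), length(attr(tr, "ground_truth")$onsets))
  }
  # flat baseline plus noise only: no beats
  set.seed(9)
  t <- seq(0, 30, by = 0.005)
  tr <- new_trace("N", t, 10 + rnorm(length(t), sd = 0.02), 5)
  expect_equal(nrow(detect_beats(detrend_trace(tr))), 0L)
})

test_that("activation times land within two samples of the true onsets", {
  p <- am_preset(noise_sd = 0.05)
  tr <- gen(p, 30, 5, seed = 3)
  beats <- detect_beats(detrend_trace(tr))
  gt <- attr(tr, "ground_truth")
  expect_equal(nrow(beats), length(gt$onsets))
  expect_true(all(abs(beats$t_activation - gt$onsets) <= 2 * 0.005))
})

test_that("noise-free summaries match ground truth (oracle equivalence)", {
  for (g in c("CT", "AM")) {
    tr <- gen(clean_preset(g), 30, 5, seed = 1)
    s <- summarize_well(detect_beats(detrend_trace(tr)), 30)
    gt <- attr(tr, "ground_truth")
    expect_true(all(abs(s$pwd - gt$apd_targets) <= 1),
                label = paste(g, "durations within 1 ms"))
    expect_lt(abs(s$beat_rate - gt$beat_rate), 1)
    expect_lt(abs(s$amplitude_mean - gt$amplitude) / gt$amplitude, 0.02)
    expect_lt(abs(s$v_up_mean - gt$v_up_max) / gt$v_up_max, 0.02)
    expect_lt(abs(s$v_down_mean - gt$v_down_max) / gt$v_down_max, 0.02)
  }
})

test_that("durations are monotone across fractions on every measured beat", {
  for (g in c("CT", "AM")) {
    tr <- gen(default_preset(g), 30, 5, seed = 5)
    beats <- detect_beats(detrend_trace(tr))
    pwd <- as.matrix(beats[, paste0("pwd", 100 * PWD_FRACTIONS)])
    ok <- stats::complete.cases(pwd)
    expect_true(all(apply(pwd[ok, , drop = FALSE], 1,
                          function(r) all(diff(r) >= 0))))
  }
})

test_that("durations agree between 5 and 10 ms sampling within one coarse sample", {
  for (g in c("CT", "AM")) {
    p <- clean_preset(g)
    s5 <- summarize_well(detect_beats(detrend_trace(gen(p, 30, 5, seed = 1))), 30)
    s10 <- summarize_well(detect_beats(detrend_trace(gen(p, 30, 10, seed = 1))), 30)
    expect_true(all(abs(s10$pwd - s5$pwd) <= 10),
                label = paste(g, "5 vs 10 ms"))
  }
})

test_that("12-well mean recovers APD90 with small bias under 5 percent noise", {
  p <- am_preset(noise_sd = 0.05)
  sh <- cached_shape(p)
  errs <- vapply(1:12, function(sd) {
    tr <- generate_trace(p, 30, 5, seed = sd, shape = sh)
    s <- summarize_well(detect_beats(detrend_trace(tr)), 30)
    unname(s$pwd["pwd90"]) - unname(attr(tr, "ground_truth")$apd_targets["0.9"])
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3)
})

test_that("well summary handles sparse windows", {
  tr <- gen(clean_preset("CT"), 30, 5, seed = 1)
  beats <- detect_beats(detrend_trace(tr))
  # single beat in a narrow window: durations defined, rate undefined
  one <- summarize_well(beats, window = c(0, 0.5))
  expect_equal(one$n_beats, 1L)
  expect_true(is.na(one$beat_rate))
  expect_false(any(is.na(one$pwd)))
  # empty window
  zero <- summarize_well(beats, window = c(29.9, 30))
  expect_equal(zero$n_beats, 0L)
  expect_true(is.na(zero$beat_rate))
})

test_that("summary invariants hold: PWD30-80 and the rate estimator", {
  tr <- gen(am_preset(), 30, 5, seed = 6)
  s <- summarize_well(detect_beats(detrend_trace(tr)), 30)
  expect_equal(s$pwd30_80,
               unname(s$pwd_cf["pwd80cF"] - s$pwd_cf["pwd30cF"]))
  expect_equal(s$pwd30_80_unc, unname(s$pwd["pwd80"] - s$pwd["pwd30"]))
  # rate consistent with the count over the window to one beat's quantization
  expect_lt(abs(s$beat_rate - s$n_beats * 2), 60 / 30 * 2)
})

test_that("analyze_trace returns a classed end-to-end result", {
  tr <- gen(am_preset(), 10, 5, seed = 7)
  fit <- analyze_trace(tr, window = 10)
  expect_s3_class(fit, "well_analysis")
  expect_identical(fit$event$label, "normal")
  expect_output(print(fit), "beat rate")
  df <- as.data.frame(summary(fit))
  expect_true(all(c("pwd50cF", "beat_rate", "plateau_ratio") %in% names(df)))
})
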