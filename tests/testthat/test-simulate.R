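test_that("trace generation realizes the preset's beat count", {
  tr <- gen(ct_preset(), 30, 5, seed = 42)
  gt <- attr(tr, "ground_truth")
  expect_true(abs(length(gt$onsets) - floor(30 * 83.7 / 60)) <= 1)
})

test_that("a jitter-free, noise-free, drift-free trace is exactly periodic", {
  # rate 80/min -> period 750 ms, an exact multiple of the 5 ms grid
  p <- ct_preset(beat_rate = 80, noise_sd = 0, drift_rate = 0,
                 rate_jitter_cv = 0)
  tr <- generate_trace(p, 10, 5, seed = 1)
  k <- 150L  # samples per period
  x <- tr$signal
  gt <- attr(tr, "ground_truth")
  first <- gt$onsets[1]
  last <- gt$onsets[length(gt$onsets)]
  core <- which(tr$time >= first - 0.05 & tr$time <= last - 0.75 + 0.05)
  expect_equal(x[core + k], x[core], tolerance = 1e-12)
})

test_that("identical preset and seed give bitwise-identical traces", {
  a <- gen(am_preset(), 10, 5, seed = 7)
  b <- gen(am_preset(), 10, 5, seed = 7)
  expect_identical(a$signal, b$signal)
  expect_identical(attr(a, "ground_truth")$onsets,
                   attr(b, "ground_truth")$onsets)
  c <- gen(am_preset(), 10, 5, seed = 8)
  expect_false(identical(a$signal, c$signal))
})

test_that("noise scales as noise_sd * amplitude over diastolic segments", {
  p <- ct_preset(noise_sd = 0.04)
  tr <- gen(p, 30, 5, seed = 3)
  resid <- tr$signal - attr(tr, "noise_free")
  gt <- attr(tr, "ground_truth")
  # samples at least 600 ms after each onset are diastole for CT
  after <- vapply(tr$time, function(tt) {
    d <- tt - gt$onsets
    any(d > 0.60 & d < 0.66)
  }, logical(1))
  expect_gt(sum(after), 200)
  expect_equal(stats::sd(resid[after]), 0.04 * p$amplitude, tolerance = 0.1)
})

test_that("invalid generation arguments are rejected", {
  expect_error(generate_trace(ct_preset(), duration = 0, seed = 1), "duration")
  expect_error(generate_trace(ct_preset(), sampling_interval = -5, seed = 1),
               "sampling_interval")
})

test_that("arrest injection removes beats from its onset", {
  tr <- gen(ct_preset(), 10, 5, seed = 2)
  out <- inject_event(tr, "arrest", onset = 0)
  expect_length(attr(out, "ground_truth")$onsets, 0)
  mid <- inject_event(tr, "arrest", onset = 5)
  expect_true(all(attr(mid, "ground_truth")$onsets < 5))
  expect_error(inject_event(tr, "arrest", onset = 11), "beyond")
})

test_that("EAD injection creates a secondary maximum on the repolarization limb", {
  p <- clean_preset("CT")
  tr <- generate_trace(p, 10, 5, seed = 1,
                       event = list(type = "EAD", bump = 0.10, phase = 0.5,
                                    affect_fraction = 1))
  gt <- attr(tr, "ground_truth")
  x <- tr$signal
  for (on in gt$onsets[2:4]) {
    # scan the noise-free waveform between peak and baseline for a sign
    # change of the first difference (local maximum)
    idx <- which(tr$time > on + 0.1 & tr$time < on + 0.33)
    d <- diff(x[idx])
    expect_true(any(d[-length(d)] < 0 & d[-1] > 0),
                label = sprintf("secondary max after onset %.2f", on))
  }
  expect_length(gt$event$affected_beats, length(gt$onsets))
})

test_that("irregular injection at the preset's own jitter reproduces the trace", {
  p <- ct_preset()
  tr <- gen(p, 10, 5, seed = 4)
  same <- inject_event(tr, "irregular", cv = p$rate_jitter_cv)
  expect_identical(tr$signal, same$signal)
  wild <- inject_event(tr, "irregular", cv = 0.30)
  expect_false(identical(tr$signal, wild$signal))
  expect_gt(attr(wild, "ground_truth")$realized_ibi_cv, 0.15)
})

test_that("event injection leaves the noise draws untouched", {
  tr <- gen(ct_preset(), 10, 5, seed = 5)
  ead <- inject_event(tr, "EAD", bump = 0.1, phase = 0.5)
  noise_a <- tr$signal - attr(tr, "noise_free")
  noise_b <- ead$signal - attr(ead, "noise_free")
  expect_identical(noise_a, noise_b)
})

test_that("event parameter validation enforces the documented domains", {
  tr <- gen(ct_preset(), 5, 5, seed = 6)
  expect_error(inject_event(tr, "EAD", bump = 1.5), "bump")
  expect_error(inject_event(tr, "EAD", phase = 0.95), "phase")
  expect_error(inject_event(tr, "irregular", cv = -1), "CV")
})
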