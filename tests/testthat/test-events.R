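analyze_post <- function(trace, config = classifier_config()) {
  td <- detrend_trace(trace)
  beats <- detect_beats(td)
  summ <- summarize_well(beats, 30)
  list(td = td, beats = beats, summ = summ,
       call = classify_well(td, beats, summ, config))
}

test_that("injected EADs are flagged and clean beats are not", {
  tr <- gen(ct_preset(), 30, 5, seed = 1,
            event = list(type = "EAD", bump = 0.10, phase = 0.5,
                         affect_fraction = 0.5))
  a <- analyze_post(tr)
  gt <- attr(tr, "ground_truth")
  flagged <- which(detect_ead(a$td, a$beats)$flags)
  expect_gte(length(intersect(flagged, gt$event$affected_beats)), 2)
  expect_identical(a$call$label, "EAD")

  clean <- gen(clean_preset("CT"), 30, 5, seed = 1)
  b <- analyze_post(clean)
  expect_equal(detect_ead(b$td, b$beats)$n_ead_beats, 0L)
})

test_that("false-positive EAD beat rate stays below 1 percent at 2 percent noise", {
  p <- ct_preset()  # noise_sd 0.02
  sh <- cached_shape(p)
  fp <- 0L
  n <- 0L
  for (sd in 1:12) {
    tr <- generate_trace(p, 30, 5, seed = sd, shape = sh)
    a <- analyze_post(tr)
    fp <- fp + detect_ead(a$td, a$beats)$n_ead_beats
    n <- n + nrow(a$beats)
  }
  expect_lt(fp / n, 0.01)
})

test_that("irregularity detection follows the IBI coefficient of variation", {
  # constant IBIs: cv = 0, not flagged
  beats <- detect_beats(detrend_trace(gen(clean_preset("AM"), 30, 5, seed = 1)))
  res <- detect_irregular(beats)
  expect_lt(res$ibi_cv, 0.02)
  expect_false(res$flag)
  # injected irregular at cv 0.30: flagged
  tr <- gen(am_preset(), 30, 5, seed = 2,
            event = list(type = "irregular", cv = 0.30))
  res2 <- detect_irregular(detect_beats(detrend_trace(tr)))
  expect_true(res2$flag)
  expect_gt(res2$ibi_cv, 0.15)
  # too few beats: not evaluable
  expect_true(is.na(detect_irregular(beats[1:3, ])$flag))
})

test_that("arrest is called at one beat or fewer, with a sharp boundary", {
  tr <- gen(ct_preset(), 30, 5, seed = 3,
            event = list(type = "arrest", onset = 0))
  a <- analyze_post(tr)
  expect_equal(a$summ$n_beats, 0L)
  expect_identical(a$call$label, "arrest")
  # a normal AM trace (~118 beats/30 s) is not arrest
  b <- analyze_post(gen(am_preset(), 30, 5, seed = 4))
  expect_gt(b$summ$n_beats, 100)
  expect_false(detect_arrest(b$summ))
  # exactly 2 beats: not arrest (boundary contract)
  expect_false(detect_arrest(list(n_beats = 2L)))
  expect_true(detect_arrest(list(n_beats = 1L)))
})

test_that("classification priority is arrest > EAD > irregular > normal", {
  # EAD beats early, then arrest: label must be arrest
  tr <- gen(ct_preset(), 30, 5, seed = 5,
            event = list(type = "arrest", onset = 0.5))
  a <- analyze_post(tr)
  expect_identical(a$call$label, "arrest")
  # EAD only
  tr2 <- gen(ct_preset(), 30, 5, seed = 5,
             event = list(type = "EAD", bump = 0.12, phase = 0.5,
                          affect_fraction = 0.8))
  expect_identical(analyze_post(tr2)$call$label, "EAD")
})

test_that("incidence tables count each condition with its denominator", {
  cfg <- plate_config(paste0("A", 1:4), group = "AM", drug = "vehicle",
                      concentration_uM = 0, seeds = 1:4, phases = "post")
  pa <- analyze_plate(as_plate_recording(generate_plate(cfg, duration = 15)),
                      window = 15)
  inc <- pa$incidence
  expect_equal(inc$n, 4L)
  expect_equal(inc$n_irregular + inc$n_ead + inc$n_arrest, 0L)
})

test_that("labels are exhaustive and mutually exclusive on a mixed plate", {
  cfg <- plate_config(paste0("B", 1:6), group = "CT", drug = "mix",
                      concentration_uM = 1, seeds = 1:6,
                      events = c("none", "EAD", "irregular", "arrest",
                                 "none", "arrest"),
                      ead_bump = 0.10, ead_phase = 0.5, irr_cv = 0.30,
                      arrest_onset = 0, phases = "post")
  pa <- analyze_plate(as_plate_recording(generate_plate(cfg)))
  calls <- pa$event_calls
  expect_equal(nrow(calls), 6L)
  expect_true(all(calls$label %in% c("normal", "irregular", "EAD", "arrest")))
  inc <- pa$incidence
  expect_equal(inc$n_irregular + inc$n_ead + inc$n_arrest +
                 sum(calls$label == "normal"), 6L)
})
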