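small_sim <- function(n = 2, duration = 5, events = "none", ...) {
  cfg <- plate_config(paste0("A", seq_len(n)), group = "AM", drug = "drugX",
                      concentration_uM = 1, seeds = seq_len(n),
                      events = events, ...)
  generate_plate(cfg, duration = duration)
}

test_that("plate generation has the declared shape", {
  sim <- small_sim(3)
  expect_equal(ncol(sim$trace_df), 1 + 3 * 2)   # time + well x phase
  expect_identical(names(sim$trace_df)[1], "time_s")
  expect_setequal(names(sim$traces),
                  c(outer(paste0("A", 1:3), c("pre", "post"), paste, sep = "_")))
  # post-only plates have one column per well
  cfg <- plate_config(paste0("B", 1:6), group = "AM", seeds = 1:6,
                      phases = "post")
  sim2 <- generate_plate(cfg, duration = 5)
  expect_equal(ncol(sim2$trace_df), 1 + 6)
})

test_that("duplicate wells and empty configs are handled per contract", {
  cfg <- plate_config(c("A1", "A1"), group = "AM", seeds = 1:2)
  expect_error(generate_plate(cfg, duration = 5), "duplicate")
  empty <- plate_config(character(0), group = "AM", seeds = integer(0))
  sim <- generate_plate(empty, duration = 5)
  expect_equal(ncol(sim$trace_df), 1L)   # time column only
  expect_equal(nrow(sim$ground_truth), 0L)
})

test_that("write/read round-trip preserves the recording", {
  dir <- withr::local_tempdir()
  sim <- small_sim(2)
  write_plate(sim, dir)
  rec <- read_plate(file.path(dir, "traces.csv"),
                    file.path(dir, "plate_map.csv"))
  expect_s3_class(rec, "plate_recording")
  expect_length(rec$wells, 2L)
  for (w in names(rec$wells)) {
    for (ph in c("pre", "post")) {
      orig <- sim$traces[[paste(w, ph, sep = "_")]]
      got <- rec$wells[[w]][[ph]]
      expect_equal(got$signal, orig$signal, tolerance = 1e-9)
      expect_equal(got$time, orig$time, tolerance = 1e-9)
      expect_identical(got$phase, ph)
    }
  }
})

test_that("malformed trace files raise format errors", {
  dir <- withr::local_tempdir()
  sim <- small_sim(2)
  write_plate(sim, dir)
  tf <- file.path(dir, "traces.csv")
  pf <- file.path(dir, "plate_map.csv")

  # gap in the time column
  td <- utils::read.csv(tf, check.names = FALSE)
  utils::write.csv(td[-3, ], file.path(dir, "gap.csv"), row.names = FALSE)
  expect_error(read_plate(file.path(dir, "gap.csv"), pf), "uniform")

  # NaN in a signal
  td2 <- utils::read.csv(tf, check.names = FALSE)
  td2$A1_pre[5] <- NaN
  utils::write.csv(td2, file.path(dir, "nan.csv"), row.names = FALSE)
  expect_error(read_plate(file.path(dir, "nan.csv"), pf), "non-finite")

  # plate map missing a well present in the CSV: error names the well
  pm <- utils::read.csv(pf)
  utils::write.csv(pm[!(pm$well == "A2" & pm$phase == "post"), ],
                   file.path(dir, "short_map.csv"), row.names = FALSE)
  expect_error(read_plate(tf, file.path(dir, "short_map.csv")), "A2_post")

  # post trace without a pre partner
  pm2 <- pm[!(pm$well == "A2" & pm$phase == "pre"), ]
  td3 <- utils::read.csv(tf, check.names = FALSE)
  td3$A2_pre <- NULL
  utils::write.csv(td3, file.path(dir, "nopre.csv"), row.names = FALSE)
  utils::write.csv(pm2, file.path(dir, "nopre_map.csv"), row.names = FALSE)
  expect_error(read_plate(file.path(dir, "nopre.csv"),
                          file.path(dir, "nopre_map.csv")), "A2")
})

test_that("result tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  sim <- small_sim(2, duration = 15)
  pa <- analyze_plate(as_plate_recording(sim), window = 15)
  paths <- write_results(pa, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("well_summary.csv",
                                               "dose_response.csv",
                                               "incidence.csv")))))
  inc <- utils::read.csv(file.path(dir, "incidence.csv"))
  expect_equal(inc$n, 2L)
  dr <- utils::read.csv(file.path(dir, "dose_response.csv"))
  expect_equal(sort(unique(dr$parameter)), sort(dose_response_parameters()))
  back <- utils::read.csv(file.path(dir, "well_summary.csv"))
  expect_equal(nrow(back), 4L)   # 2 wells x 2 phases
  expect_equal(back$beat_rate,
               round(pa$well_summaries$beat_rate, 3), tolerance = 1e-9)
})

test_that("empty result tables produce header-only files", {
  dir <- withr::local_tempdir()
  empty <- data.frame(well_id = character(0), beat_rate = numeric(0))
  write_results(empty, out_dir = dir)
  lines <- readLines(file.path(dir, "well_summary.csv"))
  expect_length(lines, 1L)
  expect_match(lines, "well_id")
})
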