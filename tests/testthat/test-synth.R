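test_that("noise-free trials are still outside the saccade, pulse inside", {
  cfg <- synthConfig(nParticipants = 1, nSessions = 1, nPoints = 6,
                     noiseSd = 0, driftSd = 0, microsaccadeRate = 0,
                     seed = 12)
  r <- simulateRecording(cfg)
  rec <- r$recording
  nPer <- 3000L
  for (j in seq_len(6L)) {
    tr <- r$truth[j, ]
    v <- differentiate(rec@x[tr$trial_start_sample:(tr$trial_start_sample +
                                                      nPer - 1L)], rec@fs)
    win <- tr$sacc_onset_sample:tr$sacc_offset_sample
    expect_true(all(v[-win] == 0))
    # the in-window velocity is the discrete raised-cosine pulse
    durSamp <- tr$sacc_offset_sample - tr$sacc_onset_sample + 1L
    delta <- tr$target_to - tr$target_from
    prof <- function(u) pmin(pmax(u, 0), 1) - sin(2 * pi *
                                                  pmin(pmax(u, 0), 1)) /
      (2 * pi)
    expected <- (prof((win - tr$sacc_onset_sample + 1) / durSamp) -
                 prof((win - tr$sacc_onset_sample) / durSamp)) *
      delta * rec@fs
    expect_equal(v[win], expected, tolerance = 1e-9)
    # pulse integral equals the target displacement
    expect_equal(sum(v[win]) / rec@fs, delta, tolerance = 1e-9)
  }
})

test_that("simulation is bit-reproducible from its seed", {
  cfg <- synthConfig(nParticipants = 2, nSessions = 1, nPoints = 3,
                     seed = 33)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(lapply(a, function(r) r$recording@x),
                   lapply(b, function(r) r$recording@x))
  expect_identical(lapply(a, `[[`, "truth"), lapply(b, `[[`, "truth"))
})

test_that("cohort layout and identifiers follow the config", {
  cfg <- synthConfig(nParticipants = 2, nSessions = 1, nPoints = 5,
                     seed = 2)
  coh <- simulateCohort(cfg)
  expect_length(coh, 2L)
  for (r in coh) {
    expect_identical(nrow(r$recording@onsets), 5L)
    expect_identical(nrow(r$truth), 5L)
    expect_identical(length(r$recording@x), 5L * 3000L)
    # saccade window inside the trial, onset at the latency sample
    expect_true(all(r$truth$sacc_onset_sample ==
                      round(r$truth$latency_ms) + 1L))
    expect_true(all(r$truth$sacc_offset_sample <= 3000L))
  }
  expect_identical(vapply(coh, function(r) r$recording@participant,
                          character(1)), c("P01", "P02"))
  expect_error(synthConfig(trialMs = 300, latencyRange = c(100, 250),
                           saccadeDurRange = c(30, 80)), "infeasible")
})

test_that("velocity peaks fall inside the labelled saccade windows", {
  cfg <- synthConfig(nParticipants = 1, nSessions = 1, nPoints = 20,
                     seed = 71)
  r <- simulateRecording(cfg)
  for (j in seq_len(20L)) {
    tr <- r$truth[j, ]
    v <- differentiate(r$recording@x[tr$trial_start_sample:
                                       (tr$trial_start_sample + 2999L)],
                       r$recording@fs)
    peak <- which.max(abs(v))
    expect_true(peak >= tr$sacc_onset_sample &&
                  peak <= tr$sacc_offset_sample)
  }
})

test_that("latencies are uniform over the configured bounds", {
  cfg <- synthConfig(nParticipants = 1, nSessions = 1, nPoints = 1000,
                     trialMs = 500, seed = 100)
  lat <- simulateRecording(cfg)$truth$latency_ms
  expect_gte(min(lat), 100)
  expect_lte(max(lat), 250)
  ks <- suppressWarnings(stats::ks.test(lat, "punif", 100, 250))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohorts round-trip through the gaze CSV dialect", {
  cfg <- synthConfig(nParticipants = 2, nSessions = 1, nPoints = 2,
                     trialMs = 600, latencyRange = c(80, 200),
                     saccadeDurRange = c(30, 60), seed = 9)
  coh <- simulateCohort(cfg)
  dir <- withr::local_tempdir()
  files <- writeCohort(coh, dir)
  expect_true(all(file.exists(files)))
  g <- file.path(dir, "P02_S1_gaze.csv")
  back <- readGaze(g, fs = 1000,
                   schedule = file.path(dir, "P02_S1_schedule.csv"),
                   columns = list(t = "t", x = "x",
                                  participant = "participant",
                                  session = "session"))
  expect_identical(back@x, coh[[2]]$recording@x)
  expect_identical(back@participant, "P02")
  expect_equal(back@onsets, coh[[2]]$recording@onsets)
})

test_that("saccade-bearing windows score lower entropy than fixation", {
  cfg <- synthConfig(nParticipants = 1, nSessions = 1, nPoints = 10,
                     seed = 55)
  r <- simulateRecording(cfg)
  maps <- lapply(extractEMSeries(r$recording, 2048L), buildMEM)
  # level 3 (256-sample windows): the cell holding each trial's saccade
  # midpoint, against the purely fixational second half of the series
  mid <- ceiling((r$truth$sacc_onset_sample +
                    r$truth$sacc_offset_sample) / 2 / 256)
  sacc <- vapply(seq_along(maps), function(i) memCell(maps[[i]], 3, mid[i]),
                 numeric(1))
  fix <- vapply(maps, function(m) mean(memCell(m, 3, 5:8)), numeric(1))
  expect_lt(mean(sacc), mean(fix))
  expect_lt(t.test(sacc, fix, alternative = "less")$p.value, 0.01)
})
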