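test_that("generator spec validates its parameters", {
  expect_error(generator_spec(partial_error_prob = 1.2), "probabilities")
  expect_error(generator_spec(pmt_base = -1), "positive")
  s <- generator_spec(noise_sd = 3, burst_snr = 10)
  expect_equal(s$burst_gain, 30)
  expect_equal(generator_spec(burst_gain = 7)$burst_gain, 7)
})

test_that("dataset counting, determinism and file layout", {
  spec <- generator_spec(n_participants = 2, trials_per_cell = 10)
  ds <- generate_dataset(spec, seed = 123)
  # 2 participants x 3 SAT x 2 lexicality x 10 trials = 120 event rows
  expect_equal(nrow(ds$events), 120)
  expect_equal(nrow(ds$truth), 120)
  expect_equal(length(ds$recordings), 2)
  expect_silent(validate_events(ds$events))
  # identical seed -> byte-identical files
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  generate_dataset(spec, seed = 123, dir = d1)
  generate_dataset(spec, seed = 123, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and the written layout is readable by the io layer
  rec <- read_recording(file.path(d1, "recording_P01.tsv"))
  expect_equal(rec$sampling_rate, 1000)
  ev <- read_events(file.path(d1, "events.tsv"))
  expect_equal(nrow(ev), 120)
})

test_that("ground truth satisfies rt = pmt + mt and the deadline logic", {
  spec <- generator_spec(n_participants = 3, trials_per_cell = 15)
  ds <- generate_dataset(spec, seed = 7)
  tru <- ds$truth
  expect_equal(tru$rt_ms, tru$pmt_ms + tru$mt_ms)
  dl <- spec$deadline_ms[tru$sat]
  expect_equal(tru$no_response, unname(tru$rt_ms > dl))
  ev <- ds$events
  expect_true(all(is.na(ev$rt_ms) == tru$no_response))
  pl <- tru$partial_latency_ms
  expect_true(all(pl[!is.na(pl)] < tru$rt_ms[!is.na(pl)]))
})

test_that("zero-noise construction places the burst exactly at the onset", {
  spec <- generator_spec(noise_sd = 0, burst_gain = 10,
                         error_prob = c(neutral = 0, accuracy = 0,
                                        speed = 0),
                         partial_error_prob = 0)
  set.seed(99)
  tr <- generate_trial(spec, "neutral", "word")
  stim <- 501
  onset <- tr$truth$onset_sample
  expect_equal(onset, stim + round(tr$truth$pmt_ms))
  expect_true(all(tr$signal[seq_len(onset - 1), ] == 0))
  expect_true(any(tr$signal[onset:(onset + 50), "right"] != 0))
  # detector lands within the envelope rise of the programmed onset
  ep <- make_epoch(tr$signal, rt_ms = tr$event$rt_ms)
  est <- detect_trial_onset(ep)
  expect_lt(abs(est$onset_ms - tr$truth$pmt_ms), 10)
})

test_that("forced partial errors are detectable end to end", {
  spec <- generator_spec(n_participants = 1, trials_per_cell = 4,
                         partial_error_prob = 1,
                         error_prob = c(neutral = 0, accuracy = 0,
                                        speed = 0))
  res <- suppressWarnings(recovery_experiment(spec, seed = 31))
  resp <- res$trials[!res$trials$trial_class %in%
                       c("no_response", "excluded"), ]
  expect_true(all(resp$trial_class == "partial_error_trial"))
  # recovered covert latencies track the programmed ones
  m <- merge(res$partials, res$truth, by = c("participant", "trial"))
  expect_lt(median(abs(m$latency_ms - m$partial_latency_ms)), 25)
})

test_that("programmed motor-time contrasts are exact at the truth level", {
  spec <- generator_spec()
  set.seed(13)
  draw <- function(sat, lex, n)
    vapply(seq_len(n), function(i)
      emgchrono:::sample_trial_truth(spec, sat, lex)$mt, numeric(1))
  n <- 10000
  d_speed <- mean(draw("speed", "word", n)) - mean(draw("neutral", "word", n))
  expect_lt(abs(d_speed - (-24.37)), 1)
  d_lex <- mean(draw("neutral", "pseudoword", n)) -
    mean(draw("neutral", "word", n))
  expect_lt(abs(d_lex - 5.94), 1)
})

test_that("no-response rate concentrates in the speed condition", {
  run <- study_run()
  nr <- tapply(run$truth$no_response, run$truth$sat, mean)
  expect_gt(nr[["speed"]], nr[["neutral"]])
  expect_gt(nr[["speed"]], 0.005)
  expect_lt(nr[["speed"]], 0.06)
})
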