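test_that("baseline threshold is mean + 3.5 SD of rectified baseline", {
  # two baseline samples |x| = 1, 3: mean 2, SD sqrt(2)
  sig <- cbind(left = rep(0, 4), right = c(1, -3, 5, 5))
  ep <- make_epoch(sig, fs = 4, pre_ms = 500)
  expect_equal(baseline_threshold(ep, "right"), 2 + 3.5 * sqrt(2))
  # all-equal baseline: SD = 0, threshold = mean
  sig2 <- cbind(left = rep(0, 4), right = c(2, -2, 9, 9))
  expect_equal(baseline_threshold(make_epoch(sig2, fs = 4), "right"), 2)
  # multiplier configurable
  expect_equal(baseline_threshold(ep, "right", multiplier = 2),
               2 + 2 * sqrt(2))
  ep_empty <- make_epoch(sig, fs = 4, pre_ms = 0)
  expect_error(baseline_threshold(ep_empty, "right"), "baseline")
})

test_that("window rules: merge within 25 ms, keep >= 50 ms, pre-press only", {
  x <- numeric(1200)
  # runs [100,140) and [160,230): 20-ms gap -> merged to [100,230), 130 ms
  x[c(100:139, 160:229)] <- 10
  w <- detect_windows(x, threshold = 5, rt_sample = 1000)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$start, w$end), c(100, 230))
  expect_equal(w$duration_ms, 130)
  # lone 40-ms run is discarded
  x2 <- numeric(1200); x2[100:139] <- 10
  expect_equal(nrow(detect_windows(x2, 5, 1000)), 0)
  # run starting after the press (rt 650 ms -> sample 651 in this frame)
  x3 <- numeric(1200); x3[900:1100] <- 10
  expect_equal(nrow(detect_windows(x3, 5, rt_sample = 651)), 0)
  expect_equal(nrow(detect_windows(x3, 5, rt_sample = NULL)), 1)
  # exactly 25 ms does NOT merge (strict rule)
  x4 <- numeric(1200); x4[c(100:159, 185:244)] <- 10
  expect_equal(nrow(detect_windows(x4, 5, 1000)), 2)
})

test_that("detect_windows matches the brute-force oracle on random masks", {
  set.seed(303)
  for (i in 1:400) {
    n <- sample(c(30:400, 2000:3000), 1)
    p <- runif(1, 0.02, 0.6)
    mask <- runif(n) < p
    # occasionally plant long runs so retained windows actually occur
    if (runif(1) < 0.5) {
      s <- sample(max(1, n - 80), 1)
      mask[s:min(n, s + sample(30:80, 1))] <- TRUE
    }
    rt <- if (runif(1) < 0.5) sample(n, 1) else NULL
    got <- emgchrono:::detect_windows_mask(mask, rt)
    want <- oracle_windows(mask, rt)
    expect_equal(unname(got), unname(want))
  }
})

test_that("merging is idempotent and thresholds act monotonically", {
  set.seed(404)
  for (i in 1:40) {
    n <- 2000
    x <- abs(rnorm(n)) + 3 * (runif(n) < 0.1)
    w1 <- detect_windows(x, threshold = 1.5)
    # re-applying the rules to the windows' own mask changes nothing
    mask <- rep(FALSE, n)
    for (k in seq_len(nrow(w1))) mask[w1$start[k]:(w1$end[k] - 1)] <- TRUE
    w2 <- emgchrono:::detect_windows_mask(mask)
    expect_equal(unname(cbind(w1$start, w1$end)), unname(w2))
    # total retained duration never grows as the threshold is raised
    durs <- vapply(c(1, 1.5, 2, 3, 4), function(th)
      sum(detect_windows(x, th)$duration_ms), numeric(1))
    expect_true(all(diff(durs) <= 0))
  }
})

test_that("onset validation accepts only the last pre-press window", {
  w <- data.frame(start = c(200, 700), end = c(260, 900),
                  duration_ms = c(60, 200), peak_abs = c(5, 20))
  onset_in <- list(onset_sample = 705, onset_ms = 204)
  expect_true(validate_onset(onset_in, w, rt_sample = 850)$valid)
  # onset sitting in an earlier window (noise burst) -> rejected
  onset_early <- list(onset_sample = 210, onset_ms = -291)
  v <- validate_onset(onset_early, w, rt_sample = 850)
  expect_false(v$valid)
  expect_equal(v$reason, "onset_outside_last_window")
  # tolerance admits onsets slightly before the window start
  onset_near <- list(onset_sample = 692)
  expect_true(validate_onset(onset_near, w, rt_sample = 850)$valid)
  expect_false(validate_onset(list(onset_sample = 680), w, 850)$valid)
  # no retained window at all
  v0 <- validate_onset(onset_in, w[0, ], rt_sample = 850)
  expect_false(v0$valid)
  expect_equal(v0$reason, "no_window")
})

test_that("covert activations are typed by the correctness of the press", {
  set.seed(55)
  n <- 2000
  base <- function() rnorm(n, 0, 2)
  burst <- function(x, at, len, amp) {
    x[at:(at + len - 1)] <- x[at:(at + len - 1)] + rnorm(len, 0, amp)
    x
  }
  # correct press, covert burst on the other (incorrect) hand at ~320 ms
  sig <- cbind(left = burst(base(), 820, 120, 30),
               right = burst(base(), 1100, 250, 50))
  ep <- make_epoch(sig, rt_ms = 700, responding = "right",
                   correct = "right")
  pa <- detect_partial_activations(ep)
  expect_equal(nrow(pa), 1)
  expect_equal(pa$kind, "partial_error")
  expect_lt(abs(pa$latency_ms - 320), 25)
  # overt error (press with left, correct was right): covert right burst
  ep2 <- make_epoch(sig[, 2:1], rt_ms = 700, responding = "left",
                    correct = "right")
  colnames(ep2$signal) <- c("left", "right")
  pa2 <- detect_partial_activations(ep2)
  expect_equal(pa2$kind, "partial_correct")
  # clean channel -> empty
  ep3 <- make_epoch(cbind(left = base(), right = burst(base(), 1100, 250,
                                                       50)),
                    rt_ms = 700, responding = "right", correct = "right")
  expect_equal(nrow(detect_partial_activations(ep3)), 0)
})
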