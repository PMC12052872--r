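test_that("masked averaging rectifies and ignores padded samples", {
  a <- c(1, -2, 3, -4)
  # single segment: curve equals the rectified segment
  av1 <- average_curve(rbind(a))
  expect_equal(av1$curve, abs(a))
  # two segments a and -a: mean rectified curve is |a|
  av2 <- average_curve(rbind(a, -a))
  expect_equal(av2$curve, abs(a))
  expect_equal(av2$n_epochs, 2)
  # masked-mean oracle: a sample with one valid contributor uses it alone
  segs <- rbind(c(1, 1, 5), c(3, 3, 99))
  valid <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, FALSE))
  av3 <- average_curve(segs, valid)
  expect_equal(av3$curve, c(2, 1, 5))
  expect_equal(av3$n_contributing, c(2L, 1L, 1L))
  # signed averaging on request
  expect_equal(average_curve(rbind(a, -a), rectify = FALSE)$curve,
               rep(0, 4))
  expect_error(average_curve(matrix(0, 0, 4)), "no segments")
})

test_that("amplitude metric: analytic triangle case and boundaries", {
  tri <- triangle_curve(A = 4)
  amp <- curve_amplitude(tri$y, tri$t, return_fraction = 0.30)
  # descending flank hits 0.3*peak at t = 170 ms; the mean over the
  # 1-ms grid on [0, 170) is (sum_{0..99} 4t/100 + 4 + sum_{101..169}
  # 4(200-t)/100) / 170 = 4 * 95.35 / 170
  expect_false(amp$no_return)
  expect_equal(amp$window_end_ms, 170)
  expect_equal(amp$amplitude, 4 * 95.35 / 170, tolerance = 1e-9)
  # linearity in a global rescaling
  amp2 <- curve_amplitude(3 * tri$y, tri$t)
  expect_equal(amp2$amplitude, 3 * amp$amplitude, tolerance = 1e-9)
  expect_equal(amp2$window_end_ms, amp$window_end_ms)
  # monotone non-decreasing curve never returns below the fraction
  t <- -500:1000
  mono <- pmax(t, 0) / 1000
  ampm <- curve_amplitude(mono, t)
  expect_true(ampm$no_return)
  expect_gt(ampm$window_end_ms, 1000)
  # all-zero curve -> missing
  expect_true(is.na(curve_amplitude(numeric(1501), t)$amplitude))
})

test_that("slope metric equals the OLS coefficient over 0-30 ms", {
  t <- -500:1000
  line <- ifelse(t >= 0, 2 * t, 0)
  expect_equal(curve_slope(line, t), 2.0)
  expect_equal(curve_slope(rep(5, length(t)), t), 0)
  # agrees with lm() on an arbitrary curve
  set.seed(21)
  y <- abs(rnorm(length(t)))
  sel <- t >= 0 & t <= 30
  expect_equal(curve_slope(y, t),
               unname(coef(lm(y[sel] ~ t[sel]))[2]))
  expect_error(curve_slope(y, t, window_ms = c(0, 0.2)), "two samples")
})

test_that("OLS slope is unbiased under centered noise", {
  set.seed(31)
  t <- 0:30
  est <- replicate(1000, curve_slope(2 * t + rnorm(31, 0, 3), t))
  se <- sd(est) / sqrt(1000)
  expect_lt(abs(mean(est) - 2), 4 * se)
})

test_that("per-cell curves: onset-locked shape and metric monotonicity", {
  run <- small_run()
  curves <- run$res$curves
  expect_true(all(curves$n_epochs >= 1))
  expect_true(all(curves$amplitude_metric > 0))
  expect_true(all(curves$slope_metric > 0))
  # rebuild one cell's curve and check the value at lag 0 sits near the
  # detection threshold, far below the peak
  spec <- run$spec
  cfg <- run_config()
  rec <- preprocess_recording(run$ds$recordings[[1]], cfg)
  ev <- run$ds$events[run$ds$events$participant == "P01", ]
  eps <- epoch_stimulus_locked(rec, ev, cfg)
  pr <- process_epochs(eps, cfg)
  tab <- participant_curves(eps, pr$trials, cfg, keep_curves = TRUE)
  cv <- attr(tab, "curves")
  times <- cv$times_ms
  for (k in setdiff(names(cv), "times_ms")) {
    y <- cv[[k]]
    peak <- max(y[times >= 0], na.rm = TRUE)
    at0 <- y[times == 0]
    expect_gt(at0, 0)           # above zero at the estimated onset
    expect_lt(at0, 0.5 * peak)  # but nowhere near the burst peak
  }
})

test_that("faster envelope rise steepens the measured rising flank", {
  cfg <- run_config()
  slopes <- vapply(c(60, 15), function(rise) {
    spec <- generator_spec(n_participants = 1, trials_per_cell = 8,
                           rise_ms = rise, partial_error_prob = 0,
                           error_prob = c(neutral = 0, accuracy = 0,
                                          speed = 0))
    ds <- generate_dataset(spec, seed = 9)
    res <- suppressWarnings(
      run_pipeline(ds$recordings, ds$events, cfg))
    mean(res$curves$slope_metric)
  }, numeric(1))
  expect_gt(slopes[2], slopes[1])
})
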