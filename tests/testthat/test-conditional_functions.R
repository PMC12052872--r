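trial_stub <- function(rt, class, participant = "P01", sat = "neutral",
                       lexicality = "word") {
  data.frame(participant = participant, trial = seq_along(rt),
             sat = sat, lexicality = lexicality, rt_ms = rt,
             trial_class = class, stringsAsFactors = FALSE)
}

test_that("quantile partition is rank-based with balanced bins", {
  expect_equal(quantile_partition(1:10, 5), rep(1:5, each = 2))
  expect_equal(quantile_partition(10:1, 5), rep(5:1, each = 2))
  expect_equal(quantile_partition(c(3, 1, 2, 5, 4), 5), c(3, 1, 2, 5, 4))
  # ties: stable input order, sizes differ by at most one
  b <- quantile_partition(rep(7, 9), 4)
  expect_equal(b, c(1, 1, 1, 2, 2, 3, 3, 4, 4))
  expect_true(all(abs(diff(as.integer(table(b)))) <= 1))
  expect_error(quantile_partition(1:3, 5), "at least K")
  # invariance under monotone transforms of latency
  set.seed(1)
  x <- rexp(37)
  expect_equal(quantile_partition(x, 5), quantile_partition(log(x), 5))
  expect_equal(quantile_partition(x, 5), quantile_partition(x * 100, 5))
})

test_that("CAF proportions follow the per-bin accuracy", {
  tr <- trial_stub(seq(400, 490, by = 10),
                   c("overt_error", "overt_error", rep("pure_correct", 8)))
  out <- caf(tr, K = 5)
  expect_equal(out$proportion, c(0, 1, 1, 1, 1))
  expect_equal(out$n_trials, rep(2L, 5))
  expect_equal(out$mean_latency_ms, c(405, 425, 445, 465, 485))
  # all-correct cell
  out2 <- caf(trial_stub(seq(400, 490, 10), "pure_correct"), K = 5)
  expect_equal(out2$proportion, rep(1, 5))
  # cells smaller than K are skipped with a warning
  expect_warning(res <- caf(trial_stub(1:3, "pure_correct"), K = 5),
                 "skipped")
  expect_null(res)
})

test_that("CIAF pools overt responses with covert partial-error onsets", {
  tr <- trial_stub(seq(500, 570, by = 10), rep("pure_correct", 8))
  partials <- data.frame(participant = "P01", trial = 9:10,
                         sat = "neutral", lexicality = "word",
                         rt_ms = c(600, 610), latency_ms = c(310, 320),
                         duration_ms = 80, peak_abs = 10,
                         kind = "partial_error", stringsAsFactors = FALSE)
  out <- ciaf(tr, partials, K = 5)
  # the two partials have the two smallest latencies: bin 1 is all-flagged
  expect_equal(out$proportion, c(1, 0, 0, 0, 0))
  expect_equal(sum(out$n_trials), 10)
  # no partials and no overt errors -> all zero
  out0 <- ciaf(tr, partials[0, ], K = 4)
  expect_equal(out0$proportion, rep(0, 4))
})

test_that("CIAF incorrect-activation mass dominates CAF error mass", {
  run <- study_run()
  ciaf_tab <- suppressWarnings(ciaf(run$trials, run$partials,
                                    by_participant = FALSE))
  caf_tab <- suppressWarnings(caf(run$trials, by_participant = FALSE))
  for (s in unique(ciaf_tab$sat)) for (l in unique(ciaf_tab$lexicality)) {
    ia <- ciaf_tab[ciaf_tab$sat == s & ciaf_tab$lexicality == l, ]
    ac <- caf_tab[caf_tab$sat == s & caf_tab$lexicality == l, ]
    expect_gte(sum(ia$proportion * ia$n_trials),
               sum((1 - ac$proportion) * ac$n_trials))
  }
})

test_that("bin counts partition each cell and pool to the overall rate", {
  run <- study_run()
  caf_tab <- suppressWarnings(caf(run$trials))
  tr <- run$trials[run$trials$trial_class %in%
                     c("pure_correct", "partial_error_trial", "overt_error",
                       "partial_correct_trial"), ]
  cells <- split(tr, interaction(tr$participant, tr$sat, tr$lexicality,
                                 drop = TRUE))
  for (cell in cells) {
    sub <- caf_tab[caf_tab$participant == cell$participant[1] &
                     caf_tab$sat == cell$sat[1] &
                     caf_tab$lexicality == cell$lexicality[1], ]
    if (nrow(sub) == 0) next
    expect_equal(sum(sub$n_trials), nrow(cell))
    pooled <- sum(sub$proportion * sub$n_trials) / sum(sub$n_trials)
    expect_equal(pooled,
                 mean(cell$trial_class %in% c("pure_correct",
                                              "partial_error_trial")))
  }
})

test_that("partial-error rate and correction likelihood count correctly", {
  cls <- c(rep("partial_error_trial", 6), rep("overt_error", 2),
           rep("pure_correct", 94), rep("no_response", 3))
  tr <- trial_stub(c(seq(400, length.out = 102, by = 2), NA, NA, NA), cls)
  expect_equal(partial_error_rate(tr), 6 / 100)
  expect_equal(correction_likelihood(tr), 0.75)
  # boundary cases
  expect_equal(correction_likelihood(trial_stub(1:6,
    c("partial_error_trial", rep("pure_correct", 5)))), 1.0)
  expect_true(is.na(correction_likelihood(trial_stub(1:5,
                                                     "pure_correct"))))
  expect_equal(partial_error_rate(trial_stub(1:5, "pure_correct")), 0)
  expect_true(is.na(partial_error_rate(trial_stub(c(NA, NA),
    c("no_response", "no_response")))))
  # brute-force recount on a random table
  set.seed(77)
  classes <- sample(c("pure_correct", "partial_error_trial", "overt_error",
                      "partial_correct_trial", "no_response"), 50,
                    replace = TRUE, prob = c(.6, .1, .1, .05, .15))
  rts <- ifelse(classes == "no_response", NA, runif(50, 300, 900))
  tab <- trial_stub(rts, classes)
  pe <- sum(classes == "partial_error_trial")
  pc <- sum(classes == "pure_correct")
  oe <- sum(classes %in% c("overt_error", "partial_correct_trial"))
  expect_equal(partial_error_rate(tab), pe / (pe + pc))
  expect_equal(correction_likelihood(tab), pe / (pe + oe))
})

test_that("Morey CI matches the brute-force two-step computation", {
  # participants with identical condition profiles shifted by constants:
  # between-participant variance is removed entirely
  prof <- c(400, 450, 520)
  m <- rbind(prof, prof + 30, prof - 12, prof + 100)
  expect_equal(unname(morey_ci(m)), rep(0, 3))
  # J = 2: correction factor sqrt(2) exactly
  set.seed(88)
  m2 <- matrix(rnorm(20, 500, 40), ncol = 2)
  norm <- m2 - rowMeans(m2) + mean(m2)
  hand <- qt(0.975, 9) * apply(norm, 2, sd) / sqrt(10) * sqrt(2)
  expect_equal(unname(morey_ci(m2)), unname(hand))
  # random 10 x 3 tables against the independent implementation
  for (i in 1:20) {
    m3 <- matrix(rnorm(30, 600, 50) + rep(rnorm(10, 0, 80), 3), ncol = 3)
    expect_equal(unname(morey_ci(m3)), oracle_morey(m3))
    expect_equal(unname(morey_ci(m3, 0.9)), oracle_morey(m3, 0.9))
  }
  expect_error(morey_ci(matrix(1:10, ncol = 1)), "two conditions")
  m4 <- matrix(rnorm(30), ncol = 3); m4[2, 3] <- NA
  expect_error(morey_ci(m4), "missing")
})

test_that("BIC Bayes-factor approximation is exp(deltaBIC / 2)", {
  expect_equal(bic_bayes_factor(100, 100), 1)
  expect_equal(bic_bayes_factor(102, 100), exp(1))
  # a deltaBIC of 2 * log(0.00048) recovers BF = 0.00048
  expect_equal(bic_bayes_factor(2 * log(0.00048), 0), 0.00048)
  expect_error(bic_bayes_factor(Inf, 0), "finite")
  expect_error(bic_bayes_factor(0, NA), "finite")
})

test_that("model-ready export carries centered and orthogonal quantiles", {
  tr <- trial_stub(seq(400, 490, by = 10), rep("pure_correct", 10))
  out <- model_ready(caf(tr, K = 5))
  expect_equal(out$quantile_c, (1:5) - 3)
  P <- poly(1:5, 2)
  expect_equal(out$q_lin, P[, 1], ignore_attr = TRUE)
  expect_equal(out$q_quad, P[, 2], ignore_attr = TRUE)
  expect_equal(sum(out$q_lin * out$q_quad), 0, tolerance = 1e-12)
})
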