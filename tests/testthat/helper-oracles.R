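# Independent brute-force oracles, deliberately written with explicit loops
# so they share no code path with the implementation.

# exhaustive integrated-profile argmin: recompute c_i and the chord point
# by point
oracle_ip_onset <- function(x) {
  n <- length(x)
  d <- numeric(n)
  c1 <- abs(x[1])
  cn <- sum(abs(x))
  for (i in seq_len(n)) {
    ci <- sum(abs(x[seq_len(i)]))
    d[i] <- ci - (c1 + (cn - c1) * (i - 1) / (n - 1))
  }
  which(d == min(d))[1]
}

# scan-based implementation of the four activity-window rules
oracle_windows <- function(mask, rt_sample = NULL, fs = 1000,
                           gap_ms = 25, min_ms = 50) {
  n <- length(mask)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j + 1)
      i <- j + 1
    } else i <- i + 1
  }
  merged <- list()
  for (r in runs) {
    k <- length(merged)
    if (k > 0 && (r[1] - merged[[k]][2]) * 1000 / fs < gap_ms)
      merged[[k]][2] <- r[2]
    else merged[[k + 1]] <- r
  }
  out <- list()
  for (r in merged) {
    dur <- (r[2] - r[1]) * 1000 / fs
    if (dur < min_ms) next
    if (!is.null(rt_sample) && r[1] >= rt_sample) next
    out[[length(out) + 1]] <- r
  }
  if (length(out) == 0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

# two-step within-participant CI computation, written long-hand
oracle_morey <- function(m, coverage = 0.95) {
  n <- nrow(m); J <- ncol(m)
  grand <- mean(m)
  norm <- m
  for (i in seq_len(n))
    for (j in seq_len(J))
      norm[i, j] <- m[i, j] - mean(m[i, ]) + grand
  hw <- numeric(J)
  for (j in seq_len(J)) {
    se <- sd(norm[, j]) / sqrt(n)
    hw[j] <- qt(1 - (1 - coverage) / 2, n - 1) * se * sqrt(J / (J - 1))
  }
  hw
}

# step segment: q quiescent samples then a constant plateau of height h
step_segment <- function(q, total, h = 1) c(rep(0, q), rep(h, total - q))

# minimal hand-built epoch for unit tests
make_epoch <- function(signal, fs = 1000, pre_ms = 500, rt_ms = NA,
                       responding = "right", correct = "right",
                       sat = "neutral", lexicality = "word",
                       participant = "P01", trial = 1L) {
  n <- nrow(signal)
  structure(list(signal = signal,
                 times_ms = seq(-pre_ms, by = 1000 / fs, length.out = n),
                 sampling_rate = fs, rt_ms = rt_ms,
                 responding_hand = responding, correct_hand = correct,
                 sat = sat, lexicality = lexicality,
                 participant = participant, trial = trial,
                 excluded = FALSE, exclusion_reason = NA_character_),
            class = "trial_epoch")
}

# isoceles-triangle test curve: rises 0 -> A over [0, 100] ms, back to 0
# at 200 ms, on the 1-kHz grid spanning [-500, 1000] ms
triangle_curve <- function(A = 4) {
  t <- -500:1000
  y <- numeric(length(t))
  up <- t >= 0 & t <= 100
  down <- t > 100 & t <= 200
  y[up] <- A * t[up] / 100
  y[down] <- A * (200 - t[down]) / 100
  list(t = t, y = y)
}

# fitted amplitude of a sinusoid of known frequency in a filtered trace
fitted_amplitude <- function(y, freq, fs) {
  n <- length(y)
  mid <- seq(round(n * 0.25), round(n * 0.75))  # skip filter transients
  t <- (mid - 1) / fs
  co <- coef(lm(y[mid] ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t)))
  sqrt(co[2]^2 + co[3]^2)
}
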