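# Conditional accuracy (CAF) and incorrect-activation (CIAF) functions,
# descriptive rates, within-participant confidence intervals and the
# BIC-based Bayes-factor approximation.

RESPONDED_CLASSES <- c("pure_correct", "partial_error_trial",
                       "overt_error", "partial_correct_trial")
CORRECT_CLASSES <- c("pure_correct", "partial_error_trial")
OVERT_ERROR_CLASSES <- c("overt_error", "partial_correct_trial")

#' Rank-based equal-count quantile bins
#'
#' Trial with 0-based stable rank `r` among `n` latencies goes to bin
#' `floor(r * K / n) + 1`; bin sizes differ by at most one and ties keep
#' input order (deterministic).
#'
#' @param latencies numeric latencies, ms.
#' @param K number of bins (default 5).
#' @return Integer bin index per trial, in input order.
#' @export
quantile_partition <- function(latencies, K = 5) {
  n <- length(latencies)
  if (n < K) stop("need at least K latencies to form K quantile bins",
                  call. = FALSE)
  r <- rank(latencies, ties.method = "first") - 1
  as.integer(floor(r * K / n) + 1L)
}

conditional_groups <- function(tab, by_participant) {
  keys <- if (by_participant) c("participant", "sat", "lexicality")
  else c("sat", "lexicality")
  interaction(tab[keys], drop = TRUE, lex.order = TRUE)
}

build_conditional <- function(events, K, kind, by_participant) {
  out <- lapply(split(events, conditional_groups(events, by_participant)),
                function(cell) {
    if (nrow(cell) < K) {
      warning(sprintf("cell %s/%s/%s has %d < K events; skipped",
                      cell$participant[1] %||% "pooled", cell$sat[1],
                      cell$lexicality[1], nrow(cell)), call. = FALSE)
      return(NULL)
    }
    bin <- quantile_partition(cell$latency_ms, K)
    data.frame(participant = if (by_participant) cell$participant[1]
               else "pooled",
               sat = cell$sat[1], lexicality = cell$lexicality[1],
               quantile_index = seq_len(K),
               mean_latency_ms = as.numeric(
                 tapply(cell$latency_ms, factor(bin, seq_len(K)), mean)),
               proportion = as.numeric(
                 tapply(cell$flag, factor(bin, seq_len(K)), mean)),
               n_trials = as.integer(
                 table(factor(bin, seq_len(K)))),
               kind = kind, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Conditional accuracy function (CAF)
#'
#' Within each participant (or pooled) by SAT by lexicality cell, responded
#' trials are partitioned into `K` equal-count RT quantile bins; the CAF is
#' the proportion of correct presses per bin, together with the bin's mean
#' RT. All responded trials enter, irrespective of covert activation on the
#' other channel; no-response and excluded trials do not.
#'
#' @param trials trial table from [process_epochs()].
#' @param K number of quantile bins.
#' @param by_participant compute per participant (default) or pooled across
#'   participants.
#' @return `data.frame` of `ConditionalFunction` rows (`kind = "caf"`).
#' @export
caf <- function(trials, K = 5, by_participant = TRUE) {
  tr <- trials[trials$trial_class %in% RESPONDED_CLASSES, , drop = FALSE]
  ev <- data.frame(participant = tr$participant, sat = tr$sat,
                   lexicality = tr$lexicality, latency_ms = tr$rt_ms,
                   flag = as.numeric(tr$trial_class %in% CORRECT_CLASSES),
                   stringsAsFactors = FALSE)
  build_conditional(ev, K, "caf", by_participant)
}

#' Conditional incorrect-activation function (CIAF)
#'
#' The event set pools overt responses (latency = RT, flagged when the
#' press was an overt error) with covert partial errors (latency = the
#' activation onset, always flagged), so the function tracks the proportion
#' of incorrect EMG activations as a function of (partial) response
#' latency.
#'
#' @param trials trial table from [process_epochs()].
#' @param partials covert-activation table from [process_epochs()].
#' @inheritParams caf
#' @return `data.frame` of `ConditionalFunction` rows (`kind = "ciaf"`).
#' @export
ciaf <- function(trials, partials, K = 5, by_participant = TRUE) {
  tr <- trials[trials$trial_class %in% RESPONDED_CLASSES, , drop = FALSE]
  overt <- data.frame(participant = tr$participant, sat = tr$sat,
                      lexicality = tr$lexicality, latency_ms = tr$rt_ms,
                      flag = as.numeric(tr$trial_class %in%
                                          OVERT_ERROR_CLASSES),
                      stringsAsFactors = FALSE)
  pe <- partials[partials$kind == "partial_error", , drop = FALSE]
  cov <- data.frame(participant = pe$participant, sat = pe$sat,
                    lexicality = pe$lexicality, latency_ms = pe$latency_ms,
                    flag = rep(1, nrow(pe)), stringsAsFactors = FALSE)
  build_conditional(rbind(overt, cov), K, "ciaf", by_participant)
}

count_classes <- function(tr) {
  c(pe = sum(tr$trial_class == "partial_error_trial"),
    pc = sum(tr$trial_class == "pure_correct"),
    oe = sum(tr$trial_class %in% OVERT_ERROR_CLASSES),
    responded = sum(tr$trial_class %in% RESPONDED_CLASSES))
}

#' Partial-error rate
#'
#' Share of correct-response trials carrying a covert incorrect-hand
#' activation: `partial_error_trials / (partial_error_trials +
#' pure_correct)`. No-response trials are discarded; `NA` when no correct
#' responses exist.
#'
#' @param trials trial table (already restricted to the cell of interest).
#' @return Rate in \[0, 1\] or `NA`.
#' @export
partial_error_rate <- function(trials) {
  k <- count_classes(trials)
  if (k[["pe"]] + k[["pc"]] == 0) return(NA_real_)
  unname(k[["pe"]] / (k[["pe"]] + k[["pc"]]))
}

#' Correction likelihood
#'
#' Among trials featuring an incorrect EMG activation (covert partial
#' errors or overt errors), the share that nevertheless ended in a correct
#' press: `partial_error_trials / (partial_error_trials + overt_errors)`.
#' `NA` when no incorrect activation exists.
#'
#' @inheritParams partial_error_rate
#' @return Rate in \[0, 1\] or `NA`.
#' @export
correction_likelihood <- function(trials) {
  k <- count_classes(trials)
  if (k[["pe"]] + k[["oe"]] == 0) return(NA_real_)
  unname(k[["pe"]] / (k[["pe"]] + k[["oe"]]))
}

#' Per-cell descriptive summary
#'
#' Accuracy (correct / responded, irrespective of covert activation),
#' partial-error rate and correction likelihood per participant by SAT by
#' lexicality cell, plus trial counts.
#'
#' @param trials trial table from [process_epochs()].
#' @return One row per cell.
#' @export
descriptive_summary <- function(trials) {
  cells <- split(trials, conditional_groups(trials, TRUE))
  out <- lapply(cells, function(tr) {
    k <- count_classes(tr)
    data.frame(participant = tr$participant[1], sat = tr$sat[1],
               lexicality = tr$lexicality[1],
               n = unname(k[["responded"]]),
               n_no_response = sum(tr$trial_class == "no_response"),
               accuracy = if (k[["responded"]] > 0)
                 unname((k[["pc"]] + k[["pe"]]) / k[["responded"]])
               else NA_real_,
               partial_error_rate = partial_error_rate(tr),
               correction_likelihood = correction_likelihood(tr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Within-participant confidence-interval half-widths (Morey adjustment)
#'
#' Two-step procedure for repeated-measures designs: each participant's
#' mean is subtracted from their condition scores and the grand mean added
#' back; the per-condition SE of the normalized scores is then inflated by
#' `sqrt(J / (J - 1))` for `J` conditions, and the half-width is that SE
#' times the `t` quantile with `n - 1` degrees of freedom.
#'
#' @param cell_means numeric matrix or data.frame, participants in rows and
#'   conditions in columns; complete (no missing cells).
#' @param coverage interval coverage (default 0.95).
#' @return Named numeric vector of half-widths, one per condition.
#' @export
morey_ci <- function(cell_means, coverage = 0.95) {
  m <- as.matrix(cell_means)
  n <- nrow(m); J <- ncol(m)
  if (J < 2) stop("need at least two conditions", call. = FALSE)
  if (anyNA(m)) stop("cell-mean table has missing cells", call. = FALSE)
  norm <- m - rowMeans(m) + mean(m)
  se <- apply(norm, 2, stats::sd) / sqrt(n)
  hw <- stats::qt(1 - (1 - coverage) / 2, df = n - 1) *
    se * sqrt(J / (J - 1))
  stats::setNames(hw, colnames(m))
}

#' BIC-based Bayes-factor approximation
#'
#' `BF = exp((BIC_a - BIC_b) / 2)`, the approximate Bayes factor in favor
#' of model `b` over model `a`. In the standard usage for testing an
#' interaction, pass the additive (null) model's BIC as `bic_model_a` and
#' the interaction model's as `bic_model_b`: values near zero then mean
#' the data lend the interaction no support.
#'
#' @param bic_model_a,bic_model_b finite BIC values.
#' @return The approximate Bayes factor.
#' @export
bic_bayes_factor <- function(bic_model_a, bic_model_b) {
  if (!is.finite(bic_model_a) || !is.finite(bic_model_b))
    stop("BIC values must be finite", call. = FALSE)
  exp((bic_model_a - bic_model_b) / 2)
}

#' Model-ready long-format export of a conditional function
#'
#' Adds a centered quantile covariate and orthogonal-polynomial columns of
#' degree <= 2 (values only; model fitting is left to external tools).
#'
#' @param cf `data.frame` from [caf()] or [ciaf()].
#' @return The input with `quantile_c`, `q_lin` and `q_quad` columns.
#' @export
model_ready <- function(cf) {
  K <- max(cf$quantile_index)
  P <- stats::poly(seq_len(K), degree = 2)
  cf$quantile_c <- cf$quantile_index - mean(seq_len(K))
  cf$q_lin <- P[cf$quantile_index, 1]
  cf$q_quad <- P[cf$quantile_index, 2]
  cf
}
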