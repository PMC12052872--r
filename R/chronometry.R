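# RT decomposition into premotor time (PMT) and motor time (MT), trial
# classification, and the per-epoch driver that ties detection together.
#
# PMT is the interval from stimulus onset to the EMG burst onset of the
# responding hand; MT is the remainder up to the registered button press,
# so PMT + MT = RT by construction for every retained trial.

#' Decompose a trial's RT into premotor and motor time
#'
#' @param epoch a `trial_epoch` with a press.
#' @param onset a validated `onset_estimate`.
#' @return List with `pmt_ms`, `mt_ms`, `ok` and `reason`; trials whose
#'   onset falls before the stimulus or at/after the press are flagged for
#'   exclusion (`onset_before_stimulus`, `onset_after_rt`).
#' @export
decompose_trial <- function(epoch, onset) {
  pmt <- onset$onset_ms
  mt <- epoch$rt_ms - onset$onset_ms
  if (pmt <= 0)
    return(list(pmt_ms = NA_real_, mt_ms = NA_real_, ok = FALSE,
                reason = "onset_before_stimulus"))
  if (mt <= 0)
    return(list(pmt_ms = NA_real_, mt_ms = NA_real_, ok = FALSE,
                reason = "onset_after_rt"))
  list(pmt_ms = pmt, mt_ms = mt, ok = TRUE, reason = NA_character_)
}

#' Assign a trial to its analysis class
#'
#' Classes partition all trials: `no_response` (no press before the
#' deadline), `excluded` (invalid or degenerate onset, out-of-bounds epoch,
#' non-positive PMT/MT), `overt_error` / `partial_correct_trial` (wrong-hand
#' press, the latter with a covert correct-hand activation),
#' `partial_error_trial` (correct press with a covert incorrect-hand
#' activation), and `pure_correct`.
#'
#' @param has_response press registered?
#' @param onset_ok onset valid and decomposition retained?
#' @param is_correct responding hand equals correct hand?
#' @param n_partials number of covert activations on the non-responding
#'   channel.
#' @return Trial class string.
#' @export
classify_trial <- function(has_response, onset_ok, is_correct, n_partials) {
  if (!has_response) return("no_response")
  if (!onset_ok) return("excluded")
  if (!is_correct)
    return(if (n_partials > 0) "partial_correct_trial" else "overt_error")
  if (n_partials > 0) return("partial_error_trial")
  "pure_correct"
}

# Full measurement chain for one epoch. Returns a plain list (one trial row)
# plus the covert-activation table; kept lean because it runs once per trial.
process_epoch <- function(epoch, config = run_config()) {
  base <- list(participant = epoch$participant, trial = epoch$trial,
               sat = epoch$sat, lexicality = epoch$lexicality,
               rt_ms = epoch$rt_ms, pmt_ms = NA_real_, mt_ms = NA_real_,
               trial_class = NA_character_,
               partial_error_latency_ms = NA_real_,
               n_partial_activations = 0L,
               onset_valid = NA, exclusion_reason = NA_character_)
  partials <- NULL
  if (isTRUE(epoch$excluded)) {
    base$trial_class <- "excluded"
    base$exclusion_reason <- epoch$exclusion_reason
    return(list(row = base, partials = partials))
  }
  if (is.na(epoch$rt_ms)) {
    base$trial_class <- "no_response"
    return(list(row = base, partials = partials))
  }
  fs <- epoch$sampling_rate
  rt_sample <- round((epoch$rt_ms - epoch$times_ms[1]) * fs / 1000) + 1
  onset <- tryCatch(detect_trial_onset(epoch), error = function(e) NULL)
  if (is.null(onset)) {
    base$trial_class <- "excluded"
    base$exclusion_reason <- "onset_degenerate"
    base$onset_valid <- FALSE
    return(list(row = base, partials = partials))
  }
  thr <- baseline_threshold(epoch, epoch$responding_hand,
                            config$threshold_sd, config$baseline_ms)
  w <- detect_windows(epoch$signal[, epoch$responding_hand], thr, rt_sample,
                      fs, config$merge_gap_ms, config$min_window_ms)
  val <- validate_onset(onset, w, rt_sample, config$onset_tolerance_ms, fs)
  base$onset_valid <- val$valid
  if (!val$valid) {
    base$trial_class <- "excluded"
    base$exclusion_reason <- val$reason
    return(list(row = base, partials = partials))
  }
  dec <- decompose_trial(epoch, onset)
  if (!dec$ok) {
    base$trial_class <- "excluded"
    base$exclusion_reason <- dec$reason
    return(list(row = base, partials = partials))
  }
  base$pmt_ms <- dec$pmt_ms
  base$mt_ms <- dec$mt_ms
  pa <- detect_partial_activations(epoch, config)
  base$n_partial_activations <- nrow(pa)
  if (nrow(pa) > 0) {
    partials <- data.frame(participant = epoch$participant,
                           trial = epoch$trial, sat = epoch$sat,
                           lexicality = epoch$lexicality,
                           rt_ms = epoch$rt_ms,
                           latency_ms = pa$latency_ms,
                           duration_ms = pa$duration_ms,
                           peak_abs = pa$peak_abs, kind = pa$kind,
                           stringsAsFactors = FALSE)
    if (pa$kind[1] == "partial_error")
      base$partial_error_latency_ms <- pa$latency_ms[1]
  }
  base$trial_class <- classify_trial(
    has_response = TRUE, onset_ok = TRUE,
    is_correct = epoch$responding_hand == epoch$correct_hand,
    n_partials = nrow(pa))
  list(row = base, partials = partials)
}

#' Run the detection and decomposition chain over a set of epochs
#'
#' @param epochs list of `trial_epoch` objects (see
#'   [epoch_stimulus_locked()]).
#' @param config a [run_config()].
#' @return List with `trials` (one row per epoch; see
#'   [write_trial_table()] for columns) and `partials` (one row per covert
#'   activation, possibly zero rows).
#' @export
process_epochs <- function(epochs, config = run_config()) {
  rows <- vector("list", length(epochs))
  parts <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    res <- process_epoch(epochs[[i]], config)
    rows[[i]] <- res$row
    parts[[i]] <- res$partials
  }
  pull <- function(name) unlist(lapply(rows, `[[`, name), use.names = FALSE)
  trials <- data.frame(
    participant = pull("participant"), trial = pull("trial"),
    sat = pull("sat"), lexicality = pull("lexicality"),
    rt_ms = pull("rt_ms"), pmt_ms = pull("pmt_ms"), mt_ms = pull("mt_ms"),
    trial_class = pull("trial_class"),
    partial_error_latency_ms = pull("partial_error_latency_ms"),
    n_partial_activations = pull("n_partial_activations"),
    onset_valid = pull("onset_valid"),
    exclusion_reason = pull("exclusion_reason"),
    stringsAsFactors = FALSE)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  partials <- if (length(parts)) do.call(rbind, parts) else
    data.frame(participant = character(0), trial = integer(0),
               sat = character(0), lexicality = character(0),
               rt_ms = numeric(0), latency_ms = numeric(0),
               duration_ms = numeric(0), peak_abs = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
  list(trials = trials, partials = partials)
}
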