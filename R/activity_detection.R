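# Supra-threshold activity windows, onset validation, covert activations.
#
# Rule order is fixed: (1) maximal supra-threshold runs, (2) merge runs
# separated by gaps strictly shorter than the merge gap, (3) discard merged
# windows shorter than the minimum duration, (4) discard windows starting at
# or after the press sample. Windows are half-open [start, end) in 1-based
# sample indices.

#' Baseline-derived activity threshold
#'
#' Threshold = mean(|x|) + `multiplier` * SD(|x|) over the pre-stimulus
#' baseline (default -500 to 0 ms, SD with denominator n - 1).
#'
#' @param epoch a `trial_epoch`.
#' @param channel hand label (`"left"`/`"right"`).
#' @param multiplier SD multiplier (default 3.5).
#' @param baseline_ms half-open baseline span, ms relative to stimulus.
#' @return Amplitude threshold (same units as the signal).
#' @export
baseline_threshold <- function(epoch, channel, multiplier = 3.5,
                               baseline_ms = c(-500, 0)) {
  sel <- epoch$times_ms >= baseline_ms[1] & epoch$times_ms < baseline_ms[2]
  if (!any(sel)) stop("empty baseline period", call. = FALSE)
  a <- abs(epoch$signal[sel, channel])
  mean(a) + multiplier * stats::sd(a)
}

# Core of detect_windows, operating on a logical supra-threshold mask.
# Returns a two-column matrix (start, end), half-open, after the four rules.
detect_windows_mask <- function(mask, rt_sample = NULL, fs = 1000,
                                merge_gap_ms = 25, min_window_ms = 50) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("start", "end"))))
  start <- starts[keep]
  end <- ends[keep] + 1L           # half-open
  if (length(start) > 1) {
    gap_ms <- (start[-1] - end[-length(end)]) * 1000 / fs
    grp <- cumsum(c(0, as.integer(gap_ms >= merge_gap_ms)))
    start <- tapply(start, grp, min)
    end <- tapply(end, grp, max)
  }
  dur_ms <- (end - start) * 1000 / fs
  ok <- dur_ms >= min_window_ms
  if (!is.null(rt_sample) && is.finite(rt_sample))
    ok <- ok & start < rt_sample
  cbind(start = as.integer(start[ok]), end = as.integer(end[ok]))
}

#' Detect EMG activity windows on one channel
#'
#' Applies the run / merge (< `merge_gap_ms`) / minimum-duration
#' (>= `min_window_ms`) / pre-press rules to the rectified signal against a
#' baseline-derived threshold.
#'
#' @param x single-channel amplitude segment.
#' @param threshold amplitude threshold from [baseline_threshold()].
#' @param rt_sample 1-based sample index of the button press; windows
#'   starting at or after it are dropped. `NULL` keeps all windows.
#' @param fs sampling rate, Hz.
#' @param merge_gap_ms gaps strictly shorter than this are merged.
#' @param min_window_ms minimum retained duration.
#' @return `data.frame` with `start`, `end` (half-open, 1-based),
#'   `duration_ms` and `peak_abs`; zero rows when nothing qualifies.
#' @export
detect_windows <- function(x, threshold, rt_sample = NULL, fs = 1000,
                           merge_gap_ms = 25, min_window_ms = 50) {
  w <- detect_windows_mask(abs(x) > threshold, rt_sample, fs,
                           merge_gap_ms, min_window_ms)
  data.frame(start = w[, "start"], end = w[, "end"],
             duration_ms = (w[, "end"] - w[, "start"]) * 1000 / fs,
             peak_abs = if (nrow(w)) vapply(seq_len(nrow(w)), function(i)
               max(abs(x[w[i, "start"]:(w[i, "end"] - 1)])), numeric(1))
             else numeric(0))
}

#' Validate an onset estimate against the activity windows
#'
#' An onset is accepted only when it marks the last window of activity
#' before the button press: at least one retained window must start before
#' the press, and the onset sample must fall within
#' `[start - tolerance, end)` of the last such window. Epochs failing this
#' check are excluded downstream, screening out noise bursts, false starts
#' and drifts that capture the integrated profile.
#'
#' @param onset an `onset_estimate`.
#' @param windows window `data.frame` for the responding channel.
#' @param rt_sample 1-based press sample index.
#' @param tolerance_ms slack before the window start (absorbs the <= 1
#'   sample argmin bias and filter ringing).
#' @param fs sampling rate, Hz.
#' @return List with `valid` (logical) and `reason`
#'   (`"ok"`, `"no_window"`, `"onset_outside_last_window"`).
#' @export
validate_onset <- function(onset, windows, rt_sample, tolerance_ms = 10,
                           fs = 1000) {
  pre <- windows[windows$start < rt_sample, , drop = FALSE]
  if (nrow(pre) == 0) return(list(valid = FALSE, reason = "no_window"))
  last <- pre[nrow(pre), ]
  tol <- round(tolerance_ms * fs / 1000)
  ok <- onset$onset_sample >= last$start - tol &
    onset$onset_sample < last$end
  list(valid = ok,
       reason = if (ok) "ok" else "onset_outside_last_window")
}

#' Detect covert activations on the non-responding channel
#'
#' The same threshold / merge / duration / pre-press rules are applied to
#' the channel of the hand not involved in the final button press. Each
#' retained window yields a covert activation whose onset latency is
#' re-estimated by the integrated-profile detector on a local segment from
#' `partial_pre_ms` before the window start to the window end. Activations
#' are partial errors when the final press was correct and partial corrects
#' when it was an overt error.
#'
#' @param epoch a `trial_epoch` with an overt response.
#' @param config a [run_config()].
#' @param threshold optional precomputed threshold for the channel.
#' @return `data.frame` with `start`, `end`, `duration_ms`, `peak_abs`,
#'   `latency_ms` and `kind`; zero rows when the channel is clean.
#' @export
detect_partial_activations <- function(epoch, config = run_config(),
                                       threshold = NULL) {
  stopifnot(!is.na(epoch$rt_ms))
  hand <- other_hand(epoch$responding_hand)
  fs <- epoch$sampling_rate
  if (is.null(threshold))
    threshold <- baseline_threshold(epoch, hand, config$threshold_sd,
                                    config$baseline_ms)
  x <- epoch$signal[, hand]
  rt_sample <- round((epoch$rt_ms - epoch$times_ms[1]) * fs / 1000) + 1
  w <- detect_windows(x, threshold, rt_sample, fs,
                      config$merge_gap_ms, config$min_window_ms)
  kind <- if (epoch$responding_hand == epoch$correct_hand)
    "partial_error" else "partial_correct"
  if (nrow(w) == 0) {
    w$latency_ms <- numeric(0)
    w$kind <- character(0)
    return(w)
  }
  pre <- round(config$partial_pre_ms * fs / 1000)
  w$latency_ms <- vapply(seq_len(nrow(w)), function(i) {
    s0 <- max(1L, w$start[i] - pre)
    seg <- x[s0:(w$end[i] - 1)]
    idx <- tryCatch(integrated_profile_onset(seg),
                    error = function(e) w$start[i] - s0 + 1L)
    epoch$times_ms[s0 + idx - 1]
  }, numeric(1))
  w$kind <- kind
  w
}
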