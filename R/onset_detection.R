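# Integrated-profile EMG onset detection.
#
# The integrated profile of a segment is the cumulative sum of its rectified
# amplitudes minus the chord joining the first and last cumulative values
# (the integrated profile of a uniform signal). During baseline the profile
# drifts below the chord; once the burst starts it climbs above it, so its
# minimum marks the burst onset. On an ideal noise-free step the minimum
# falls on the last quiescent sample, i.e. one sample before the first
# active one; this <= 1-sample bias is accepted as part of the method.

#' Integrated-profile onset of a single-channel segment
#'
#' Computes `c_i = sum(|x_j|, j <= i)`, the chord
#' `L_i = c_1 + (c_n - c_1) * (i - 1) / (n - 1)`, and returns the index
#' minimizing `c_i - L_i`. Ties are broken toward the earliest index.
#'
#' @param x numeric amplitude segment (length >= 3, not constant in `|x|`).
#' @return Integer sample index (1-based) of the estimated onset.
#' @export
integrated_profile_onset <- function(x) {
  n <- length(x)
  if (n < 3) stop("segment too short for onset detection", call. = FALSE)
  cx <- cumsum(abs(x))
  d <- cx - (cx[1] + (cx[n] - cx[1]) * (seq_len(n) - 1) / (n - 1))
  if (max(abs(d)) <= 1e-10 * max(cx[n], 1))
    stop("degenerate segment: integrated profile is flat (constant |x|)",
         call. = FALSE)
  which.min(d)
}

#' Detect the response-burst onset within an epoch
#'
#' Runs the integrated-profile detector on the responding-hand channel over
#' the full epoch (baseline included) and converts the index to a latency
#' relative to stimulus onset. The validity flag is left unset; it is filled
#' in by [validate_onset()] against the detected activity windows.
#'
#' @param epoch a `trial_epoch` with a registered button press.
#' @return List of class `onset_estimate` with `onset_sample`, `onset_ms`,
#'   `channel` and `valid` (NA until validated), or `NULL` for no-response
#'   trials.
#' @export
detect_trial_onset <- function(epoch) {
  if (is.null(epoch$rt_ms) || is.na(epoch$rt_ms)) return(NULL)
  ch <- epoch$signal[, epoch$responding_hand]
  idx <- integrated_profile_onset(ch)
  structure(list(onset_sample = idx, onset_ms = epoch$times_ms[idx],
                 channel = epoch$responding_hand, valid = NA),
            class = "onset_estimate")
}
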