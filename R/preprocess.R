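# Filtering of the continuous signal and epoch extraction.
#
# Filters run on the continuous recording before epoching, and by default
# forward-backward (zero phase) so that onset latencies are not delayed by
# the filter group delay; the effective magnitude response is then the
# squared single-pass response.

apply_filter_cols <- function(x, b, a, zero_phase) {
  apply(x, 2, function(col) {
    if (zero_phase) signal::filtfilt(b, a, col)
    else as.numeric(signal::filter(b, a, col))
  })
}

filter_recording <- function(recording, b, a, zero_phase) {
  if (inherits(recording, "emg_recording")) {
    recording$signal <- apply_filter_cols(recording$signal, b, a, zero_phase)
    recording
  } else if (is.matrix(recording)) {
    apply_filter_cols(recording, b, a, zero_phase)
  } else {
    y <- apply_filter_cols(matrix(as.numeric(recording)), b, a, zero_phase)
    as.numeric(y)
  }
}

#' High-pass filter a recording
#'
#' Butterworth high-pass (default 10 Hz, order 2) removing DC offset and
#' slow drift. Accepts an [emg_recording()], a matrix (columns = channels)
#' or a numeric vector; for the latter two `sampling_rate` must be given.
#'
#' @param recording signal container (see above).
#' @param cutoff cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order.
#' @param zero_phase forward-backward application (no phase delay).
#' @param sampling_rate Hz, required when `recording` is not an
#'   `emg_recording`.
#' @return Filtered object of the same shape.
#' @export
highpass_filter <- function(recording, cutoff = 10, order = 2,
                            zero_phase = TRUE, sampling_rate = NULL) {
  fs <- if (inherits(recording, "emg_recording"))
    recording$sampling_rate else sampling_rate
  if (is.null(fs)) stop("sampling_rate required", call. = FALSE)
  if (cutoff >= fs / 2)
    stop("high-pass cutoff must be below the Nyquist frequency",
         call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  filter_recording(recording, bf$b, bf$a, zero_phase)
}

# Second-order IIR notch: zeros on the unit circle at +-w0, poles just
# inside at radius r set by the -3 dB bandwidth; gain normalized to 1 at DC.
design_notch <- function(freq, bandwidth, fs) {
  w0 <- 2 * pi * freq / fs
  r <- exp(-pi * bandwidth / fs)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

#' Notch filter a recording
#'
#' Second-order IIR notch (default 50 Hz mains, -3 dB bandwidth 2 Hz).
#' Same calling conventions as [highpass_filter()].
#'
#' @inheritParams highpass_filter
#' @param freq notch center frequency, Hz; must be below Nyquist.
#' @param bandwidth -3 dB bandwidth, Hz.
#' @return Filtered object of the same shape.
#' @export
notch_filter <- function(recording, freq = 50, bandwidth = 2,
                         zero_phase = TRUE, sampling_rate = NULL) {
  fs <- if (inherits(recording, "emg_recording"))
    recording$sampling_rate else sampling_rate
  if (is.null(fs)) stop("sampling_rate required", call. = FALSE)
  if (freq >= fs / 2)
    stop("notch frequency must be below the Nyquist frequency",
         call. = FALSE)
  nf <- design_notch(freq, bandwidth, fs)
  filter_recording(recording, nf$b, nf$a, zero_phase)
}

#' Apply the standard preprocessing chain
#'
#' High-pass then notch, with parameters taken from the configuration.
#'
#' @param recording an [emg_recording()].
#' @param config a [run_config()].
#' @return The filtered recording.
#' @export
preprocess_recording <- function(recording, config = run_config()) {
  recording <- highpass_filter(recording, config$highpass_hz,
                               config$filter_order, config$zero_phase)
  notch_filter(recording, config$notch_hz, config$notch_bw_hz,
               config$zero_phase)
}

new_trial_epoch <- function(signal, times_ms, sampling_rate, event,
                            excluded = FALSE, exclusion_reason = NA_character_) {
  structure(list(signal = signal, times_ms = times_ms,
                 sampling_rate = sampling_rate,
                 rt_ms = event$rt_ms,
                 responding_hand = event$responding_hand,
                 correct_hand = event$correct_hand,
                 sat = event$sat, lexicality = event$lexicality,
                 participant = event$participant, trial = event$trial,
                 excluded = excluded, exclusion_reason = exclusion_reason),
            class = "trial_epoch")
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Each epoch spans from `epoch_pre_ms` before stimulus onset to
#' `post_deadline_ms` past the condition deadline (2500 / 6000 / 1800 ms
#' post-stimulus for neutral / accuracy / speed at the defaults), so the
#' whole EMG burst is contained even on the slowest admissible trials.
#' Epoch channels are re-labelled by hand. Trials whose epoch would overrun
#' the recording are returned flagged as excluded rather than failing the
#' run.
#'
#' @param recording a (filtered) [emg_recording()].
#' @param events validated event table for this recording.
#' @param config a [run_config()].
#' @return A list of `trial_epoch` objects, one per event row.
#' @export
epoch_stimulus_locked <- function(recording, events, config = run_config()) {
  fs <- recording$sampling_rate
  n <- nrow(recording$signal)
  left_col <- hand_column(recording, "left")
  right_col <- hand_column(recording, "right")
  pre <- config$epoch_pre_ms
  lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    post <- epoch_post_ms(ev$sat, config)
    n_samp <- round((pre + post) * fs / 1000)
    first <- round((ev$stimulus_onset_ms - recording$start_time_ms - pre) *
                     fs / 1000) + 1
    times <- seq(-pre, by = 1000 / fs, length.out = n_samp)
    if (first < 1 || first + n_samp - 1 > n)
      return(new_trial_epoch(NULL, times, fs, ev, excluded = TRUE,
                             exclusion_reason = "epoch_out_of_bounds"))
    idx <- first:(first + n_samp - 1)
    sig <- cbind(left = recording$signal[idx, left_col],
                 right = recording$signal[idx, right_col])
    new_trial_epoch(sig, times, fs, ev)
  })
}

#' Extract an onset-locked segment from an epoch
#'
#' Re-references an epoch to an EMG onset latency, returning a fixed-length
#' two-channel segment spanning `window_ms` (default \[-500, 1000\] ms,
#' inclusive endpoints: 1501 samples at 1 kHz). Samples falling outside the
#' source epoch are zero-filled and marked invalid in the returned mask so
#' that curve averaging can ignore them.
#'
#' @param epoch a `trial_epoch`.
#' @param onset_ms onset latency relative to stimulus onset, ms.
#' @param window_ms two-element window around the onset, ms.
#' @return List with `signal` (matrix, columns left/right), `valid`
#'   (logical mask, `FALSE` where padded) and `times_ms` relative to onset.
#' @export
epoch_onset_locked <- function(epoch, onset_ms, window_ms = c(-500, 1000)) {
  if (is.null(onset_ms) || is.na(onset_ms))
    stop("cannot onset-lock: onset latency is missing", call. = FALSE)
  fs <- epoch$sampling_rate
  offs <- seq(round(window_ms[1] * fs / 1000),
              round(window_ms[2] * fs / 1000))
  onset_idx <- round((onset_ms - epoch$times_ms[1]) * fs / 1000) + 1
  src <- onset_idx + offs
  ok <- src >= 1 & src <= nrow(epoch$signal)
  sig <- matrix(0, nrow = length(offs), ncol = 2,
                dimnames = list(NULL, c("left", "right")))
  sig[ok, ] <- epoch$signal[src[ok], , drop = FALSE]
  list(signal = sig, valid = ok, times_ms = offs * 1000 / fs)
}
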