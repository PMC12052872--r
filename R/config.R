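#' @keywords internal
"_PACKAGE"

SAT_LEVELS <- c("neutral", "accuracy", "speed")
LEX_LEVELS <- c("word", "pseudoword")
HAND_LEVELS <- c("left", "right")

TRIAL_CLASSES <- c("pure_correct", "overt_error", "partial_error_trial",
                   "partial_correct_trial", "no_response", "excluded")

`%||%` <- function(a, b) if (is.null(a)) b else a

other_hand <- function(hand) c(left = "right", right = "left")[[hand]]

#' Analysis configuration
#'
#' Bundles every tunable constant of the measurement chain: filter design,
#' per-condition epoch geometry, the activity-window rules (threshold
#' multiplier, merge gap, minimum duration), onset-validation tolerance,
#' quantile count for conditional functions, and the EMG-curve metric
#' parameters (peak-return fraction, slope window).
#'
#' Response deadlines are 1500 ms (neutral), 5000 ms (accuracy) and 800 ms
#' (speed); each condition's epoch runs from `epoch_pre_ms` before stimulus
#' onset to `post_deadline_ms` after its deadline.
#'
#' @param highpass_hz high-pass cutoff in Hz.
#' @param filter_order Butterworth order of the high-pass.
#' @param notch_hz notch (mains) frequency in Hz.
#' @param notch_bw_hz -3 dB bandwidth of the notch in Hz.
#' @param zero_phase apply filters forward-backward (no group delay).
#' @param epoch_pre_ms pre-stimulus span of every epoch, ms.
#' @param post_deadline_ms epoch extension past the response deadline, ms.
#' @param deadline_ms named vector of response deadlines per SAT condition, ms.
#' @param baseline_ms half-open baseline span relative to stimulus onset, ms.
#' @param threshold_sd multiplier of the baseline SD for the activity threshold.
#' @param merge_gap_ms windows separated by gaps strictly shorter than this
#'   are merged, ms.
#' @param min_window_ms merged windows shorter than this are discarded, ms.
#' @param onset_tolerance_ms slack allowed between a detected onset and the
#'   start of the last pre-press activity window, ms.
#' @param n_quantiles number of latency quantile bins (K) for CAF/CIAF.
#' @param curve_window_ms onset-locked window for EMG curves, ms (inclusive).
#' @param return_fraction fraction of the curve peak defining the end of the
#'   amplitude-averaging window.
#' @param slope_window_ms window (inclusive endpoints) for the rising-flank
#'   regression, ms.
#' @param rectify_curves average rectified (TRUE) or signed segments.
#' @param partial_pre_ms lead-in before a covert activity window over which
#'   its onset latency is re-estimated, ms.
#' @param seed optional RNG seed recorded with the configuration.
#' @return A list of class `run_config`.
#' @export
run_config <- function(highpass_hz = 10,
                       filter_order = 2,
                       notch_hz = 50,
                       notch_bw_hz = 2,
                       zero_phase = TRUE,
                       epoch_pre_ms = 500,
                       post_deadline_ms = 1000,
                       deadline_ms = c(neutral = 1500, accuracy = 5000,
                                       speed = 800),
                       baseline_ms = c(-500, 0),
                       threshold_sd = 3.5,
                       merge_gap_ms = 25,
                       min_window_ms = 50,
                       onset_tolerance_ms = 10,
                       n_quantiles = 5,
                       curve_window_ms = c(-500, 1000),
                       return_fraction = 0.30,
                       slope_window_ms = c(0, 30),
                       rectify_curves = TRUE,
                       partial_pre_ms = 50,
                       seed = NULL) {
  cfg <- list(highpass_hz = highpass_hz, filter_order = filter_order,
              notch_hz = notch_hz, notch_bw_hz = notch_bw_hz,
              zero_phase = zero_phase,
              epoch_pre_ms = epoch_pre_ms,
              post_deadline_ms = post_deadline_ms,
              deadline_ms = deadline_ms, baseline_ms = baseline_ms,
              threshold_sd = threshold_sd, merge_gap_ms = merge_gap_ms,
              min_window_ms = min_window_ms,
              onset_tolerance_ms = onset_tolerance_ms,
              n_quantiles = n_quantiles, curve_window_ms = curve_window_ms,
              return_fraction = return_fraction,
              slope_window_ms = slope_window_ms,
              rectify_curves = rectify_curves,
              partial_pre_ms = partial_pre_ms, seed = seed)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  durs <- c(cfg$epoch_pre_ms, cfg$post_deadline_ms, cfg$deadline_ms,
            cfg$merge_gap_ms, cfg$min_window_ms)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("run_config: all durations must be positive", call. = FALSE)
  if (cfg$n_quantiles < 2)
    stop("run_config: n_quantiles must be >= 2", call. = FALSE)
  if (cfg$return_fraction <= 0 || cfg$return_fraction >= 1)
    stop("run_config: return_fraction must lie in (0, 1)", call. = FALSE)
  if (!all(SAT_LEVELS %in% names(cfg$deadline_ms)))
    stop("run_config: deadline_ms must name every SAT condition",
         call. = FALSE)
  invisible(cfg)
}

#' Epoch span for a SAT condition
#'
#' @param sat condition label(s).
#' @param config a [run_config()].
#' @return Post-stimulus epoch length in ms (deadline + post-deadline span).
#' @export
epoch_post_ms <- function(sat, config = run_config()) {
  unname(config$deadline_ms[sat] + config$post_deadline_ms)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param config a [run_config()].
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$deadline_ms <- unlist(raw$deadline_ms)
  raw$baseline_ms <- unlist(raw$baseline_ms)
  raw$curve_window_ms <- unlist(raw$curve_window_ms)
  raw$slope_window_ms <- unlist(raw$slope_window_ms)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$deadline_ms <- as.list(out$deadline_ms)  # keep condition names in YAML
  yaml::write_yaml(out, path)
  invisible(path)
}
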