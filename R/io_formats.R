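# Plain-text interchange: recordings as TSV (+ JSON sidecar carrying the
# sampling rate and channel->hand map), events and trial-level outputs as TSV.

#' Two-channel continuous EMG recording
#'
#' Container for a continuous surface-EMG recording with one channel per
#' response hand. Amplitudes are carried through unchanged and assumed to be
#' microvolts; the pipeline is scale-invariant except for the reported
#' amplitude metrics.
#'
#' @param signal numeric matrix (samples x channels) with channel labels as
#'   column names.
#' @param sampling_rate sampling rate in Hz (positive).
#' @param channel_map named character vector mapping channel label to hand
#'   (`"left"`/`"right"`).
#' @param start_time_ms time of sample 1 in ms.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, sampling_rate,
                          channel_map = c(emg_left = "left",
                                          emg_right = "right"),
                          start_time_ms = 0) {
  signal <- as.matrix(signal)
  if (is.null(colnames(signal)))
    colnames(signal) <- names(channel_map)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar", call. = FALSE)
  keep <- intersect(colnames(signal), names(channel_map))
  if (length(keep) != 2)
    stop("recording must resolve to exactly two EMG channels, got ",
         length(keep), call. = FALSE)
  signal <- signal[, keep, drop = FALSE]
  channel_map <- channel_map[keep]
  if (!all(channel_map %in% HAND_LEVELS) ||
      anyDuplicated(channel_map))
    stop("channel_map must assign the two channels to distinct hands",
         call. = FALSE)
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 channel_map = channel_map, start_time_ms = start_time_ms),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              nrow(x$signal) / x$sampling_rate))
  cat("  channels:",
      paste(sprintf("%s->%s", names(x$channel_map), x$channel_map),
            collapse = ", "), "\n")
  invisible(x)
}

# column index of the channel recorded from `hand`
hand_column <- function(recording, hand) {
  lab <- names(recording$channel_map)[recording$channel_map == hand]
  match(lab, colnames(recording$signal))
}

sidecar_path <- function(path) sub("\\.tsv(\\.gz)?$", ".json", path)

#' Read a continuous recording (TSV + JSON sidecar)
#'
#' Expects `<name>.tsv` (optionally gzip-compressed) with a `t_ms` column and
#' one column per EMG channel, plus `<name>.json` carrying
#' `sampling_rate_hz` and `channel_map`.
#'
#' @param path path to the TSV file.
#' @param sidecar path to the JSON sidecar; derived from `path` by default.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stop("recording file not found: ", path,
                               call. = FALSE)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar,
                                  call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz))
    stop("sidecar is missing sampling_rate_hz", call. = FALSE)
  if (is.null(meta$channel_map))
    stop("sidecar is missing channel_map", call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE)
  ch <- setdiff(colnames(tab), "t_ms")
  cmap <- unlist(meta$channel_map)
  emg_recording(as.matrix(tab[, ch, drop = FALSE]),
                sampling_rate = meta$sampling_rate_hz,
                channel_map = cmap,
                start_time_ms = if ("t_ms" %in% colnames(tab))
                  tab$t_ms[1] else meta$start_time_ms %||% 0)
}

#' Write a continuous recording (TSV + JSON sidecar)
#'
#' @param recording an [emg_recording()].
#' @param path output TSV path (`.tsv` or `.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  n <- nrow(recording$signal)
  t_ms <- recording$start_time_ms +
    (seq_len(n) - 1) * 1000 / recording$sampling_rate
  tab <- data.frame(t_ms = t_ms, recording$signal, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(sampling_rate_hz = recording$sampling_rate,
         channel_map = as.list(recording$channel_map),
         start_time_ms = recording$start_time_ms,
         units = "microvolts"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

EVENT_COLUMNS <- c("participant", "trial", "stimulus_onset_ms", "rt_ms",
                   "responding_hand", "correct_hand", "sat", "lexicality")

#' Read and validate a trial event table
#'
#' Tab-separated, one row per trial, columns `participant, trial,
#' stimulus_onset_ms, rt_ms, responding_hand, correct_hand, sat, lexicality`.
#' No-response trials carry `NA` (or `n/a`) in `rt_ms` and `responding_hand`.
#'
#' @param path path to `events.tsv`.
#' @param config a [run_config()] supplying the per-condition deadlines.
#' @return A validated `data.frame`.
#' @export
read_events <- function(path, config = run_config()) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  ev <- utils::read.delim(path, na.strings = c("NA", "n/a", ""),
                          stringsAsFactors = FALSE)
  validate_events(ev, config)
}

#' @rdname read_events
#' @param events an event `data.frame`.
#' @export
validate_events <- function(events, config = run_config()) {
  missing <- setdiff(EVENT_COLUMNS, colnames(events))
  if (length(missing))
    stop("events table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad_sat <- setdiff(unique(events$sat), SAT_LEVELS)
  if (length(bad_sat))
    stop("unknown SAT condition label(s): ", paste(bad_sat, collapse = ", "),
         call. = FALSE)
  bad_lex <- setdiff(unique(events$lexicality), LEX_LEVELS)
  if (length(bad_lex))
    stop("unknown lexicality label(s): ", paste(bad_lex, collapse = ", "),
         call. = FALSE)
  if (!all(events$correct_hand %in% HAND_LEVELS))
    stop("correct_hand must be left/right", call. = FALSE)
  if (anyDuplicated(events[, c("participant", "trial")]))
    stop("trial index must be unique within participant", call. = FALSE)
  no_rt <- is.na(events$rt_ms)
  no_hand <- is.na(events$responding_hand)
  if (any(no_rt != no_hand))
    stop("responding_hand must be missing exactly on no-response trials",
         call. = FALSE)
  if (!all(events$responding_hand[!no_hand] %in% HAND_LEVELS))
    stop("responding_hand must be left/right", call. = FALSE)
  if (any(events$rt_ms[!no_rt] < 0))
    stop("negative rt_ms", call. = FALSE)
  over <- !no_rt & events$rt_ms > config$deadline_ms[events$sat]
  if (any(over))
    stop("rt_ms exceeds the condition deadline for trial(s): ",
         paste(utils::head(events$trial[over], 5), collapse = ", "),
         call. = FALSE)
  events
}

#' Write an event table
#' @param events event `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write_tsv(events[, EVENT_COLUMNS], path)
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TRIAL_COLUMNS <- c("participant", "trial", "sat", "lexicality", "rt_ms",
                   "pmt_ms", "mt_ms", "trial_class",
                   "partial_error_latency_ms", "n_partial_activations",
                   "onset_valid", "exclusion_reason")

#' Write / read the trial-level decomposition table
#'
#' One row per trial with the RT decomposition (`pmt_ms`, `mt_ms`), the
#' analysis class, the latency of the first covert incorrect activation (if
#' any), and validity flags. Column order is stable; missing values are
#' written as `NA`.
#'
#' @param trials trial `data.frame` as produced by [process_epochs()].
#' @param path output path.
#' @return `path` invisibly (`write_trial_table`), or the table
#'   (`read_trial_table`).
#' @export
write_trial_table <- function(trials, path) {
  if (NROW(trials) == 0) stop("empty trial collection", call. = FALSE)
  write_tsv(trials[, TRIAL_COLUMNS], path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.delim(path, na.strings = c("NA", "n/a", ""),
                           stringsAsFactors = FALSE)
  tab$onset_valid <- as.logical(tab$onset_valid)
  tab
}
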