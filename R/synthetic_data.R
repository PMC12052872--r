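# Synthetic two-channel EMG with known ground truth.
#
# The generator emulates a 3 (SAT: neutral / accuracy / speed) x 2
# (lexicality: word / pseudoword) two-choice design at 1000 Hz: quiescent
# Gaussian baseline on both channels, a response-locked burst (smooth
# rise-plateau-decay envelope over a Gaussian noise carrier) on the
# responding hand, covert short bursts on the other hand for partial
# errors / partial corrects, overt errors with a fast-guess latency
# mixture, and no-response trials when the drawn RT misses the condition
# deadline. Premotor and motor time are drawn from shifted log-normal
# distributions (positive support, right skew) with additive condition
# effects, crossed participant and matched-item-pair random components.

#' Generator specification
#'
#' Defaults pattern the latency structure on the fixed-effect estimates of
#' the study design this package targets: premotor time (PMT) base 524.27
#' ms with +61.64 for pseudowords, +172.41 under accuracy and -94.87 under
#' speed instructions (interactions +29.71 / -25.06); motor time (MT) base
#' 132.59 ms with +5.94 / +23.07 / -24.37 and no lexicality-by-SAT
#' interaction. Partial errors are injected on 5% of correct-response
#' trials and partial corrects on 15% of overt-error trials (~1% of
#' epochs); response deadlines are 1500 / 5000 / 800 ms.
#'
#' @param n_participants simulated participants.
#' @param trials_per_cell trials per SAT-by-lexicality cell and participant.
#' @param sampling_rate Hz.
#' @param noise_sd baseline white-noise SD, microvolts.
#' @param burst_snr burst carrier RMS as a multiple of `noise_sd`.
#' @param burst_gain absolute carrier SD of the response burst; default
#'   `noise_sd * burst_snr`.
#' @param rise_ms,decay_ms,plateau_extra_ms envelope shape: raised-cosine
#'   rise, plateau lasting until `MT + plateau_extra_ms` after onset,
#'   raised-cosine decay.
#' @param pmt_base,pmt_effects,mt_base,mt_effects condition means, ms:
#'   named effects `lex`, `acc`, `speed`, `lex_acc`, `lex_speed`
#'   (treatment coding against neutral / word).
#' @param pmt_subj_sd,mt_subj_sd participant random-intercept SDs, ms.
#' @param pmt_item_sd SD of the matched-item-pair difficulty component
#'   shared between a word and its paired pseudoword trial, ms.
#' @param pmt_trial_sd,mt_trial_sd residual trial-level SDs, ms.
#' @param pmt_skew,mt_skew log-scale SD (shape) of the skewed components.
#' @param error_prob per-SAT overt-error probability.
#' @param fast_error_weight per-SAT share of overt errors drawn from the
#'   fast-guess mixture component.
#' @param fast_error_shift_ms PMT reduction of fast guesses, ms.
#' @param partial_error_prob covert incorrect-hand activation probability
#'   on correct-response trials.
#' @param partial_correct_prob covert correct-hand activation probability
#'   on overt-error trials.
#' @param partial_amplitude_fraction covert-burst carrier SD relative to
#'   the response burst.
#' @param partial_duration_ms covert-burst envelope duration, ms.
#' @param partial_lead_ms_range the covert onset precedes the PMT by a
#'   uniform draw from this range, ms.
#' @param deadline_ms per-SAT response deadlines, ms.
#' @param epoch_pre_ms,post_deadline_ms epoch geometry (must match the
#'   analysis [run_config()]).
#' @param intertrial_gap_ms quiescent gap between consecutive trial
#'   segments in the continuous recording, ms.
#' @param min_pmt_ms,min_mt_ms hard floors for the drawn latencies, ms.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_participants = 8,
                           trials_per_cell = 20,
                           sampling_rate = 1000,
                           noise_sd = 2,
                           burst_snr = 25,
                           burst_gain = NULL,
                           rise_ms = 30, decay_ms = 80,
                           plateau_extra_ms = 20,
                           pmt_base = 524.27,
                           pmt_effects = c(lex = 61.64, acc = 172.41,
                                           speed = -94.87, lex_acc = 29.71,
                                           lex_speed = -25.06),
                           mt_base = 132.59,
                           mt_effects = c(lex = 5.94, acc = 23.07,
                                          speed = -24.37, lex_acc = 0,
                                          lex_speed = 0),
                           pmt_subj_sd = 60, mt_subj_sd = 18,
                           pmt_item_sd = 70,
                           pmt_trial_sd = 20, mt_trial_sd = 22,
                           pmt_skew = 0.55, mt_skew = 0.5,
                           error_prob = c(neutral = 0.06, accuracy = 0.03,
                                          speed = 0.10),
                           fast_error_weight = c(neutral = 0.05,
                                                 accuracy = 0,
                                                 speed = 0.5),
                           fast_error_shift_ms = 200,
                           partial_error_prob = 0.05,
                           partial_correct_prob = 0.15,
                           partial_amplitude_fraction = 0.7,
                           partial_duration_ms = 120,
                           partial_lead_ms_range = c(60, 250),
                           deadline_ms = c(neutral = 1500, accuracy = 5000,
                                           speed = 800),
                           epoch_pre_ms = 500, post_deadline_ms = 1000,
                           intertrial_gap_ms = 500,
                           min_pmt_ms = 120, min_mt_ms = 60) {
  spec <- as.list(environment())
  spec$burst_gain <- burst_gain %||% (noise_sd * burst_snr)
  probs <- c(spec$error_prob, spec$fast_error_weight,
             spec$partial_error_prob, spec$partial_correct_prob)
  if (any(probs < 0 | probs > 1))
    stop("generator_spec: probabilities must lie in [0, 1]", call. = FALSE)
  if (spec$pmt_base <= 0 || spec$mt_base <= 0)
    stop("generator_spec: latency means must be positive", call. = FALSE)
  if (!all(SAT_LEVELS %in% names(spec$deadline_ms)))
    stop("generator_spec: deadline_ms must name every SAT condition",
         call. = FALSE)
  class(spec) <- "generator_spec"
  spec
}

# mean-zero log-normal draw: right-skewed with the requested SD
rlnorm_centered <- function(n, sd, skew) {
  if (sd == 0) return(rep(0, n))
  m <- sd / sqrt(exp(skew^2) - 1)
  stats::rlnorm(n, log(m) - skew^2 / 2, skew) - m
}

cell_mean <- function(base, eff, sat, lex) {
  base +
    (lex == "pseudoword") * eff[["lex"]] +
    (sat == "accuracy") * eff[["acc"]] +
    (sat == "speed") * eff[["speed"]] +
    (lex == "pseudoword") * (sat == "accuracy") * eff[["lex_acc"]] +
    (lex == "pseudoword") * (sat == "speed") * eff[["lex_speed"]]
}

# Draw the latent truth for one trial. `item_resid` is the matched-pair
# difficulty component shared between the word and pseudoword trial of a
# pair; `subj` carries the participant intercepts.
sample_trial_truth <- function(spec, sat, lexicality,
                               subj = c(pmt = 0, mt = 0),
                               item_resid = NULL) {
  if (is.null(item_resid))
    item_resid <- rlnorm_centered(1, spec$pmt_item_sd, spec$pmt_skew)
  pmt <- cell_mean(spec$pmt_base, spec$pmt_effects, sat, lexicality) +
    subj[["pmt"]] + item_resid + stats::rnorm(1, 0, spec$pmt_trial_sd)
  mt <- cell_mean(spec$mt_base, spec$mt_effects, sat, lexicality) +
    subj[["mt"]] + rlnorm_centered(1, spec$mt_trial_sd, spec$mt_skew)
  pmt <- max(pmt, spec$min_pmt_ms)
  mt <- max(mt, spec$min_mt_ms)
  is_error <- stats::runif(1) < spec$error_prob[[sat]]
  fast <- is_error && stats::runif(1) < spec$fast_error_weight[[sat]]
  if (fast) pmt <- max(spec$min_pmt_ms, pmt - spec$fast_error_shift_ms)
  rt <- pmt + mt
  no_response <- rt > spec$deadline_ms[[sat]]
  partial <- NA_character_
  partial_latency <- NA_real_
  if (!no_response) {
    if (!is_error && stats::runif(1) < spec$partial_error_prob)
      partial <- "partial_error"
    if (is_error && stats::runif(1) < spec$partial_correct_prob)
      partial <- "partial_correct"
    if (!is.na(partial))
      partial_latency <- max(80, pmt - stats::runif(
        1, spec$partial_lead_ms_range[1], spec$partial_lead_ms_range[2]))
  }
  list(pmt = pmt, mt = mt, rt = rt, is_error = is_error, fast = fast,
       no_response = no_response, partial = partial,
       partial_latency = partial_latency, item_resid = item_resid)
}

burst_envelope <- function(total_ms, spec, fs) {
  rise_n <- max(1, round(spec$rise_ms * fs / 1000))
  decay_n <- max(1, round(spec$decay_ms * fs / 1000))
  plat_n <- max(0, round(total_ms * fs / 1000) - rise_n)
  c((1 - cos(pi * seq_len(rise_n) / rise_n)) / 2,
    rep(1, plat_n),
    (1 + cos(pi * seq_len(decay_n) / decay_n)) / 2)
}

partial_envelope <- function(duration_ms, fs) {
  n <- max(3, round(duration_ms * fs / 1000))
  edge <- max(1, round(20 * fs / 1000))
  edge <- min(edge, floor(n / 3))
  c((1 - cos(pi * seq_len(edge) / edge)) / 2,
    rep(1, n - 2 * edge),
    (1 + cos(pi * seq_len(edge) / edge)) / 2)
}

# One trial's burst contributions as (channel, start sample, values)
# triplets; the caller adds them into its signal matrix in place, which
# avoids copying multi-minute recordings once per trial.
trial_bursts <- function(stim_sample, truth, responding_hand, other, spec) {
  fs <- spec$sampling_rate
  if (truth$no_response) return(list())
  env <- burst_envelope(truth$mt + spec$plateau_extra_ms, spec, fs)
  out <- list(list(col = responding_hand,
                   at = stim_sample + round(truth$pmt * fs / 1000),
                   values = env * stats::rnorm(length(env), 0,
                                               spec$burst_gain)))
  if (!is.na(truth$partial)) {
    penv <- partial_envelope(spec$partial_duration_ms, fs)
    out[[2]] <- list(col = other,
                     at = stim_sample + round(truth$partial_latency *
                                                fs / 1000),
                     values = penv * stats::rnorm(
                       length(penv), 0,
                       spec$partial_amplitude_fraction * spec$burst_gain))
  }
  out
}

paint_trial <- function(signal, stim_sample, truth, responding_hand,
                        other, spec) {
  for (b in trial_bursts(stim_sample, truth, responding_hand, other,
                         spec)) {
    idx <- b$at + seq_along(b$values) - 1
    ok <- idx >= 1 & idx <= nrow(signal)
    signal[idx[ok], b$col] <- signal[idx[ok], b$col] + b$values[ok]
  }
  signal
}

#' Generate a single synthetic trial
#'
#' Returns an epoch-length two-channel signal (stimulus at
#' `epoch_pre_ms`), the corresponding event row and the ground-truth row.
#' Mostly useful for unit tests; [generate_dataset()] builds continuous
#' recordings.
#'
#' @param spec a [generator_spec()].
#' @param sat,lexicality condition labels.
#' @param correct_hand hand mapped to the correct response.
#' @param participant,trial identifiers copied into the rows.
#' @return List with `signal`, `times_ms` (stimulus-locked), `event` and
#'   `truth` (single-row data.frames).
#' @export
generate_trial <- function(spec, sat, lexicality, correct_hand = "right",
                           participant = "P01", trial = 1L) {
  fs <- spec$sampling_rate
  post <- spec$deadline_ms[[sat]] + spec$post_deadline_ms
  n <- round((spec$epoch_pre_ms + post) * fs / 1000)
  truth <- sample_trial_truth(spec, sat, lexicality)
  responding <- if (truth$no_response) NA_character_
  else if (truth$is_error) other_hand(correct_hand) else correct_hand
  signal <- matrix(stats::rnorm(2 * n, 0, spec$noise_sd), ncol = 2,
                   dimnames = list(NULL, c("left", "right")))
  stim_sample <- round(spec$epoch_pre_ms * fs / 1000) + 1
  if (!truth$no_response)
    signal <- paint_trial(signal, stim_sample, truth, responding,
                          other_hand(responding), spec)
  event <- data.frame(participant = participant, trial = trial,
                      stimulus_onset_ms = spec$epoch_pre_ms,
                      rt_ms = if (truth$no_response) NA_real_ else truth$rt,
                      responding_hand = responding,
                      correct_hand = correct_hand,
                      sat = sat, lexicality = lexicality,
                      stringsAsFactors = FALSE)
  truth_row <- data.frame(participant = participant, trial = trial,
                          sat = sat, lexicality = lexicality,
                          pmt_ms = truth$pmt, mt_ms = truth$mt,
                          rt_ms = truth$rt,
                          onset_sample = stim_sample +
                            round(truth$pmt * fs / 1000),
                          is_error = truth$is_error, fast = truth$fast,
                          no_response = truth$no_response,
                          partial_kind = truth$partial,
                          partial_latency_ms = truth$partial_latency,
                          stringsAsFactors = FALSE)
  list(signal = signal,
       times_ms = seq(-spec$epoch_pre_ms, by = 1000 / fs, length.out = n),
       event = event, truth = truth_row)
}

# trial schedule for one participant: SAT blocks in fixed order, word /
# pseudoword pairs sharing an item component, stimulus-response mapping
# reversed halfway through each block, order shuffled within each half.
participant_schedule <- function(spec) {
  sched <- do.call(rbind, lapply(SAT_LEVELS, function(sat) {
    pairs <- seq_len(spec$trials_per_cell)
    half <- ceiling(spec$trials_per_cell / 2)
    d <- expand.grid(lexicality = LEX_LEVELS, pair = pairs,
                     stringsAsFactors = FALSE)
    d$sat <- sat
    d$correct_hand <- ifelse(xor(d$pair <= half,
                                 d$lexicality == "word"),
                             "left", "right")
    within_half <- ifelse(d$pair <= half, 1L, 2L)
    idx <- unlist(lapply(split(seq_len(nrow(d)), within_half), sample))
    d[idx, ]
  }))
  sched$trial <- seq_len(nrow(sched))
  rownames(sched) <- NULL
  sched
}

#' Generate a synthetic dataset
#'
#' Builds, per participant, a continuous two-channel recording (trial
#' segments separated by quiescent gaps), the event table and the
#' ground-truth table. With a fixed seed the output is fully deterministic.
#'
#' @param spec a [generator_spec()].
#' @param seed optional RNG seed set before generation.
#' @param dir optional output directory; when given, writes
#'   `recording_<id>.tsv` + sidecars, `events.tsv` and `truth.tsv`.
#' @param participants indices of the participants to generate (defaults
#'   to all); useful for streaming large simulations one participant at a
#'   time.
#' @return List with `recordings` (named list of [emg_recording()]),
#'   `events`, `truth` and `spec`.
#' @export
generate_dataset <- function(spec = generator_spec(), seed = NULL,
                             dir = NULL,
                             participants = seq_len(spec$n_participants)) {
  if (!is.null(seed)) set.seed(seed)
  fs <- spec$sampling_rate
  pre_n <- round(spec$epoch_pre_ms * fs / 1000)
  gap_n <- round(spec$intertrial_gap_ms * fs / 1000)
  recordings <- list()
  events <- list()
  truths <- list()
  for (p in participants) {
    pid <- sprintf("P%02d", p)
    subj <- c(pmt = stats::rnorm(1, 0, spec$pmt_subj_sd),
              mt = stats::rnorm(1, 0, spec$mt_subj_sd))
    sched <- participant_schedule(spec)
    # shared matched-pair difficulty components
    items <- lapply(SAT_LEVELS, function(s)
      rlnorm_centered(spec$trials_per_cell, spec$pmt_item_sd,
                      spec$pmt_skew))
    names(items) <- SAT_LEVELS
    seg_n <- round((spec$epoch_pre_ms + spec$deadline_ms[sched$sat] +
                      spec$post_deadline_ms) * fs / 1000) + gap_n
    total <- sum(seg_n) + gap_n
    signal <- matrix(stats::rnorm(2 * total, 0, spec$noise_sd), ncol = 2,
                     dimnames = list(NULL, c("left", "right")))
    pointer <- gap_n
    ev <- vector("list", nrow(sched))
    tru <- vector("list", nrow(sched))
    for (i in seq_len(nrow(sched))) {
      row <- sched[i, ]
      truth <- sample_trial_truth(spec, row$sat, row$lexicality, subj,
                                  items[[row$sat]][row$pair])
      stim_sample <- pointer + pre_n + 1
      responding <- if (truth$no_response) NA_character_
      else if (truth$is_error) other_hand(row$correct_hand)
      else row$correct_hand
      if (!truth$no_response) {
        for (b in trial_bursts(stim_sample, truth, responding,
                               other_hand(responding), spec)) {
          idx <- b$at + seq_along(b$values) - 1
          signal[idx, b$col] <- signal[idx, b$col] + b$values
        }
      }
      stim_ms <- (stim_sample - 1) * 1000 / fs
      ev[[i]] <- list(participant = pid, trial = row$trial,
                      stimulus_onset_ms = stim_ms,
                      rt_ms = if (truth$no_response) NA_real_
                      else truth$rt,
                      responding_hand = responding,
                      correct_hand = row$correct_hand,
                      sat = row$sat, lexicality = row$lexicality)
      tru[[i]] <- list(participant = pid, trial = row$trial,
                       sat = row$sat, lexicality = row$lexicality,
                       pmt_ms = truth$pmt, mt_ms = truth$mt,
                       rt_ms = truth$rt,
                       onset_sample = stim_sample +
                         round(truth$pmt * fs / 1000),
                       is_error = truth$is_error, fast = truth$fast,
                       no_response = truth$no_response,
                       partial_kind = truth$partial %||% NA_character_,
                       partial_latency_ms = truth$partial_latency)
      pointer <- pointer + seg_n[i]
    }
    recordings[[pid]] <- emg_recording(
      signal, fs, channel_map = c(left = "left", right = "right"))
    events[[pid]] <- rbindlist_plain(ev)
    truths[[pid]] <- rbindlist_plain(tru)
  }
  events <- do.call(rbind, events)
  truth <- do.call(rbind, truths)
  rownames(events) <- rownames(truth) <- NULL
  out <- list(recordings = recordings, events = events, truth = truth,
              spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(recordings))
      write_recording(recordings[[pid]],
                      file.path(dir, paste0("recording_", pid, ".tsv")))
    write_events(events, file.path(dir, "events.tsv"))
    write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  out
}

# fast rbind of homogeneous scalar lists
rbindlist_plain <- function(rows) {
  nm <- names(rows[[1]])
  cols <- lapply(nm, function(f)
    unlist(lapply(rows, `[[`, f), use.names = FALSE))
  names(cols) <- nm
  as.data.frame(cols, stringsAsFactors = FALSE)
}
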