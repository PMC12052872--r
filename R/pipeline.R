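# End-to-end orchestration: filter -> epoch -> detect -> decompose ->
# summarize, with a manifest of trial-class counts and exclusions.

pipeline_one_recording <- function(recording, events, config,
                                   compute_curves = TRUE) {
  rec <- preprocess_recording(recording, config)
  epochs <- epoch_stimulus_locked(rec, events, config)
  res <- process_epochs(epochs, config)
  curves <- NULL
  if (compute_curves && any(res$trials$trial_class == "pure_correct"))
    curves <- participant_curves(epochs, res$trials, config)
  list(trials = res$trials, partials = res$partials, curves = curves)
}

#' Run the full measurement pipeline
#'
#' Filters each continuous recording, cuts stimulus-locked epochs, runs
#' onset and activity detection, decomposes RTs, classifies trials, and
#' derives the conditional functions, descriptive summary and EMG-curve
#' metrics. Deterministic given inputs and configuration.
#'
#' @param recordings named list of [emg_recording()] objects (names =
#'   participant ids), or a character vector of recording TSV paths named
#'   by participant.
#' @param events validated event table covering all participants, or a
#'   path to `events.tsv`.
#' @param config a [run_config()].
#' @param out_dir optional output directory for `trials.tsv`,
#'   `partials.tsv`, `caf.tsv`, `ciaf.tsv`, `summary.tsv`, `curves.tsv`,
#'   `model_ready.tsv` and `manifest.json`.
#' @param compute_curves compute EMG-curve metrics (skip to save time).
#' @return List with `trials`, `partials`, `caf`, `ciaf`, `summary`,
#'   `curves` and `manifest`.
#' @export
run_pipeline <- function(recordings, events, config = run_config(),
                         out_dir = NULL, compute_curves = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  input_hashes <- NULL
  if (is.character(recordings)) {
    input_hashes <- unname(tools::md5sum(recordings))
    recordings <- stats::setNames(lapply(recordings, read_recording),
                                  names(recordings))
  }
  if (is.character(events)) events <- read_events(events, config)
  events <- validate_events(events, config)
  trials <- list(); partials <- list(); curves <- list()
  timings <- c()
  for (pid in names(recordings)) {
    tp <- proc.time()[["elapsed"]]
    ev <- events[events$participant == pid, , drop = FALSE]
    res <- pipeline_one_recording(recordings[[pid]], ev, config,
                                  compute_curves)
    trials[[pid]] <- res$trials
    partials[[pid]] <- res$partials
    curves[[pid]] <- res$curves
    timings[pid] <- proc.time()[["elapsed"]] - tp
  }
  trials <- do.call(rbind, trials)
  partials <- do.call(rbind, partials)
  curves <- if (compute_curves) do.call(rbind, curves)
  rownames(trials) <- rownames(partials) <- NULL
  caf_tab <- caf(trials, config$n_quantiles)
  ciaf_tab <- ciaf(trials, partials, config$n_quantiles)
  summary_tab <- descriptive_summary(trials)
  class_counts <- table(factor(trials$trial_class, TRIAL_CLASSES))
  manifest <- list(
    n_trials = nrow(trials),
    class_counts = as.list(class_counts),
    excluded_epoch_proportion =
      unname(class_counts[["excluded"]] / nrow(trials)),
    per_participant_seconds = as.list(round(timings, 3)),
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3),
    software = paste0("emgchrono ",
                      as.character(utils::packageVersion("emgchrono"))),
    input_hashes = input_hashes,
    config = unclass(config))
  stopifnot(sum(unlist(manifest$class_counts)) == manifest$n_trials)
  out <- list(trials = trials, partials = partials, caf = caf_tab,
              ciaf = ciaf_tab, summary = summary_tab, curves = curves,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(trials, file.path(out_dir, "trials.tsv"))
    write_tsv(partials, file.path(out_dir, "partials.tsv"))
    write_tsv(caf_tab, file.path(out_dir, "caf.tsv"))
    write_tsv(ciaf_tab, file.path(out_dir, "ciaf.tsv"))
    write_tsv(summary_tab, file.path(out_dir, "summary.tsv"))
    write_tsv(model_ready(rbind(caf_tab, ciaf_tab)),
              file.path(out_dir, "model_ready.tsv"))
    if (!is.null(curves)) write_tsv(curves, file.path(out_dir, "curves.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Simulate-and-measure parameter-recovery experiment
#'
#' Streams participants one at a time: generates each synthetic recording,
#' runs the measurement pipeline on it, and keeps only the trial-level
#' table, covert activations and ground truth, so arbitrarily large
#' simulations fit in memory.
#'
#' @param spec a [generator_spec()].
#' @param seed base RNG seed; participant `p` uses `seed + p`.
#' @param config a [run_config()]; deadlines and epoch geometry should
#'   match the generator's.
#' @param compute_curves forward to [run_pipeline()]'s per-participant
#'   processing (off by default for speed).
#' @return List with `trials`, `partials` and `truth` tables.
#' @export
recovery_experiment <- function(spec, seed = 1, config = run_config(),
                                compute_curves = FALSE) {
  trials <- list(); partials <- list(); truth <- list()
  for (p in seq_len(spec$n_participants)) {
    ds <- generate_dataset(spec, seed = seed + p, participants = p)
    res <- pipeline_one_recording(ds$recordings[[1]], ds$events, config,
                                  compute_curves)
    pid <- names(ds$recordings)[1]
    trials[[pid]] <- res$trials
    partials[[pid]] <- res$partials
    truth[[pid]] <- ds$truth
  }
  out <- list(trials = do.call(rbind, trials),
              partials = do.call(rbind, partials),
              truth = do.call(rbind, truth))
  rownames(out$trials) <- rownames(out$partials) <- rownames(out$truth) <-
    NULL
  out
}
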