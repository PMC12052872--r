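# Onset-locked EMG curves and their shape metrics.
#
# Curves are per-sample means of rectified onset-locked segments (signed
# averaging would cancel across motor-unit phase); padded samples are
# excluded via the validity masks. Two metrics summarize burst shape: the
# mean amplitude from onset until the falling flank returns to a fixed
# fraction of the absolute peak, and the OLS slope of the rising flank over
# a short post-onset window.

#' Average onset-locked segments into an EMG curve
#'
#' @param segments numeric matrix, one onset-locked segment per row.
#' @param valid logical matrix of the same shape; `FALSE` marks padded
#'   samples, which are ignored in the per-sample mean.
#' @param rectify average rectified amplitudes (default) or signed values.
#' @return List with `curve` (per-sample mean; `NA` where no segment
#'   contributes), `n_epochs` and `n_contributing` per sample.
#' @export
average_curve <- function(segments, valid = NULL, rectify = TRUE) {
  segments <- rbind(segments)
  if (nrow(segments) == 0) stop("no segments to average", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(segments), ncol(segments))
  valid <- rbind(valid)
  stopifnot(identical(dim(segments), dim(valid)))
  a <- if (rectify) abs(segments) else segments
  a[!valid] <- 0
  n_con <- colSums(valid)
  curve <- colSums(a) / ifelse(n_con > 0, n_con, NA)
  list(curve = as.numeric(curve), n_epochs = nrow(segments),
       n_contributing = as.integer(n_con))
}

#' Mean amplitude of an EMG curve up to the peak-return point
#'
#' Finds the absolute peak of the curve at or after time 0, then the first
#' sample after the peak whose value has returned to at most
#' `return_fraction` of that peak; the metric is the mean of the curve over
#' the half-open window from time 0 to that sample. When the curve never
#' returns, the window runs to the end of the curve and `no_return` is set.
#'
#' @param curve numeric curve (from [average_curve()]).
#' @param times_ms time axis of the curve, ms relative to EMG onset.
#' @param return_fraction fraction of the peak (default 0.30).
#' @return List with `amplitude`, `window_end_ms`, `no_return` and
#'   `peak`. `amplitude` is `NA` for an all-zero or all-`NA` curve.
#' @export
curve_amplitude <- function(curve, times_ms, return_fraction = 0.30) {
  post <- which(times_ms >= 0 & !is.na(curve))
  if (length(post) == 0 || all(abs(curve[post]) == 0))
    return(list(amplitude = NA_real_, window_end_ms = NA_real_,
                no_return = NA, peak = NA_real_))
  peak_idx <- post[which.max(abs(curve[post]))]
  peak <- abs(curve[peak_idx])
  after <- post[post > peak_idx]
  ret <- after[abs(curve[after]) <= return_fraction * peak]
  no_return <- length(ret) == 0
  end_idx <- if (no_return) max(post) + 1L else ret[1]
  win <- post[post < end_idx]
  end_ms <- if (end_idx <= length(times_ms)) times_ms[end_idx]
  else times_ms[length(times_ms)] + diff(times_ms[1:2])
  list(amplitude = mean(curve[win]), window_end_ms = end_ms,
       no_return = no_return, peak = peak)
}

#' Rising-flank slope of an EMG curve
#'
#' Ordinary least-squares slope of amplitude against time over a short
#' window after the EMG onset (default 0-30 ms, endpoints inclusive), in
#' amplitude units per ms.
#'
#' @param curve numeric curve.
#' @param times_ms time axis, ms relative to onset.
#' @param window_ms two-element window, ms (inclusive).
#' @return Slope (units/ms).
#' @export
curve_slope <- function(curve, times_ms, window_ms = c(0, 30)) {
  sel <- times_ms >= window_ms[1] & times_ms <= window_ms[2] &
    !is.na(curve)
  if (sum(sel) < 2) stop("slope window must contain at least two samples",
                         call. = FALSE)
  t <- times_ms[sel]; y <- curve[sel]
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Per-cell EMG curves and shape metrics
#'
#' For every participant by SAT by lexicality cell, averages the
#' onset-locked responding-channel segments of pure-correct trials with a
#' validated onset, and extracts the amplitude and rising-flank slope
#' metrics.
#'
#' @param epochs list of `trial_epoch` objects.
#' @param trials matching trial table from [process_epochs()].
#' @param config a [run_config()].
#' @param keep_curves also return the per-sample curves.
#' @return `data.frame` with one row per cell (`n_epochs`,
#'   `amplitude_metric`, `amplitude_window_end_ms`, `no_return`,
#'   `slope_metric`); when `keep_curves`, the curves are attached as the
#'   `"curves"` attribute (list of numeric vectors plus a `times_ms`
#'   element).
#' @export
participant_curves <- function(epochs, trials, config = run_config(),
                               keep_curves = FALSE) {
  use <- which(trials$trial_class == "pure_correct")
  if (length(use) == 0) stop("no pure-correct trials", call. = FALSE)
  segs <- vector("list", length(use))
  masks <- vector("list", length(use))
  key <- character(length(use))
  for (j in seq_along(use)) {
    i <- use[j]
    ep <- epochs[[i]]
    ol <- epoch_onset_locked(ep, trials$pmt_ms[i], config$curve_window_ms)
    segs[[j]] <- ol$signal[, ep$responding_hand]
    masks[[j]] <- ol$valid
    key[j] <- paste(trials$participant[i], trials$sat[i],
                    trials$lexicality[i], sep = "\r")
    times_ms <- ol$times_ms
  }
  groups <- split(seq_along(use), key)
  curves <- list()
  tab <- do.call(rbind, lapply(names(groups), function(k) {
    ii <- groups[[k]]
    av <- average_curve(do.call(rbind, segs[ii]),
                        do.call(rbind, masks[ii]),
                        rectify = config$rectify_curves)
    amp <- curve_amplitude(av$curve, times_ms, config$return_fraction)
    slope <- curve_slope(av$curve, times_ms, config$slope_window_ms)
    if (keep_curves) curves[[k]] <<- av$curve
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(participant = parts[1], sat = parts[2],
               lexicality = parts[3], n_epochs = av$n_epochs,
               amplitude_metric = amp$amplitude,
               amplitude_window_end_ms = amp$window_end_ms,
               no_return = amp$no_return,
               slope_metric = slope, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  if (keep_curves)
    attr(tab, "curves") <- c(curves, list(times_ms = times_ms))
  tab
}
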