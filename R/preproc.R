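#' Re-reference, band-pass filter and downsample a continuous recording
#'
#' The preprocessing chain applied to every session before epoching:
#'
#' 1. re-reference every channel to the algebraic average of TP9 and TP10;
#' 2. zero-phase band-pass 0.05-50 Hz, realized as a cascade of a 2nd-order
#'    Butterworth high-pass at 0.05 Hz and a 4th-order Butterworth low-pass
#'    at 50 Hz, each applied forward-backward (`signal::filtfilt`) so no
#'    latency bias enters the response-locked analyses;
#' 3. anti-aliased downsampling to `target_rate` (zero-phase FIR low-pass
#'    with cutoff at 0.8 x the target Nyquist, then decimation), with event
#'    sample indices rescaled consistently.
#'
#' @param raw A `wd_raw` containing channels TP9 and TP10.
#' @param events Optional `wd_events`; indices are rescaled to the new rate.
#' @param low,high Band edges in Hz.
#' @param target_rate Output sampling rate in Hz; must divide the input
#'   rate. When equal to the input rate no resampling is done.
#' @return If `events` is `NULL`, the preprocessed `wd_raw`; otherwise a
#'   list with elements `raw` and `events`.
#' @export
preprocess_raw <- function(raw, events = NULL, low = 0.05, high = 50,
                           target_rate = 250) {
  miss <- setdiff(c("TP9", "TP10"), raw$channel_names)
  if (length(miss) > 0) {
    stop("missing reference channel(s): ", paste(miss, collapse = ", "))
  }
  fs <- raw$sampling_rate
  bp_hi <- signal::butter(2, low / (fs / 2), type = "high")
  bp_lo <- signal::butter(4, high / (fs / 2), type = "low")
  X <- preprocess_matrix_cpp(raw$samples,
                             match("TP9", raw$channel_names),
                             match("TP10", raw$channel_names),
                             bp_hi$b, bp_hi$a, bp_lo$b, bp_lo$a)

  ev <- events
  if (target_rate != fs) {
    if (fs %% target_rate != 0) {
      stop("target_rate must divide the input sampling rate")
    }
    q <- fs %/% target_rate
    aa <- signal::fir1(64, 0.8 * (target_rate / 2) / (fs / 2))
    X <- filtfilt_matrix_cpp(X, as.numeric(aa), 1)
    keep <- seq(1, ncol(X), by = q)
    X <- X[, keep, drop = FALSE]
    if (!is.null(ev)) {
      ev$sample_index <- as.integer((ev$sample_index - 1L) %/% q + 1L)
    }
    fs <- target_rate
  }
  out <- new_raw(X, fs, raw$channel_names)
  if (is.null(events)) out else list(raw = out, events = ev)
}

new_epochs <- function(data, time_ms, lock, labels, sampling_rate,
                       channel_names, subject_id = NA_character_) {
  structure(list(data = data, time_ms = time_ms, lock = lock, labels = labels,
                 kept = rep(TRUE, dim(data)[1]), sampling_rate = sampling_rate,
                 channel_names = channel_names, subject_id = subject_id,
                 n_dropped_bounds = 0L),
            class = "wd_epochs")
}

#' @export
print.wd_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<wd_epochs> %d trials x %d channels x %d samples, %s-locked [%g, %g] ms, %d kept\n",
              d[1], d[2], d[3], x$lock, min(x$time_ms), max(x$time_ms),
              sum(x$kept)))
  invisible(x)
}

#' Cut labeled epochs around events
#'
#' Extracts one epoch per trial around the lock event (array onset or button
#' press), labeling each trial `"left"`/`"right"` from the press code. No
#' baseline subtraction is applied: the stimulus stream is continuously
#' present, so there is no neutral baseline period. Trials whose window
#' falls outside the recording are dropped and counted.
#'
#' @param raw A preprocessed `wd_raw`.
#' @param events A `wd_events` tibble.
#' @param lock `"stimulus"` (array onset) or `"response"` (button press).
#' @param window_ms Two-element window in ms relative to the lock event.
#'   Defaults to the analysis windows: `c(-1000, 4000)` stimulus-locked,
#'   `c(-4000, 1400)` response-locked.
#' @param subject_id Optional subject identifier carried in the result.
#' @return A `wd_epochs`: trials x channels x samples array with a
#'   millisecond time axis containing 0 at the lock event, per-trial labels
#'   and an all-`TRUE` kept mask. The number of boundary-dropped trials is
#'   in field `n_dropped_bounds`.
#' @export
epoch_events <- function(raw, events, lock = c("response", "stimulus"),
                         window_ms = NULL, subject_id = NA_character_) {
  lock <- match.arg(lock)
  if (is.null(window_ms)) {
    window_ms <- if (lock == "stimulus") c(-1000, 4000) else c(-4000, 1400)
  }
  fs <- raw$sampling_rate
  press <- events[events$code %in% c("press_left", "press_right"), ]
  onset <- events[events$code == "array_onset", ]
  if (lock == "stimulus") {
    # label each onset from the first press that follows it
    lab_idx <- findInterval(onset$sample_index, press$sample_index) + 1L
    valid <- lab_idx <= nrow(press)
    centers <- onset$sample_index[valid]
    labels <- ifelse(press$code[lab_idx[valid]] == "press_left", "left", "right")
  } else {
    centers <- press$sample_index
    labels <- ifelse(press$code == "press_left", "left", "right")
  }
  if (length(centers) == 0) stop("no matching events to epoch")

  off <- seq(round(window_ms[1] * fs / 1000), round(window_ms[2] * fs / 1000))
  in_bounds <- (centers + off[1]) >= 1 & (centers + off[length(off)]) <= ncol(raw$samples)
  n_dropped <- sum(!in_bounds)
  centers <- centers[in_bounds]
  labels <- labels[in_bounds]
  if (length(centers) == 0) stop("every epoch window exceeds the recording bounds")

  nch <- nrow(raw$samples)
  data <- array(NA_real_, dim = c(length(centers), nch, length(off)))
  for (i in seq_along(centers)) {
    data[i, , ] <- raw$samples[, centers[i] + off, drop = FALSE]
  }
  ep <- new_epochs(data, time_ms = off / fs * 1000, lock = lock,
                   labels = labels, sampling_rate = fs,
                   channel_names = raw$channel_names, subject_id = subject_id)
  ep$n_dropped_bounds <- n_dropped
  ep
}

#' Moving-window peak-to-peak artifact rejection
#'
#' Marks a trial as rejected when any channel in the selected subset shows a
#' peak-to-peak (max minus min) excursion above `threshold` within any
#' window of `window_ms` placed every `step_ms`, with a final window flushed
#' to the epoch end so coverage is complete. The kept mask is cumulative:
#' already-rejected trials stay rejected.
#'
#' @param epochs A `wd_epochs`.
#' @param threshold Peak-to-peak threshold in uV (default 100).
#' @param window_ms Window length in ms (default 100).
#' @param step_ms Step between window onsets in ms (default 50).
#' @param channels Channel labels to scan; default all non-reference
#'   channels (everything except TP9/TP10).
#' @return The `wd_epochs` with an updated `kept` mask.
#' @export
reject_artifacts_p2p <- function(epochs, threshold = 100, window_ms = 100,
                                 step_ms = 50, channels = NULL) {
  stopifnot(threshold > 0, step_ms <= window_ms)
  if (is.null(channels)) {
    channels <- setdiff(epochs$channel_names, c("TP9", "TP10"))
  }
  ch_idx <- match(channels, epochs$channel_names)
  if (length(ch_idx) == 0 || anyNA(ch_idx)) {
    stop("rejection channel subset is empty or contains unknown channels")
  }
  fs <- epochs$sampling_rate
  w <- as.integer(round(window_ms / 1000 * fs))
  s <- max(1L, as.integer(floor(step_ms / 1000 * fs)))
  flagged <- p2p_flag_cpp(epochs$data, as.integer(ch_idx), w, s, threshold)
  epochs$kept <- epochs$kept & !flagged
  epochs
}

#' Eye-movement rejection on the FT9/FT10 proxy channels
#'
#' The same moving-window peak-to-peak operator as
#' [reject_artifacts_p2p()], restricted to FT9 and FT10 at a 20 uV
#' threshold: horizontal eye movements project strongly onto these
#' anterior-temporal sites.
#'
#' @param epochs A `wd_epochs` containing FT9 and FT10.
#' @param threshold Peak-to-peak threshold in uV (default 20).
#' @return The `wd_epochs` with an updated `kept` mask.
#' @export
reject_eye_movements <- function(epochs, threshold = 20) {
  reject_artifacts_p2p(epochs, threshold = threshold, window_ms = 100,
                       step_ms = 50, channels = c("FT9", "FT10"))
}
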