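#' Continuous multi-channel EEG recording
#'
#' Lightweight container: a channels x time matrix of microvolt samples, the
#' sampling rate, channel names, and an event table (sample index + marker
#' code) sorted by time.
#'
#' @param samples Numeric matrix, channels x time, microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `samples`.
#' @param events data.frame with columns `sample` (1-based index) and `code`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_names,
                          events = data.frame(sample = integer(0),
                                              code = character(0))) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (anyNA(samples)) stop("recording contains NaN/NA samples")
  if (nrow(samples) != length(channel_names)) {
    stop("channel count does not match channel_names")
  }
  stopifnot(is.data.frame(events), all(c("sample", "code") %in% names(events)))
  if (nrow(events) > 1 && is.unsorted(events$sample)) {
    events <- events[order(events$sample), , drop = FALSE]
  }
  if (nrow(events) &&
      (min(events$sample) < 1 || max(events$sample) > ncol(samples))) {
    stop("event sample indices outside the recording")
  }
  rownames(samples) <- channel_names
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_names = channel_names, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Trial-aligned epochs with condition labels and phase windows
#'
#' Holds the trials x channels x time array cut from -1000 ms to +2000 ms
#' around each arrow-onset marker, the load condition of each trial, a
#' per-trial kept mask from the +/-100 microvolt rejection rule, and the
#' three phase windows (attention 0-500 ms, encoding 500-1000 ms, retention
#' 1000-2000 ms after the arrow) as sample ranges into the epoch.
#'
#' @param epochs 3-d numeric array, trials x channels x time.
#' @param sampling_rate Hz.
#' @param channel_names Channel labels (second dimension).
#' @param condition Per-trial condition labels ("2T"/"4T").
#' @param kept_mask Per-trial logical; FALSE marks amplitude-rejected trials.
#' @param window_ms Epoch window relative to the marker, milliseconds.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, sampling_rate, channel_names, condition,
                       kept_mask = rep(TRUE, dim(epochs)[1]),
                       window_ms = c(-1000, 2000)) {
  stopifnot(length(dim(epochs)) == 3,
            dim(epochs)[1] == length(condition),
            dim(epochs)[1] == length(kept_mask),
            dim(epochs)[2] == length(channel_names))
  expected_len <- round(diff(window_ms) / 1000 * sampling_rate)
  if (dim(epochs)[3] != expected_len) {
    stop("epoch length does not match the window and sampling rate")
  }
  pw <- phase_windows(sampling_rate, window_ms)
  structure(list(epochs = epochs, sampling_rate = sampling_rate,
                 channel_names = channel_names, condition = condition,
                 kept_mask = kept_mask, window_ms = window_ms,
                 phase_windows = pw),
            class = "eeg_epochs")
}

#' Phase windows of the change-detection trial
#'
#' Attention (0-500 ms), encoding (500-1000 ms) and retention (1000-2000 ms)
#' after arrow onset, expressed as disjoint, ordered sample ranges within an
#' epoch whose first sample sits at `window_ms[1]` relative to the arrow.
#'
#' @param sampling_rate Hz.
#' @param window_ms Epoch window relative to arrow onset.
#' @return Named list of integer sample-index vectors.
#' @export
phase_windows <- function(sampling_rate, window_ms = c(-1000, 2000)) {
  bounds_ms <- list(attention = c(0, 500), encoding = c(500, 1000),
                    retention = c(1000, 2000))
  lapply(bounds_ms, function(b) {
    from <- round((b[1] - window_ms[1]) / 1000 * sampling_rate) + 1L
    to <- round((b[2] - window_ms[1]) / 1000 * sampling_rate)
    seq.int(from, to)
  })
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %d trials (%d kept) x %d channels x %d samples @ %g Hz\n",
              d[1], sum(x$kept_mask), d[2], d[3], x$sampling_rate))
  tab <- table(x$condition[x$kept_mask])
  cat("  kept per condition:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
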