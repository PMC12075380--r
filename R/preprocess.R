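#' Remove high-intensity artifact segments from a continuous recording
#'
#' The continuous record is scanned in fixed-length segments (2 s by
#' default); segment intensity is the root-mean-square amplitude across all
#' channels, and any segment whose intensity strictly exceeds `factor` times
#' the mean segment intensity is excised. Events falling inside removed
#' segments are dropped; remaining event indices are shifted to the spliced
#' record.
#'
#' @param recording An [eeg_recording].
#' @param segment_s Segment length in seconds.
#' @param factor Rejection multiplier on the mean segment RMS (strict `>`).
#' @return A list: `recording` (cleaned), `log` (data.frame with
#'   segment_index, start_s, rms, threshold, removed).
#' @export
reject_segments <- function(recording, segment_s = 2, factor = 5) {
  fs <- recording$sampling_rate
  seg_len <- round(segment_s * fs)
  total_n <- ncol(recording$samples)
  if (total_n <= seg_len) stop("recording shorter than one segment")
  n_seg <- floor(total_n / seg_len)

  rms <- vapply(seq_len(n_seg), function(s) {
    idx <- ((s - 1) * seg_len + 1):(s * seg_len)
    sqrt(mean(recording$samples[, idx]^2))
  }, numeric(1))
  threshold <- factor * mean(rms)
  removed <- rms > threshold
  if (all(removed)) {
    stop("segment rejection removed every segment of the recording")
  }

  log <- data.frame(segment_index = seq_len(n_seg),
                    start_s = (seq_len(n_seg) - 1) * segment_s,
                    rms = rms, threshold = threshold, removed = removed)

  keep_sample <- rep(TRUE, total_n)
  for (s in which(removed)) {
    keep_sample[((s - 1) * seg_len + 1):(s * seg_len)] <- FALSE
  }
  new_index <- cumsum(keep_sample)        # old sample -> new sample
  ev <- recording$events
  ev_keep <- keep_sample[ev$sample]
  ev <- ev[ev_keep, , drop = FALSE]
  ev$sample <- new_index[ev$sample]

  cleaned <- eeg_recording(recording$samples[, keep_sample, drop = FALSE],
                           fs, recording$channel_names, ev)
  list(recording = cleaned, log = log)
}

#' Band-pass and notch filtering
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass at
#' 0.5-95 Hz followed by 2nd-order Butterworth band-stop notches at 50 and
#' 100 Hz. Forward-backward application squares the magnitude response and
#' cancels phase distortion, so downstream Hilbert phase estimates are
#' undistorted.
#'
#' @param recording An [eeg_recording].
#' @param bandpass_hz Band-pass edges, Hz.
#' @param notch_hz Centre frequencies of the notches, Hz; notches above the
#'   Nyquist frequency are skipped.
#' @return A filtered [eeg_recording].
#' @export
filter_chain <- function(recording, bandpass_hz = c(0.5, 95),
                         notch_hz = c(50, 100)) {
  fs <- recording$sampling_rate
  nyq <- fs / 2
  if (fs <= 200 || bandpass_hz[2] >= nyq) {
    stop("sampling rate too low for the ", bandpass_hz[2], " Hz band edge")
  }
  bp <- signal::butter(2, bandpass_hz / nyq, type = "pass")
  notches <- lapply(notch_hz[notch_hz < nyq], function(f0) {
    signal::butter(1, c(f0 - 2, f0 + 2) / nyq, type = "stop")
  })
  X <- recording$samples
  for (i in seq_len(nrow(X))) {
    x <- signal::filtfilt(bp, X[i, ])
    for (nf in notches) x <- signal::filtfilt(nf, x)
    X[i, ] <- x
  }
  eeg_recording(X, fs, recording$channel_names, recording$events)
}

#' Remove stereotyped artifact components by ICA
#'
#' Optional stage (off by default for synthetic data): decomposes the
#' recording into independent components, flags components whose topography
#' is dominated by the frontal-most channels with mostly low-frequency power
#' (blink-like) or whose spectrum is dominated by activity above 20 Hz
#' (muscle-like), and reconstructs the recording without them. On
#' decomposition failure the input is passed through with a warning.
#'
#' @param recording An [eeg_recording].
#' @param enabled Logical; FALSE returns the input unchanged.
#' @param n_components Number of components (default: min(channels, 20)).
#' @return An [eeg_recording]; attribute `removed_components` lists flagged
#'   component indices.
#' @export
remove_artifact_components <- function(recording, enabled = FALSE,
                                       n_components = NULL) {
  if (!enabled) return(recording)
  if (nrow(recording$samples) < 20) {
    stop("ICA artifact removal requires at least 20 channels")
  }
  out <- tryCatch({
    X <- recording$samples
    mu <- rowMeans(X)
    Xc <- X - mu
    k <- if (is.null(n_components)) min(nrow(X), 20L) else n_components
    dec <- fast_ica(Xc, k)
    S <- dec$unmixing %*% Xc                    # components x time
    A <- dec$mixing                             # channels x components
    flagged <- flag_artifact_components(S, A, recording)
    if (length(flagged)) {
      S[flagged, ] <- 0
    }
    Xr <- A %*% S + mu
    rec <- eeg_recording(Xr, recording$sampling_rate,
                         recording$channel_names, recording$events)
    attr(rec, "removed_components") <- flagged
    rec
  }, error = function(e) {
    warning("ICA decomposition failed (", conditionMessage(e),
            "); recording passed through unchanged")
    recording
  })
  out
}

## Symmetric FastICA with tanh contrast on pre-whitened data.
fast_ica <- function(Xc, k, max_iter = 100, tol = 1e-5) {
  n <- ncol(Xc)
  C <- Xc %*% t(Xc) / n
  eig <- eigen(C, symmetric = TRUE)
  k <- min(k, sum(eig$values > 1e-12))
  D <- eig$values[seq_len(k)]
  E <- eig$vectors[, seq_len(k), drop = FALSE]
  whiten <- diag(1 / sqrt(D), k) %*% t(E)       # k x channels
  Z <- whiten %*% Xc                            # whitened, k x time
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gp <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / n - diag(gp, k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmixing <- W %*% whiten                      # k x channels
  mixing <- E %*% diag(sqrt(D), k) %*% t(W)     # channels x k
  list(unmixing = unmixing, mixing = mixing)
}

flag_artifact_components <- function(S, A, recording) {
  fs <- recording$sampling_rate
  frontal <- grepl("^(Fp|AF)", recording$channel_names)
  flagged <- integer(0)
  for (j in seq_len(nrow(S))) {
    topo <- abs(A[, j]) / max(abs(A[, j]))
    spec <- Mod(stats::fft(S[j, ]))^2
    freqs <- (seq_along(spec) - 1) * fs / length(spec)
    half <- freqs <= fs / 2
    p_low <- sum(spec[half & freqs < 5])
    p_high <- sum(spec[half & freqs > 20])
    p_all <- sum(spec[half]) + .Machine$double.eps
    blink_like <- any(frontal) && mean(topo[frontal]) > 2 * mean(topo[!frontal]) &&
      p_low / p_all > 0.6
    muscle_like <- p_high / p_all > 0.7
    if (blink_like || muscle_like) flagged <- c(flagged, j)
  }
  flagged
}

#' Cut condition-labelled epochs around arrow-onset markers
#'
#' One epoch per event, spanning `window_ms` (default -1000 to +2000 ms)
#' around the marker. Trials whose window would read outside the recording
#' are dropped and logged. A trial is flagged not-kept when the absolute
#' amplitude exceeds `reject_uv` microvolts on any channel at any sample.
#'
#' @param recording An [eeg_recording] whose event codes end in the condition
#'   label (e.g. `arrow_2T`).
#' @param window_ms Epoch window relative to the marker, milliseconds.
#' @param reject_uv Absolute amplitude rejection threshold, microvolts.
#' @return An [eeg_epochs]; attribute `dropped_boundary` counts boundary
#'   trials that were discarded.
#' @export
make_epochs <- function(recording, window_ms = c(-1000, 2000),
                        reject_uv = 100) {
  ev <- recording$events
  if (!nrow(ev)) stop("recording has no event markers to epoch around")
  fs <- recording$sampling_rate
  pre <- round(-window_ms[1] / 1000 * fs)
  post <- round(window_ms[2] / 1000 * fs)
  len <- pre + post
  total_n <- ncol(recording$samples)

  start <- ev$sample - pre
  stop_ <- ev$sample + post - 1L
  in_bounds <- start >= 1 & stop_ <= total_n
  dropped_boundary <- sum(!in_bounds)
  ev <- ev[in_bounds, , drop = FALSE]
  if (!nrow(ev)) stop("no epochs lie fully inside the recording")

  n_ch <- nrow(recording$samples)
  arr <- array(NA_real_, dim = c(nrow(ev), n_ch, len))
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$sample[i] - pre):(ev$sample[i] + post - 1L)
    arr[i, , ] <- recording$samples[, idx]
  }
  condition <- sub("^.*_", "", ev$code)
  kept <- apply(arr, 1, function(m) max(abs(m)) <= reject_uv)

  for (cond in unique(condition)) {
    if (!any(kept[condition == cond])) {
      stop("every epoch rejected in condition ", cond)
    }
  }
  ep <- eeg_epochs(arr, fs, recording$channel_names, condition,
                   kept_mask = kept, window_ms = window_ms)
  attr(ep, "dropped_boundary") <- dropped_boundary
  ep
}

#' Full preprocessing chain
#'
#' Fixed stage order: segment rejection on the continuous record, zero-phase
#' filtering, optional ICA artifact-component removal, then epoching with
#' the +/-100 microvolt rule. A provenance list records the stage order,
#' parameters and counts.
#'
#' @param recording An [eeg_recording].
#' @param seg_len_s,seg_factor Segment-rejection parameters.
#' @param bandpass_hz,notch_hz Filter parameters.
#' @param ica Logical, run the ICA stage.
#' @param epoch_ms,reject_uv Epoching parameters.
#' @return A list: `epochs` ([eeg_epochs]), `rejection_log`, `provenance`.
#' @export
preprocess <- function(recording, seg_len_s = 2, seg_factor = 5,
                       bandpass_hz = c(0.5, 95), notch_hz = c(50, 100),
                       ica = FALSE, epoch_ms = c(-1000, 2000),
                       reject_uv = 100) {
  seg <- reject_segments(recording, seg_len_s, seg_factor)
  filt <- filter_chain(seg$recording, bandpass_hz, notch_hz)
  clean <- remove_artifact_components(filt, enabled = ica)
  epochs <- make_epochs(clean, epoch_ms, reject_uv)
  provenance <- list(
    stages = c("reject_segments", "filter_chain",
               if (ica) "remove_artifact_components", "make_epochs"),
    seg_len_s = seg_len_s, seg_factor = seg_factor,
    bandpass_hz = bandpass_hz, notch_hz = notch_hz, ica = ica,
    epoch_ms = epoch_ms, reject_uv = reject_uv,
    segments_removed = sum(seg$log$removed),
    epochs_total = length(epochs$kept_mask),
    epochs_kept = sum(epochs$kept_mask),
    boundary_dropped = attr(epochs, "dropped_boundary")
  )
  list(epochs = epochs, rejection_log = seg$log, provenance = provenance)
}
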