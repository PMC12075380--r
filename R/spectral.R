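#' Canonical EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30, low-gamma 30-60 and
#' high-gamma 60-80 Hz. Edges are half-open `[low, high)` so the six bands
#' partition 0.5-80 Hz despite the shared printed edges.
#'
#' @return data.frame with columns band, low, high.
#' @export
band_scheme <- function() {
  scheme <- data.frame(
    band = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    low  = c(0.5, 4, 8, 12, 30, 60),
    high = c(4, 8, 12, 30, 60, 80),
    stringsAsFactors = FALSE
  )
  validate_band_scheme(scheme)
}

validate_band_scheme <- function(scheme) {
  stopifnot(all(c("band", "low", "high") %in% names(scheme)),
            all(scheme$low > 0), all(scheme$high > scheme$low))
  o <- order(scheme$low)
  if (any(scheme$high[o][-nrow(scheme)] > scheme$low[o][-1])) {
    stop("bands overlap under the half-open [low, high) convention")
  }
  scheme
}

#' One-sided power spectrum of a segment
#'
#' FFT-based magnitude-squared spectrum on a fixed 2-s analysis length
#' (0.5 Hz resolution at any sampling rate): the segment is Hann-tapered
#' over its own length, zero-padded (or truncated) to `analysis_s` seconds,
#' and normalised by the effective window power so that the sum of the
#' one-sided spectrum equals the mean-square amplitude of the tapered
#' segment. Power is in microvolts squared.
#'
#' @param segment Numeric vector of samples.
#' @param sampling_rate Hz.
#' @param analysis_s Analysis window length in seconds (sets the frequency
#'   grid step to `1/analysis_s`).
#' @param taper "hann" or "none".
#' @return data.frame with columns `freq` (Hz) and `power`.
#' @export
spectrum_fft <- function(segment, sampling_rate, analysis_s = 2,
                         taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n <- length(segment)
  if (n == 0) stop("empty segment")
  N <- round(analysis_s * sampling_rate)
  w <- if (taper == "hann") hann_window(n) else rep(1, n)
  y <- segment * w
  if (n < N) y <- c(y, numeric(N - n)) else if (n > N) y <- y[seq_len(N)]
  Y <- stats::fft(y)
  half <- seq_len(floor(N / 2) + 1)
  mult <- rep(2, length(half))
  mult[1] <- 1
  if (N %% 2 == 0) mult[length(half)] <- 1
  power <- mult * Mod(Y[half])^2 / (N * n * mean(w^2))
  data.frame(freq = (half - 1) / analysis_s, power = power)
}

## Periodic Hann taper.
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

#' Band power from a spectrum
#'
#' Sum of the magnitude-squared spectrum over frequency bins with
#' `low <= f < high`.
#'
#' @param spec data.frame from [spectrum_fft()].
#' @param low,high Band edges in Hz.
#' @return Scalar power in microvolts squared.
#' @export
band_power <- function(spec, low, high) {
  if (high <= low) stop("band edges must satisfy low < high")
  if (low > max(spec$freq)) stop("band lies outside the spectrum range")
  sum(spec$power[spec$freq >= low & spec$freq < high])
}

## Band power of one segment for every band in the scheme.
segment_band_powers <- function(segment, sampling_rate, scheme, analysis_s = 2) {
  spec <- spectrum_fft(segment, sampling_rate, analysis_s)
  vapply(seq_len(nrow(scheme)), function(b) {
    band_power(spec, scheme$low[b], scheme$high[b])
  }, numeric(1))
}

#' Per-region, per-band, per-phase band-power table
#'
#' For every kept epoch, electrode and phase window, computes the band power
#' of the windowed samples (Hann-tapered, zero-padded to the 2-s analysis
#' length), then averages over the region's electrodes and over kept epochs
#' within each condition. The result is the complete factorial grid
#' condition x phase x region x band.
#'
#' @param epochs An [eeg_epochs].
#' @param scheme Band scheme data.frame ([band_scheme()]).
#' @param regions Region map ([region_map()]); regions whose electrodes are
#'   absent from the montage raise an error naming the electrode.
#' @param subject,session Labels copied into the table.
#' @param analysis_s FFT analysis length in seconds.
#' @return data.frame with columns subject, session, condition, phase,
#'   region, band, power.
#' @export
band_power_table <- function(epochs, scheme = band_scheme(),
                             regions = region_map(),
                             subject = "S01", session = "pre",
                             analysis_s = 2) {
  validate_band_scheme(scheme)
  validate_region_map(regions, epochs$channel_names)
  fs <- epochs$sampling_rate
  pw <- epochs$phase_windows
  kept <- which(epochs$kept_mask)
  if (!length(kept)) stop("no kept epochs")

  ch_index <- stats::setNames(seq_along(epochs$channel_names),
                              epochs$channel_names)
  out <- list()
  for (cond in sort(unique(epochs$condition))) {
    tr <- kept[epochs$condition[kept] == cond]
    if (!length(tr)) stop("no kept epochs in condition ", cond)
    for (ph in names(pw)) {
      idx <- pw[[ph]]
      # per-region accumulator: bands x 1
      for (rg in names(regions)) {
        els <- ch_index[regions[[rg]]]
        acc <- matrix(0, nrow = nrow(scheme), ncol = 1)
        n_acc <- 0L
        for (i in tr) {
          for (e in els) {
            acc <- acc + segment_band_powers(epochs$epochs[i, e, idx], fs,
                                             scheme, analysis_s)
            n_acc <- n_acc + 1L
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          subject = subject, session = session, condition = cond,
          phase = ph, region = rg, band = scheme$band,
          power = as.numeric(acc / n_acc), stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}
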