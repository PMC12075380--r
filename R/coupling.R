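#' Analytic signal of a band-limited component
#'
#' Band-passes the series with a zero-phase 4th-order Butterworth filter and
#' takes the Hilbert analytic extension, returning instantaneous phase in
#' \[-pi, pi) and the non-negative amplitude envelope. This is the standard
#' route to theta phase and gamma amplitude for cross-frequency coupling.
#'
#' @param series Numeric vector.
#' @param band Two-element band edges in Hz.
#' @param sampling_rate Hz.
#' @return List of class `analytic_signal` with `phase`, `amplitude`,
#'   `band`, `sampling_rate`.
#' @export
analytic_signal <- function(series, band, sampling_rate) {
  nyq <- sampling_rate / 2
  if (band[2] >= nyq) stop("band upper edge at or above Nyquist")
  min_n <- ceiling(3 / band[1] * sampling_rate)
  if (length(series) < min_n) {
    stop("series too short for the ", band[1], "-", band[2],
         " Hz band: need at least ", min_n, " samples (3 cycles of ",
         band[1], " Hz)")
  }
  bf <- signal::butter(2, band / nyq, type = "pass")
  xb <- signal::filtfilt(bf, series)
  z <- hilbert_analytic(xb)
  structure(list(phase = Arg(z), amplitude = Mod(z),
                 band = band, sampling_rate = sampling_rate),
            class = "analytic_signal")
}

## Analytic extension via the frequency-domain Hilbert transform.
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Modulation index from a phase-binned amplitude distribution
#'
#' The Kullback-Leibler divergence of the normalised distribution from
#' uniform, divided by `log(N)`: 0 for a flat distribution, 1 when all mass
#' falls in a single bin. Zero-mass bins contribute 0 (the `0 * log 0`
#' limit).
#'
#' @param p Non-negative bin masses (normalised internally).
#' @return MI in \[0, 1\].
#' @export
mi_from_distribution <- function(p) {
  if (length(p) < 2) stop("need at least 2 phase bins")
  if (any(p < 0) || any(!is.finite(p))) stop("bin masses must be finite and non-negative")
  s <- sum(p)
  if (s <= 0) stop("total amplitude mass is zero; MI undefined")
  p <- p / s
  N <- length(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] * N)) / log(N)
}

#' Tort modulation index of phase-amplitude coupling
#'
#' Assigns each amplitude sample to one of `n_bins` half-open phase bins of
#' equal width starting at -180 degrees, forms the distribution of mean
#' amplitude per bin normalised to unit sum, and returns its KL divergence
#' from uniform scaled by `1/log(N)`.
#'
#' @param phase Instantaneous phase in radians (any real values; wrapped).
#' @param amplitude Non-negative amplitude envelope, same length.
#' @param n_bins Number of phase bins (18 bins of 20 degrees by default).
#' @return MI in \[0, 1\].
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) stop("phase and amplitude lengths differ")
  if (n_bins < 2) stop("need at least 2 phase bins")
  if (!length(phase)) stop("empty input")
  if (all(amplitude == 0)) stop("all-zero amplitude; MI undefined")
  bin <- phase_bin_index(phase, n_bins)
  mean_amp <- vapply(seq_len(n_bins), function(b) {
    idx <- bin == b
    if (any(idx)) mean(amplitude[idx]) else 0
  }, numeric(1))
  mi_from_distribution(mean_amp)
}

## Half-open bins of width 2*pi/n starting at -pi.
phase_bin_index <- function(phase, n_bins) {
  ph <- (phase + pi) %% (2 * pi)
  pmin(floor(ph / (2 * pi / n_bins)) + 1L, n_bins)
}

#' n:m phase-phase coupling
#'
#' The phase-locking value of the n:m phase relationship: the modulus of the
#' mean unit phasor of `n * phi_fast - m * phi_slow`. 1 for perfect locking,
#' near `sqrt(pi) / (2 sqrt(T))` for independent phases over T samples.
#'
#' @param phase_slow,phase_fast Instantaneous phases in radians.
#' @param n,m Positive integers; the fast oscillation completes `m` cycles
#'   per `n` cycles of the slow one (default 1:6, e.g. 6 Hz theta against
#'   36 Hz gamma).
#' @return PPC in \[0, 1\].
#' @export
phase_phase_coupling <- function(phase_slow, phase_fast, n = 1, m = 6) {
  if (!length(phase_slow)) stop("empty input")
  if (length(phase_slow) != length(phase_fast)) stop("phase lengths differ")
  if (n < 1 || m < 1 || n != round(n) || m != round(m)) {
    stop("n and m must be positive integers")
  }
  Mod(mean(exp(1i * (n * phase_fast - m * phase_slow))))
}

#' Region-pair coupling over epochs and phase windows
#'
#' For each trial the phase-region electrodes are averaged into one signal
#' and its theta (4-8 Hz) analytic phase extracted over the whole epoch;
#' likewise the amplitude-region average yields low-gamma (30-60 Hz) and
#' high-gamma (60-80 Hz) analytic signals. Within each phase window the
#' Tort MI (theta phase vs gamma amplitude) and the n:m PPC (theta phase vs
#' gamma phase) are computed per epoch and then averaged over kept epochs.
#' Windows shorter than two theta cycles at 4 Hz (500 ms) are flagged
#' low-confidence rather than refused.
#'
#' @param epochs An [eeg_epochs].
#' @param regions Region map resolving every electrode named in `pairs`.
#' @param pairs List of `c(phase_region, amplitude_region)` pairs.
#' @param subject,session Labels copied into the table.
#' @param theta_band Phase band in Hz.
#' @param gamma_bands Named list of amplitude sub-bands in Hz.
#' @param nm `c(n, m)` ratio for the PPC.
#' @return data.frame with columns subject, session, condition, phase,
#'   phase_region, amp_region, gamma_band, measure (PAC_MI | PPC), value,
#'   low_confidence.
#' @export
couple_regions <- function(epochs, regions = region_map(),
                           pairs = list(c("left_frontal", "left_occipital")),
                           subject = "S01", session = "pre",
                           theta_band = c(4, 8),
                           gamma_bands = list(low_gamma = c(30, 60),
                                              high_gamma = c(60, 80)),
                           nm = c(1, 6)) {
  validate_region_map(regions, epochs$channel_names)
  fs <- epochs$sampling_rate
  pw <- epochs$phase_windows
  kept <- which(epochs$kept_mask)
  if (!length(kept)) stop("no kept epochs")
  ch_index <- stats::setNames(seq_along(epochs$channel_names),
                              epochs$channel_names)
  for (p in pairs) {
    if (!all(p %in% names(regions))) {
      stop("pair region not in region map: ", paste(setdiff(p, names(regions)),
                                                    collapse = ", "))
    }
  }

  out <- list()
  for (cond in sort(unique(epochs$condition))) {
    tr <- kept[epochs$condition[kept] == cond]
    if (!length(tr)) next
    for (p in pairs) {
      ph_els <- ch_index[regions[[p[1]]]]
      am_els <- ch_index[regions[[p[2]]]]
      # accumulate per window x gamma-band x measure
      acc <- array(0, dim = c(length(pw), length(gamma_bands), 2))
      for (i in tr) {
        ph_sig <- as.numeric(epochs$epochs[i, ph_els, , drop = FALSE])
        ph_sig <- colMeans(matrix(ph_sig, nrow = length(ph_els)))
        am_sig <- as.numeric(epochs$epochs[i, am_els, , drop = FALSE])
        am_sig <- colMeans(matrix(am_sig, nrow = length(am_els)))
        theta <- analytic_signal(ph_sig, theta_band, fs)
        for (g in seq_along(gamma_bands)) {
          gamma <- analytic_signal(am_sig, gamma_bands[[g]], fs)
          for (w in seq_along(pw)) {
            idx <- pw[[w]]
            acc[w, g, 1] <- acc[w, g, 1] +
              modulation_index(theta$phase[idx], gamma$amplitude[idx])
            acc[w, g, 2] <- acc[w, g, 2] +
              phase_phase_coupling(theta$phase[idx], gamma$phase[idx],
                                   nm[1], nm[2])
          }
        }
      }
      acc <- acc / length(tr)
      for (w in seq_along(pw)) {
        low_conf <- length(pw[[w]]) / fs < 0.5
        for (g in seq_along(gamma_bands)) {
          out[[length(out) + 1L]] <- data.frame(
            subject = subject, session = session, condition = cond,
            phase = names(pw)[w], phase_region = p[1], amp_region = p[2],
            gamma_band = names(gamma_bands)[g],
            measure = c("PAC_MI", "PPC"),
            value = c(acc[w, g, 1], acc[w, g, 2]),
            low_confidence = low_conf, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, out)
}
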