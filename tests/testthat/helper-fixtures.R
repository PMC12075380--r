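# Small, fast configurations used across the suite. 250 Hz keeps every
# band edge (95 Hz) below Nyquist while making filtering and FFTs cheap.

fast_config <- function(...) {
  defaults <- list(sampling_rate = 250, n_channels = 50,
                   n_trials_per_condition = 4, noise_sd = 2,
                   artifact_rate = 0, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# Tiny montage covering a frontal and both occipital regions.
mini_regions <- function() {
  list(left_frontal = c("Fp1", "AF3"),
       left_occipital = c("P3", "O1"),
       right_occipital = c("P4", "O2"))
}

mini_channels <- function() unlist(mini_regions(), use.names = FALSE)

# Independent brute-force step-up BH oracle (kept deliberately naive).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) adj[r] <- p[o[r]] * m / r
  for (r in (m - 1):1) if (m > 1) adj[r] <- min(adj[r], adj[r + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Independent MI oracle: KL divergence from uniform via its entropy form.
mi_oracle <- function(p) {
  p <- p / sum(p)
  nz <- p[p > 0]
  (log(length(p)) + sum(nz * log(nz))) / log(length(p))
}

# Closed-form phase-bin masses of the (1 + cos(phi)) / 2 envelope.
cosine_bin_masses <- function(n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  masses <- diff(edges) + diff(sin(edges))
  masses / sum(masses)
}

# Brute-force per-sample MI: explicit loop, no vectorised binning shared
# with the implementation.
mi_bruteforce_samples <- function(phase, amplitude, n_bins = 18) {
  width <- 2 * pi / n_bins
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (i in seq_along(phase)) {
    ph <- phase[i] %% (2 * pi)            # map to [0, 2pi) from -pi origin
    b <- floor(((phase[i] + pi) %% (2 * pi)) / width) + 1
    if (b > n_bins) b <- n_bins
    sums[b] <- sums[b] + amplitude[i]
    counts[b] <- counts[b] + 1L
  }
  means <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  mi_oracle(means)
}

sine_recording <- function(freq, fs = 1000, dur_s = 10, amp = 1,
                           channel = "Cz") {
  t <- (seq_len(fs * dur_s) - 1) / fs
  eeg_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs, channel)
}
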