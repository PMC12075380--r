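#' Configuration for the synthetic EEG + behaviour generator
#'
#' Bundles every parameter of the generative model: a theta oscillation whose
#' phase modulates the amplitude of a gamma oscillation (cosine-shaped
#' envelope, maximal at the theta peak), 1/f plus white background noise,
#' occasional high-amplitude artifact segments, the change-detection trial
#' timeline (200 ms arrow cue, 300 ms blank, 500 ms memory array, 900 ms
#' retention, response), and binomial hit/false-alarm behaviour with
#' lognormal reaction times.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param n_channels Number of montage channels (10-10 labels; region
#'   electrodes first).
#' @param n_trials_per_condition Trials per memory load condition (2T, 4T).
#' @param theta_freq Theta frequency in Hz, within 4-8.
#' @param gamma_freq Gamma frequency in Hz, within 30-80.
#' @param modulation_depth Phase-amplitude modulation depth in \[0, 1\]:
#'   0 means a flat gamma envelope, 1 means the envelope goes to zero at the
#'   theta trough.
#' @param theta_amp,gamma_amp Component amplitudes in microvolts.
#' @param noise_sd Total background noise standard deviation in microvolts,
#'   split evenly (in variance) between pink (1/f) and white noise.
#' @param artifact_rate Probability that any 2-s segment of the continuous
#'   recording is scaled into a high-amplitude artifact.
#' @param artifact_gain Multiplier applied to artifact segments (> 5 so the
#'   five-times-average-intensity rejection rule can recover them).
#' @param hit_rate,fa_rate Hit and false-alarm probabilities; either scalars
#'   or named vectors with entries `2T` and `4T`.
#' @param rt_lognormal_mu,rt_lognormal_sigma Lognormal reaction-time
#'   parameters on the log-millisecond scale.
#' @param gamma_channels Channels that carry the gamma component (and hence
#'   the coupling); defaults to the occipital region electrodes present in
#'   the montage. Theta is present on every channel so a frontal-phase /
#'   occipital-amplitude coupling analysis is well-posed.
#' @param channel_depths Optional named numeric vector overriding
#'   `modulation_depth` per channel.
#' @param channels Optional explicit channel-name vector (must be 10-10
#'   labels); overrides `n_channels`. Useful for reduced montages in
#'   simulation studies.
#' @param iti_range Inter-trial onset-to-onset interval range in seconds,
#'   jittered uniformly.
#' @param seed Integer seed; identical seed and configuration give a
#'   bit-identical recording and behaviour log.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 1000,
                         n_channels = 64,
                         n_trials_per_condition = 100,
                         theta_freq = 6,
                         gamma_freq = 40,
                         modulation_depth = 0.5,
                         theta_amp = 10,
                         gamma_amp = 5,
                         noise_sd = 5,
                         artifact_rate = 0.02,
                         artifact_gain = 10,
                         hit_rate = c("2T" = 0.92, "4T" = 0.80),
                         fa_rate = c("2T" = 0.08, "4T" = 0.20),
                         rt_lognormal_mu = log(600),
                         rt_lognormal_sigma = 0.25,
                         gamma_channels = NULL,
                         channel_depths = NULL,
                         channels = NULL,
                         iti_range = c(3.5, 4.5),
                         seed = 1L) {
  cfg <- list(
    sampling_rate = sampling_rate, n_channels = as.integer(n_channels),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    theta_freq = theta_freq, gamma_freq = gamma_freq,
    modulation_depth = modulation_depth,
    theta_amp = theta_amp, gamma_amp = gamma_amp, noise_sd = noise_sd,
    artifact_rate = artifact_rate, artifact_gain = artifact_gain,
    hit_rate = expand_rate(hit_rate), fa_rate = expand_rate(fa_rate),
    rt_lognormal_mu = rt_lognormal_mu,
    rt_lognormal_sigma = rt_lognormal_sigma,
    gamma_channels = gamma_channels, channel_depths = channel_depths,
    channels = channels, iti_range = iti_range, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

expand_rate <- function(r) {
  if (length(r) == 1 && is.null(names(r))) r <- c("2T" = unname(r), "4T" = unname(r))
  if (!all(c("2T", "4T") %in% names(r))) {
    stop("hit/fa rates must be a scalar or named with 2T and 4T")
  }
  r[c("2T", "4T")]
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with(cfg, {
    if (!is.finite(sampling_rate) || sampling_rate < 2 * 95) {
      stop("sampling_rate must be at least twice the 95 Hz filter edge")
    }
    if (gamma_freq <= theta_freq) stop("gamma_freq must exceed theta_freq")
    if (theta_freq < 4 || theta_freq > 8) stop("theta_freq must lie in [4, 8] Hz")
    if (gamma_freq < 30 || gamma_freq > 80) stop("gamma_freq must lie in [30, 80] Hz")
    if (sampling_rate < 2 * gamma_freq) {
      stop("sampling_rate below the Nyquist rate for gamma_freq (aliasing)")
    }
    if (modulation_depth < 0 || modulation_depth > 1) {
      stop("modulation_depth must lie in [0, 1]")
    }
    probs <- c(artifact_rate, hit_rate, fa_rate)
    if (!all(is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
      stop("artifact_rate, hit_rate and fa_rate must be probabilities in [0, 1]")
    }
    if (artifact_rate > 0 && artifact_gain <= 5) {
      stop("artifact_gain must exceed 5 so injected artifacts are recoverable")
    }
    if (n_trials_per_condition < 1) stop("need at least one trial per condition")
    if (noise_sd < 0 || theta_amp < 0 || gamma_amp < 0) {
      stop("amplitudes and noise_sd must be non-negative")
    }
  })
  invisible(cfg)
}

## Evaluate expr with the RNG seeded by `seed`, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## 1/f amplitude-shaped gaussian noise, unit variance.
pink_noise <- function(n) {
  if (n < 2) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  k <- pmin(k, n - k)           # two-sided frequency index
  scale <- ifelse(k == 0, 0, 1 / sqrt(k))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

synth_noise <- function(n, noise_sd) {
  if (noise_sd == 0) return(numeric(n))
  noise_sd * sqrt(0.5) * (pink_noise(n) + stats::rnorm(n))
}

#' Generate a single phase-amplitude-coupled channel
#'
#' The canonical PAC test signal: a theta carrier plus a gamma oscillation
#' whose envelope follows `(1 - d) + d * (1 + cos(phi_theta)) / 2`, so the
#' gamma amplitude is maximal at the theta peak and the modulation depth `d`
#' controls coupling strength, plus pink-and-white background noise.
#'
#' @param config A [synth_config()].
#' @param channel_depth Modulation depth for this channel, in \[0, 1\].
#' @param duration_s Length of the series in seconds.
#' @param theta_phase Optional precomputed theta phase vector (radians), used
#'   when many channels must share one theta oscillation.
#' @return Numeric vector of microvolt samples, length
#'   `sampling_rate * duration_s`.
#' @export
generate_pac_signal <- function(config, channel_depth = config$modulation_depth,
                                duration_s = 2, theta_phase = NULL) {
  validate_synth_config(config)
  if (channel_depth < 0 || channel_depth > 1) stop("channel_depth must lie in [0, 1]")
  fs <- config$sampling_rate
  n <- round(fs * duration_s)
  if (is.null(theta_phase)) {
    t <- (seq_len(n) - 1) / fs
    theta_phase <- 2 * pi * config$theta_freq * t
  }
  stopifnot(length(theta_phase) == n)
  t <- (seq_len(n) - 1) / fs
  envelope <- (1 - channel_depth) + channel_depth * (1 + cos(theta_phase)) / 2
  config$theta_amp * sin(theta_phase) +
    config$gamma_amp * envelope * sin(2 * pi * config$gamma_freq * t) +
    synth_noise(n, config$noise_sd)
}

resolve_channel_depths <- function(config, channel_names) {
  gamma_ch <- config$gamma_channels
  if (is.null(gamma_ch)) {
    occ <- c(region_map()$left_occipital, region_map()$right_occipital)
    gamma_ch <- intersect(channel_names, occ)
    if (!length(gamma_ch)) gamma_ch <- channel_names
  }
  unknown <- setdiff(gamma_ch, channel_names)
  if (length(unknown)) stop("gamma_channels not in montage: ",
                            paste(unknown, collapse = ", "))
  depths <- stats::setNames(numeric(length(channel_names)), channel_names)
  depths[gamma_ch] <- config$modulation_depth
  if (!is.null(config$channel_depths)) {
    bad <- setdiff(names(config$channel_depths), channel_names)
    if (length(bad)) stop("channel_depths names not in montage: ",
                          paste(bad, collapse = ", "))
    depths[names(config$channel_depths)] <- config$channel_depths
  }
  list(depths = depths, gamma_channels = gamma_ch)
}

#' Generate a continuous synthetic EEG recording with ground truth
#'
#' Builds the full change-detection session: trials of both load conditions
#' interleaved in random order, one `Stimulus` event marker per trial at
#' arrow onset, onset-to-onset spacing jittered in `iti_range` so that
#' -1000..+2000 ms epochs never overlap, a shared theta oscillation across
#' channels, gamma (with the configured coupling depth) on the gamma-carrying
#' channels, independent pink+white noise per channel, and 2-s artifact
#' segments scaled by `artifact_gain` at rate `artifact_rate`.
#'
#' @param config A [synth_config()].
#' @return A list with elements `recording` (an [eeg_recording]) and
#'   `ground_truth` (channel depth map, artifact segment indices, trial
#'   table with condition and onset sample).
#' @export
generate_recording <- function(config) {
  validate_synth_config(config)
  fs <- config$sampling_rate
  channels <- if (is.null(config$channels)) montage_1010(config$n_channels)
              else config$channels
  if (anyDuplicated(channels)) stop("duplicate channel names")
  depth_info <- resolve_channel_depths(config, channels)

  with_seed(config$seed, {
    n_tr <- config$n_trials_per_condition
    conditions <- sample(rep(c("2T", "4T"), each = n_tr))
    itis <- stats::runif(length(conditions) - 1,
                         config$iti_range[1], config$iti_range[2])
    onsets_s <- 2 + c(0, cumsum(itis))     # 2-s pre-roll before first arrow
    onset_samples <- round(onsets_s * fs) + 1L
    total_n <- round((onsets_s[length(onsets_s)] + 3) * fs)

    t <- (seq_len(total_n) - 1) / fs
    theta_phase <- 2 * pi * config$theta_freq * t
    gamma_carrier <- sin(2 * pi * config$gamma_freq * t)
    theta_comp <- config$theta_amp * sin(theta_phase)

    X <- matrix(0, nrow = length(channels), ncol = total_n,
                dimnames = list(channels, NULL))
    for (i in seq_along(channels)) {
      d <- depth_info$depths[i]
      x <- theta_comp
      if (channels[i] %in% depth_info$gamma_channels) {
        env <- (1 - d) + d * (1 + cos(theta_phase)) / 2
        x <- x + config$gamma_amp * env * gamma_carrier
      }
      X[i, ] <- x + synth_noise(total_n, config$noise_sd)
    }

    seg_len <- 2 * fs
    n_seg <- floor(total_n / seg_len)
    artifact_segments <- integer(0)
    if (config$artifact_rate > 0 && n_seg > 0) {
      hit <- stats::runif(n_seg) < config$artifact_rate
      artifact_segments <- which(hit)
      for (s in artifact_segments) {
        idx <- ((s - 1) * seg_len + 1):(s * seg_len)
        X[, idx] <- X[, idx] * config$artifact_gain
      }
    }

    events <- data.frame(
      sample = onset_samples,
      code = paste0("arrow_", conditions),
      stringsAsFactors = FALSE
    )
    rec <- eeg_recording(X, fs, channels, events)
    truth <- list(
      channel_depths = depth_info$depths,
      artifact_segments = artifact_segments,
      trials = data.frame(trial = seq_along(conditions),
                          condition = conditions,
                          onset_sample = onset_samples,
                          stringsAsFactors = FALSE)
    )
    list(recording = rec, ground_truth = truth)
  })
}

#' Generate a per-trial behaviour log
#'
#' Draws match/mismatch truth in balanced proportion per condition, responses
#' from the configured hit and false-alarm probabilities, and lognormal
#' reaction times.
#'
#' @param config A [synth_config()].
#' @param subject,session Labels copied into the log.
#' @return A data.frame with columns subject, session, condition, trial,
#'   truth, response, rt_ms.
#' @export
generate_behavior <- function(config, subject = "S01", session = "pre") {
  validate_synth_config(config)
  with_seed(config$seed + 1L, {
    n_tr <- config$n_trials_per_condition
    rows <- lapply(c("2T", "4T"), function(cond) {
      truth <- sample(rep(c("match", "mismatch"), length.out = n_tr))
      p_match <- ifelse(truth == "match",
                        config$hit_rate[[cond]], config$fa_rate[[cond]])
      response <- ifelse(stats::runif(n_tr) < p_match, "match", "mismatch")
      rt <- stats::rlnorm(n_tr, config$rt_lognormal_mu, config$rt_lognormal_sigma)
      data.frame(subject = subject, session = session, condition = cond,
                 trial = seq_len(n_tr), truth = truth, response = response,
                 rt_ms = rt, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
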