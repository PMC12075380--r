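#' Simulate a pre/post rTMS cohort with linked neural and behavioural change
#'
#' Generates a synthetic cohort in which each subject's post-intervention
#' session has reduced occipital gamma amplitude and reduced theta-gamma
#' modulation depth, with a per-subject effect size `r` drawn uniformly from
#' `effect_range`, and a 4-item hit rate that improves in proportion to the
#' same `r` (so the change in occipital gamma power and the change in
#' Cowan's K are negatively related across subjects, by construction). Each
#' subject-session is pushed through the full pipeline: synthesis,
#' preprocessing, band power and region-pair coupling, plus a behaviour
#' summary from an independent 100-trial-per-condition log.
#'
#' The cohort runs on a deliberately small montage (4 left-frontal,
#' 4 left-occipital, 2 right-occipital electrodes), 250 Hz sampling and
#' `n_trials_eeg` EEG trials per condition so that repeated cohorts stay
#' cheap; the generative model is otherwise identical to the full-scale
#' defaults.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer meta-seed; all per-subject seeds derive from it.
#' @param n_trials_eeg EEG trials per condition per session.
#' @param effect_range Range of the per-subject gamma-reduction fraction.
#' @param depth_pre,gamma_amp_pre Pre-session modulation depth and gamma
#'   amplitude (microvolts).
#' @param hit_gain Increase in 4T hit rate per unit of `r`.
#' @return List: `power`, `coupling`, `behavior` (stacked per-subject
#'   tables), `truth` (per-subject injected effect sizes), `regions` (the
#'   reduced region map used).
#' @export
simulate_cohort <- function(n_subjects = 20, seed = 1,
                            n_trials_eeg = 6,
                            effect_range = c(0.3, 0.6),
                            depth_pre = 0.6, gamma_amp_pre = 5,
                            hit_gain = 0.3) {
  regions <- list(
    left_frontal = c("Fp1", "AF3", "AF7", "F1"),
    left_occipital = c("P3", "P5", "P7", "PO3"),
    right_occipital = c("P4", "P6")
  )
  channels <- unlist(regions, use.names = FALSE)
  occ <- c(regions$left_occipital, regions$right_occipital)

  r <- with_seed(seed, stats::runif(n_subjects, effect_range[1],
                                    effect_range[2]))
  power <- list(); coupling <- list(); behavior <- list()
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("S%02d", s)
    for (session in c("pre", "post")) {
      is_post <- session == "post"
      depth <- if (is_post) depth_pre * (1 - r[s]) else depth_pre
      gamma_amp <- if (is_post) gamma_amp_pre * (1 - r[s]) else gamma_amp_pre
      hit4 <- if (is_post) min(0.95, 0.75 + hit_gain * r[s]) else 0.75
      sub_seed <- (seed * 131 + s * 17 + is_post) %% .Machine$integer.max

      cfg <- synth_config(
        sampling_rate = 250, channels = channels,
        n_trials_per_condition = n_trials_eeg,
        theta_freq = 6, gamma_freq = 40,
        modulation_depth = depth, theta_amp = 10, gamma_amp = gamma_amp,
        noise_sd = 3, artifact_rate = 0,
        hit_rate = c("2T" = 0.90, "4T" = hit4),
        fa_rate = c("2T" = 0.08, "4T" = 0.15),
        gamma_channels = occ, seed = sub_seed
      )
      rec <- generate_recording(cfg)
      pp <- preprocess(rec$recording, ica = FALSE)
      power[[length(power) + 1L]] <-
        band_power_table(pp$epochs, regions = regions,
                         subject = subj, session = session)
      coupling[[length(coupling) + 1L]] <-
        couple_regions(pp$epochs, regions = regions,
                       pairs = list(c("left_frontal", "left_occipital")),
                       subject = subj, session = session)

      cfg_beh <- synth_config(
        sampling_rate = 250, channels = channels,
        n_trials_per_condition = 100,
        modulation_depth = depth, gamma_amp = gamma_amp,
        artifact_rate = 0,
        hit_rate = c("2T" = 0.90, "4T" = hit4),
        fa_rate = c("2T" = 0.08, "4T" = 0.15),
        gamma_channels = occ, seed = sub_seed + 1L
      )
      behavior[[length(behavior) + 1L]] <-
        summarize_behavior(generate_behavior(cfg_beh, subject = subj,
                                             session = session))
    }
  }
  list(power = do.call(rbind, power),
       coupling = do.call(rbind, coupling),
       behavior = do.call(rbind, behavior),
       truth = data.frame(subject = sprintf("S%02d", seq_len(n_subjects)),
                          gamma_reduction = r, stringsAsFactors = FALSE),
       regions = regions)
}

#' Paired contrasts and change correlation for a simulated cohort
#'
#' Computes the headline statistics of the pre/post design on a cohort from
#' [simulate_cohort()]: a paired t-test of left-occipital low-gamma power
#' (retention window, 4-item condition) post vs pre, a paired t-test of the
#' left-frontal-theta to left-occipital-gamma modulation index on the same
#' cell, and the Spearman correlation between the per-subject change in that
#' gamma power and the change in Cowan's K (4-item condition). Directions
#' are reported as the sign of post minus pre.
#'
#' @param cohort Result of [simulate_cohort()].
#' @return List: `results` (FDR-adjusted result rows), `deltas` (per-subject
#'   change table).
#' @export
cohort_contrasts <- function(cohort) {
  # order sessions so "post minus pre" is the reported direction
  relabel <- function(d) {
    d$session_ord <- ifelse(d$session == "pre", "a_pre", "b_post")
    d
  }
  pw <- relabel(cohort$power)
  pw <- pw[pw$region == "left_occipital" & pw$band == "low_gamma" &
             pw$phase == "retention" & pw$condition == "4T", ]
  cp <- relabel(cohort$coupling)
  cp <- cp[cp$measure == "PAC_MI" & cp$gamma_band == "low_gamma" &
             cp$phase == "retention" & cp$condition == "4T" &
             cp$amp_region == "left_occipital", ]
  bh <- relabel(cohort$behavior)
  bh <- bh[bh$condition == "4T", ]

  res <- rbind(
    run_contrast(pw, "power", "session_ord", test = "paired_t",
                 subject = "subject",
                 contrast = "left_occipital_low_gamma_post_vs_pre",
                 family = "power"),
    run_contrast(cp, "value", "session_ord", test = "paired_t",
                 subject = "subject",
                 contrast = "frontal_theta_occipital_gamma_mi_post_vs_pre",
                 family = "coupling")
  )

  delta_of <- function(d, col) {
    wide <- merge(d[d$session == "pre", c("subject", col)],
                  d[d$session == "post", c("subject", col)],
                  by = "subject", suffixes = c("_pre", "_post"))
    data.frame(subject = wide$subject,
               delta = wide[[paste0(col, "_post")]] -
                 wide[[paste0(col, "_pre")]],
               stringsAsFactors = FALSE)
  }
  d_gamma <- delta_of(pw, "power")
  d_k <- delta_of(bh, "k")
  res <- rbind(res, correlate_change(d_gamma, d_k,
                                     contrast = "delta_gamma_vs_delta_k"))
  list(results = adjust_families(res),
       deltas = merge(d_gamma, d_k, by = "subject",
                      suffixes = c("_gamma", "_k")))
}
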