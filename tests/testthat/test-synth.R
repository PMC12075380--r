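test_that("synth_config validates its invariants", {
  expect_s3_class(fast_config(), "synth_config")
  expect_error(fast_config(modulation_depth = 1.2), "modulation_depth")
  expect_error(fast_config(hit_rate = 1.5), "probabilities")
  expect_error(fast_config(sampling_rate = 120), "twice the 95 Hz")
  expect_error(fast_config(theta_freq = 50, gamma_freq = 40), "exceed")
  expect_error(fast_config(gamma_freq = 130, sampling_rate = 250), "30, 80")
  expect_error(fast_config(artifact_rate = 0.1, artifact_gain = 4), "exceed 5")
})

test_that("pac signal with zero depth has a flat gamma envelope and zero MI", {
  cfg <- fast_config(noise_sd = 0, theta_freq = 6, gamma_freq = 40,
                     sampling_rate = 500)
  x <- generate_pac_signal(cfg, channel_depth = 0, duration_s = 8)
  gamma <- analytic_signal(x, c(30, 60), 500)
  theta <- analytic_signal(x, c(4, 8), 500)
  core <- 500:3500                       # away from filter edges
  expect_lt(stats::sd(gamma$amplitude[core]) / mean(gamma$amplitude[core]),
            0.02)
  expect_lt(modulation_index(theta$phase[core], gamma$amplitude[core]), 1e-3)
})

test_that("injected envelope is recovered by the analytic amplitude", {
  cfg <- fast_config(noise_sd = 0, sampling_rate = 500, theta_freq = 6,
                     gamma_freq = 40)
  for (d in c(0.5, 1)) {
    x <- generate_pac_signal(cfg, channel_depth = d, duration_s = 8)
    t <- (seq_along(x) - 1) / 500
    env <- cfg$gamma_amp * ((1 - d) + d * (1 + cos(2 * pi * 6 * t)) / 2)
    rec <- analytic_signal(x, c(30, 60), 500)$amplitude
    core <- 500:3500
    expect_gt(stats::cor(env[core], rec[core]), 0.95)
  }
})

test_that("deeper modulation gives larger MI (paired over replicate seeds)", {
  wins <- 0L
  for (s in 1:20) {
    mi <- vapply(c(0.2, 0.8), function(d) {
      cfg <- fast_config(noise_sd = 2, sampling_rate = 250, seed = s)
      x <- generate_pac_signal(cfg, channel_depth = d, duration_s = 8)
      th <- analytic_signal(x, c(4, 8), 250)
      ga <- analytic_signal(x, c(30, 60), 250)
      modulation_index(th$phase, ga$amplitude)
    }, numeric(1))
    if (mi[2] > mi[1]) wins <- wins + 1L
  }
  # sign test: 20/20 expected under a real effect, >= 15 is already p < 1e-2
  expect_gte(wins, 15L)
})

test_that("recording generation is deterministic and marker-complete", {
  cfg <- fast_config(n_channels = 6, n_trials_per_condition = 5,
                     artifact_rate = 0.1, artifact_gain = 10)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$recording$events, b$recording$events)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_equal(nrow(a$recording$events), 10)
  expect_equal(sum(grepl("2T$", a$recording$events$code)), 5)
  beh1 <- generate_behavior(cfg)
  beh2 <- generate_behavior(cfg)
  expect_identical(beh1, beh2)
})

test_that("trial spacing keeps -1000..+2000 ms epochs non-overlapping", {
  cfg <- fast_config(n_channels = 4, n_trials_per_condition = 10)
  rec <- generate_recording(cfg)$recording
  gaps <- diff(rec$events$sample) / rec$sampling_rate
  expect_true(all(gaps >= 3.5 - 1e-9))
  expect_true(all(gaps <= 4.5 + 1e-9))
})

test_that("artifact bookkeeping matches the injection rate", {
  cfg0 <- fast_config(n_channels = 4, artifact_rate = 0)
  expect_length(generate_recording(cfg0)$ground_truth$artifact_segments, 0)
  cfg1 <- fast_config(n_channels = 4, n_trials_per_condition = 10,
                      artifact_rate = 0.2, artifact_gain = 12, seed = 7)
  gt <- generate_recording(cfg1)$ground_truth
  expect_gt(length(gt$artifact_segments), 0)
  n_seg <- floor((max(gt$trials$onset_sample) + 3 * 250) / (2 * 250))
  expect_true(all(gt$artifact_segments >= 1 & gt$artifact_segments <= n_seg))
})

test_that("noiseless signal variance concentrates in the injected bands", {
  cfg <- fast_config(noise_sd = 0, sampling_rate = 500, theta_freq = 6,
                     gamma_freq = 40)
  x <- generate_pac_signal(cfg, channel_depth = 0.7, duration_s = 2)
  sp <- spectrum_fft(x, 500)
  in_band <- band_power(sp, 4, 8) + band_power(sp, 30, 60)
  expect_gt(in_band / sum(sp$power), 0.99)
})

test_that("behaviour rates converge to configuration and support K recovery", {
  cfg <- fast_config(n_channels = 4, n_trials_per_condition = 5000,
                     hit_rate = 0.85, fa_rate = 0.15, seed = 11)
  log <- generate_behavior(cfg)
  beh <- summarize_behavior(log)
  r4 <- beh[beh$condition == "4T", ]
  se <- sqrt(0.85 * 0.15 / 2500)
  expect_lt(abs(r4$hit_rate - 0.85), 4 * se)
  expect_lt(abs(r4$fa_rate - 0.15), 4 * se)
  expect_true(all(log$rt_ms > 0))
  # ceiling and chance performance
  k_ceiling <- summarize_behavior(generate_behavior(
    fast_config(n_channels = 4, hit_rate = 1, fa_rate = 0)))
  expect_equal(k_ceiling$k[k_ceiling$condition == "2T"], 2)
  cfg_chance <- fast_config(n_channels = 4, n_trials_per_condition = 4000,
                            hit_rate = 0.5, fa_rate = 0.5, seed = 5)
  k_chance <- summarize_behavior(generate_behavior(cfg_chance))
  expect_lt(max(abs(k_chance$k)), 0.25)
})
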