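make_segmented_recording <- function(n_seg = 20, fs = 250, scale = NULL,
                                     events = NULL) {
  # unit-RMS sinusoid so per-segment intensity is known exactly
  n <- n_seg * 2 * fs
  x <- sqrt(2) * sin(2 * pi * 10 * (seq_len(n) - 1) / fs)
  if (!is.null(scale)) {
    for (s in names(scale)) {
      idx <- ((as.integer(s) - 1) * 2 * fs + 1):(as.integer(s) * 2 * fs)
      x[idx] <- x[idx] * scale[[s]]
    }
  }
  ev <- if (is.null(events)) data.frame(sample = integer(0),
                                        code = character(0)) else events
  eeg_recording(matrix(x, 1), fs, "Cz", ev)
}

test_that("constant-intensity recordings lose no segments", {
  res <- reject_segments(make_segmented_recording())
  expect_equal(sum(res$log$removed), 0)
  expect_equal(ncol(res$recording$samples), 20 * 2 * 250)
})

test_that("a single 10x segment is excised and its events dropped", {
  ev <- data.frame(sample = c(3 * 500 + 100, 5 * 2 * 250 + 50),
                   code = c("arrow_2T", "arrow_4T"))
  rec <- make_segmented_recording(scale = list("4" = 10), events = ev)
  res <- reject_segments(rec)
  expect_equal(which(res$log$removed), 4)
  # event in segment 4 dropped; later event shifted left by one segment
  expect_equal(nrow(res$recording$events), 1)
  expect_equal(res$recording$events$sample, 5 * 2 * 250 + 50 - 500)
  expect_equal(res$recording$events$code, "arrow_4T")
})

test_that("a segment at exactly the 5x threshold is retained", {
  # 19 unit segments and one at amplitude a: threshold = 5*(19 + a)/20,
  # a = 95/15 puts the segment exactly at 5x the mean -> strict > keeps it
  a <- 95 / 15
  res <- reject_segments(make_segmented_recording(scale = list("7" = a)))
  expect_equal(sum(res$log$removed), 0)
  res2 <- reject_segments(make_segmented_recording(scale = list("7" = a * 1.01)))
  expect_equal(which(res2$log$removed), 7)
})

test_that("segment rejection is idempotent", {
  rec <- make_segmented_recording(scale = list("4" = 10))
  first <- reject_segments(rec)
  second <- reject_segments(first$recording)
  expect_equal(sum(second$log$removed), 0)
})

test_that("rejection refuses to remove everything", {
  rec <- make_segmented_recording(n_seg = 2)
  rec$samples <- rec$samples * 0 + 1e6   # both segments identical -> mean equal
  expect_equal(sum(reject_segments(rec)$log$removed), 0)
  short <- eeg_recording(matrix(1, 1, 100), 250, "Cz")
  expect_error(reject_segments(short), "shorter")
})

test_that("filter chain meets its attenuation contract", {
  rms <- function(rec) sqrt(mean(rec$samples^2))
  line <- sine_recording(50)
  expect_lt(rms(filter_chain(line)) / rms(line), 0.1)       # >= 20 dB down
  theta <- sine_recording(6)
  expect_gt(rms(filter_chain(theta)) / rms(theta), 0.95)    # <= ~0.5 dB
  alpha <- sine_recording(10)
  expect_gt(rms(filter_chain(alpha)) / rms(alpha), 0.891)   # <= 1 dB
  gamma <- sine_recording(40)
  expect_gt(rms(filter_chain(gamma)) / rms(gamma), 0.891)
  # DC sits below the 0.5 Hz edge; judge away from filtfilt edge transients
  dc <- eeg_recording(matrix(5, 1, 20000), 1000, "Cz")
  dc_mid <- filter_chain(dc)$samples[1, 5000:15000]
  expect_lt(sqrt(mean(dc_mid^2)), 0.05 * 5)
  slow <- eeg_recording(matrix(rnorm(100), 1), 150, "Cz")
  expect_error(filter_chain(slow), "too low")
})

test_that("zero-phase filtering leaves pass-band phase undistorted", {
  rec <- sine_recording(6, dur_s = 20)
  out <- filter_chain(rec)
  core <- 2000:18000
  expect_gt(stats::cor(rec$samples[1, core], out$samples[1, core]), 0.999)
})

test_that("epoching applies the +/-100 uV rule per trial", {
  fs <- 250
  n <- 10 * fs
  x <- matrix(sin(2 * pi * 6 * (seq_len(n) - 1) / fs) * 50, 1)
  ev <- data.frame(sample = c(2 * fs, 4.5 * fs, 7.5 * fs),
                   code = c("arrow_2T", "arrow_4T", "arrow_4T"))
  # push one sample of the second epoch just over threshold on one channel
  x[1, 4.5 * fs + 10] <- 101
  rec <- eeg_recording(x, fs, "Cz", ev)
  ep <- make_epochs(rec)
  expect_equal(dim(ep$epochs), c(3, 1, 3 * fs))
  expect_equal(ep$kept_mask, c(TRUE, FALSE, TRUE))
  x2 <- x; x2[1, 4.5 * fs + 10] <- 99
  ep2 <- make_epochs(eeg_recording(x2, fs, "Cz", ev))
  expect_equal(ep2$kept_mask, c(TRUE, TRUE, TRUE))
})

test_that("boundary trials are dropped, in-bounds trials epoched per condition", {
  cfg <- fast_config(n_channels = 4, n_trials_per_condition = 6)
  rec <- generate_recording(cfg)$recording
  ep <- make_epochs(rec)
  expect_equal(length(ep$kept_mask), 12)
  expect_equal(as.integer(table(ep$condition)), c(6L, 6L))
  # an event too close to the start is dropped and logged
  ev <- rbind(data.frame(sample = 10L, code = "arrow_2T"), rec$events)
  rec2 <- eeg_recording(rec$samples, rec$sampling_rate, rec$channel_names, ev)
  ep2 <- make_epochs(rec2)
  expect_equal(attr(ep2, "dropped_boundary"), 1L)
  expect_equal(length(ep2$kept_mask), 12)
})

test_that("phase windows are disjoint, ordered and correctly placed", {
  pw <- phase_windows(250)
  expect_named(pw, c("attention", "encoding", "retention"))
  expect_equal(pw$attention[1], 250 + 1)     # 0 ms post-arrow, 1000 ms pre-roll
  expect_equal(length(pw$attention), 125)    # 500 ms
  expect_equal(length(pw$retention), 250)    # 1000 ms
  all_idx <- unlist(pw)
  expect_false(anyDuplicated(all_idx) > 0)
  expect_true(all(diff(all_idx) == 1))
})

test_that("ICA stage is identity when off and near-identity on clean data", {
  cfg <- fast_config(n_channels = 24, n_trials_per_condition = 3,
                     noise_sd = 3)
  rec <- generate_recording(cfg)$recording
  expect_identical(remove_artifact_components(rec, enabled = FALSE), rec)
  out <- remove_artifact_components(rec, enabled = TRUE)
  cors <- vapply(seq_len(nrow(rec$samples)), function(i) {
    stats::cor(rec$samples[i, ], out$samples[i, ])
  }, numeric(1))
  expect_gt(min(cors), 0.95)
})

test_that("a blink-like frontal transient loses variance under ICA", {
  cfg <- fast_config(n_channels = 24, n_trials_per_condition = 4,
                     noise_sd = 3, seed = 9)
  rec <- generate_recording(cfg)$recording
  frontal <- grepl("^(Fp|AF)", rec$channel_names)
  n <- ncol(rec$samples)
  blink <- numeric(n)
  centers <- seq(500, n - 500, by = 1000)
  for (c0 in centers) {
    idx <- (c0 - 75):(c0 + 75)
    blink[idx] <- blink[idx] + 120 * exp(-((idx - c0) / 30)^2)
  }
  rec$samples[frontal, ] <- rec$samples[frontal, ] +
    matrix(rep(blink, sum(frontal)), nrow = sum(frontal), byrow = TRUE) *
    seq(1, 0.5, length.out = sum(frontal))
  out <- remove_artifact_components(rec, enabled = TRUE)
  expect_lt(mean(apply(out$samples[frontal, ], 1, var)),
            mean(apply(rec$samples[frontal, ], 1, var)))
})

test_that("the full preprocessing chain records its provenance", {
  cfg <- fast_config(n_channels = 6, n_trials_per_condition = 4,
                     artifact_rate = 0.05, artifact_gain = 12, seed = 3)
  rec <- generate_recording(cfg)$recording
  res <- preprocess(rec)
  expect_equal(res$provenance$stages,
               c("reject_segments", "filter_chain", "make_epochs"))
  expect_equal(res$provenance$epochs_total, length(res$epochs$kept_mask))
  expect_s3_class(res$rejection_log, "data.frame")
})
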