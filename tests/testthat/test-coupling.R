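test_that("analytic phase advances at the oscillation frequency", {
  fs <- 1000
  x <- sin(2 * pi * 6 * (seq_len(5 * fs) - 1) / fs)
  a <- analytic_signal(x, c(4, 8), fs)
  dphi <- atan2(sin(diff(a$phase)), cos(diff(a$phase)))
  slope <- mean(dphi[500:4500])
  expect_lt(abs(slope - 2 * pi * 6 / fs) / (2 * pi * 6 / fs), 0.01)
})

test_that("analytic envelope recovers constant and modulated amplitudes", {
  fs <- 500
  t <- (seq_len(5 * fs) - 1) / fs
  core <- 250:2250
  a <- analytic_signal(3.5 * sin(2 * pi * 40 * t), c(30, 60), fs)
  expect_lt(max(abs(a$amplitude[core] - 3.5)) / 3.5, 0.02)
  env <- 1 + 0.8 * cos(2 * pi * 5 * t)
  b <- analytic_signal(env * sin(2 * pi * 40 * t), c(30, 60), fs)
  expect_gt(stats::cor(env[core], b$amplitude[core]), 0.99)
  expect_error(analytic_signal(rnorm(100), c(4, 8), 500), "at least")
  expect_error(analytic_signal(rnorm(1000), c(30, 300), 500), "Nyquist")
})

test_that("MI limits: uniform distribution 0, single-bin mass 1", {
  expect_equal(mi_from_distribution(rep(1, 18)), 0)
  expect_equal(mi_from_distribution(c(5, rep(0, 17))), 1)
  phase <- runif(5000, -pi, pi)
  expect_lt(modulation_index(phase, rep(2, 5000)), 1e-3)
  # all amplitude concentrated at one phase
  expect_equal(modulation_index(rep(0.1, 1000), rep(1, 1000)), 1)
  expect_error(modulation_index(phase, numeric(5000)), "all-zero")
  expect_error(mi_from_distribution(c(-1, 1)), "non-negative")
  expect_error(modulation_index(1:3, 1:2), "lengths differ")
})

test_that("MI on the closed-form cosine-envelope masses matches the oracle", {
  q <- cosine_bin_masses(18)
  expect_equal(mi_from_distribution(q), mi_oracle(q), tolerance = 1e-10)
  # and via the sample path: uniform dense phase grid, exact envelope
  phase <- seq(-pi, pi - 1e-9, length.out = 18 * 2000)
  amp <- (1 + cos(phase)) / 2
  mi_sampled <- modulation_index(phase, amp)
  # Riemann bin means converge to the integral masses at O(1/n) only
  expect_equal(mi_sampled, mi_oracle(q), tolerance = 1e-3)
})

test_that("binned MI equals an independent per-sample brute-force loop", {
  set.seed(3)
  for (r in 1:5) {
    n <- sample(c(500, 2000, 10000), 1)
    phase <- runif(n, -pi, pi)
    amp <- rexp(n) * (1 + 0.5 * cos(phase))
    expect_equal(modulation_index(phase, amp),
                 mi_bruteforce_samples(phase, amp), tolerance = 1e-12)
  }
})

test_that("MI is invariant to amplitude scale and bounded in [0, 1]", {
  set.seed(4)
  for (r in 1:20) {
    n <- 1000
    phase <- runif(n, -pi, pi)
    amp <- rexp(n) * (1 + runif(1) * cos(phase + runif(1, -pi, pi)))
    mi <- modulation_index(phase, amp)
    expect_gte(mi, 0); expect_lte(mi, 1)
    expect_equal(modulation_index(phase, 10 * amp), mi, tolerance = 1e-12)
  }
})

test_that("mean MI increases strictly with modulation depth", {
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  mi <- matrix(0, 10, length(depths))
  for (s in 1:10) {
    for (j in seq_along(depths)) {
      cfg <- fast_config(noise_sd = 2, sampling_rate = 250, seed = 100 + s)
      x <- generate_pac_signal(cfg, channel_depth = depths[j], duration_s = 6)
      th <- analytic_signal(x, c(4, 8), 250)
      ga <- analytic_signal(x, c(30, 60), 250)
      mi[s, j] <- modulation_index(th$phase, ga$amplitude)
    }
  }
  expect_true(all(diff(colMeans(mi)) > 0))
})

test_that("PPC is 1 under perfect n:m locking and offset-invariant", {
  phi_s <- seq(0, 40 * pi, length.out = 5000)
  phi_f <- 6 * phi_s
  expect_equal(phase_phase_coupling(phi_s, phi_f, 1, 6), 1)
  expect_equal(phase_phase_coupling(phi_s, phi_f + 1.3, 1, 6),
               phase_phase_coupling(phi_s, phi_f, 1, 6), tolerance = 1e-12)
  expect_error(phase_phase_coupling(numeric(0), numeric(0)), "empty")
  expect_error(phase_phase_coupling(phi_s, phi_f, 0.5, 6), "positive integers")
})

test_that("PPC of independent phases sits at the Rayleigh null level", {
  set.seed(6)
  T_ <- 10000
  vals <- replicate(100, phase_phase_coupling(runif(T_, -pi, pi),
                                              runif(T_, -pi, pi)))
  # E[PPC] ~ sqrt(pi)/(2 sqrt(T)) ~ 0.0089; nearly all below 0.05
  expect_gte(mean(vals < 0.05), 0.95)
  expect_lt(mean(vals), 3 * sqrt(pi) / (2 * sqrt(T_)))
})

test_that("null MI shrinks with window length (estimator bias)", {
  set.seed(7)
  fs <- 250
  mi_short <- mi_long <- numeric(30)
  for (r in 1:30) {
    x <- rnorm(3 * fs)
    th <- analytic_signal(x, c(4, 8), fs)
    ga <- analytic_signal(x, c(30, 60), fs)
    mi_short[r] <- modulation_index(th$phase[1:125], ga$amplitude[1:125])
    mi_long[r] <- modulation_index(th$phase[1:250], ga$amplitude[1:250])
  }
  expect_lt(mean(mi_long), mean(mi_short))
})

test_that("region-pair coupling recovers injected coupling and its grid", {
  mk_epochs <- function(depth, seed) {
    cfg <- fast_config(channels = mini_channels(), n_channels = NULL,
                       n_trials_per_condition = 3, noise_sd = 2,
                       modulation_depth = depth,
                       gamma_channels = c("P3", "O1", "P4", "O2"),
                       seed = seed)
    preprocess(generate_recording(cfg)$recording)$epochs
  }
  wins <- 0L
  for (s in 1:8) {
    cp_hi <- couple_regions(mk_epochs(0.8, 200 + s), regions = mini_regions())
    cp_lo <- couple_regions(mk_epochs(0.0, 200 + s), regions = mini_regions())
    mi_hi <- mean(cp_hi$value[cp_hi$measure == "PAC_MI"])
    mi_lo <- mean(cp_lo$value[cp_lo$measure == "PAC_MI"])
    if (mi_hi > mi_lo) wins <- wins + 1L
  }
  expect_gte(wins, 7L)

  cp <- couple_regions(mk_epochs(0.8, 300), regions = mini_regions())
  # 3 windows x 2 gamma sub-bands x 2 measures per condition and pair
  expect_equal(nrow(cp), 2 * 12)
  expect_true(all(cp$value >= 0 & cp$value <= 1))
  expect_equal(unique(cp$low_confidence), FALSE)   # windows are >= 500 ms
})

test_that("coupling values ignore a scale change of the amplitude region", {
  cfg <- fast_config(channels = mini_channels(), n_channels = NULL,
                     n_trials_per_condition = 2, noise_sd = 1,
                     modulation_depth = 0.8,
                     gamma_channels = c("P3", "O1"), seed = 12)
  ep <- preprocess(generate_recording(cfg)$recording)$epochs
  ep10 <- ep
  occ <- match(c("P3", "O1"), ep$channel_names)
  ep10$epochs[, occ, ] <- ep10$epochs[, occ, ] * 10
  a <- couple_regions(ep, regions = mini_regions())
  b <- couple_regions(ep10, regions = mini_regions())
  expect_equal(a$value, b$value, tolerance = 1e-9)
})
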