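test_that("Fourier coefficient agrees with the brute-force complex sum", {
  g <- sim_grid(0.1, 1000)
  set.seed(5)
  for (rep in 1:5) {
    sp <- sort(sample(g$times, 40))
    for (F in c(3.7, 10, 100.2, 513)) {
      expect_equal(fourier_coefficient(g, sp, F),
                   oracle_fc(g$dt, g$duration, sp, F),
                   tolerance = 1e-9)
    }
  }
})

test_that("FC has the closed-form values for elementary trains", {
  g <- sim_grid(0.1, 1000)  # L = 1 s
  # empty train: zero at every frequency, FC_avg 0, normalized set to 0
  expect_equal(fourier_coefficient(g, numeric(0), c(0, 5, 100)), rep(0, 3))
  expect_equal(mean_coefficient(g, numeric(0)), 0)
  expect_equal(transmission_metrics(g, numeric(0), 5)$fc_norm, 0)
  # single spike: FC = 2/L at all frequencies, so FC_avg = 2/L
  expect_equal(fourier_coefficient(g, 100, c(0, 5, 77.7)), rep(2, 3))
  expect_equal(mean_coefficient(g, 100), 2)
  # periodic train, one spike per 10 ms: FC at 100 Hz = 2 * n_spikes / L
  comb <- seq(0, 990, by = 10)
  expect_equal(fourier_coefficient(g, comb, 100), 2 * length(comb) / 1)
  # millisecond comb has no energy at 7 Hz (orthogonality off-harmonic)
  dense <- seq(0, 999, by = 1)
  expect_lt(fourier_coefficient(g, dense, 7), 1e-8)
  # FC at F = 0 equals twice the mean rate
  set.seed(2)
  sp <- sort(sample(g$times, 55))
  expect_equal(fourier_coefficient(g, sp, 0), 2 * length(sp) / 1)
})

test_that("FC on the FFT grid matches the FFT of the count sequence", {
  g <- sim_grid(0.5, 500)
  set.seed(11)
  sp <- sort(sample(g$times, 30))
  counts <- spike_counts(g, sp)
  L_s <- 0.5
  mags <- (2 / L_s) * Mod(stats::fft(counts))
  for (k in c(0, 1, 7, 250)) {
    expect_equal(fourier_coefficient(g, sp, k / L_s),
                 mags[(k %% g$n_steps) + 1], tolerance = 1e-9)
  }
  # FC_avg never exceeds the maximum FC on the grid, and single-spike
  # equality shows the mean includes both endpoints consistently
  expect_lte(mean_coefficient(g, sp), max(mags))
  expect_lt(mean_coefficient(g, sp, include_dc = FALSE),
            mean_coefficient(g, sp))
})

test_that("constant-rate Poisson trains sit on the analytic noise floor", {
  # E[FC] for F >> 1/L is sqrt(pi * c / L); constant frozen after
  # Monte-Carlo derivation
  g <- sim_grid(0.1, 1000)
  c_rate <- 40
  set.seed(31)
  fcs <- replicate(100, {
    sp <- poisson_spikes(g, rate_profile("constant", PR = c_rate))
    fourier_coefficient(g, sp, 313)
  })
  expect_equal(mean(fcs), sqrt(pi * c_rate / 1), tolerance = 0.1)
})

test_that("half-maximum cutoff interpolates in log frequency", {
  freqs <- c(5, 10, 20)
  vals <- c(10, 6, 4)
  # target 5 crossed between 10 and 20 Hz: exp(log 10 + 0.5 log 2)
  expect_equal(half_cutoff(freqs, vals), 10 * sqrt(2), tolerance = 1e-9)
  # invariant to rescaling all values
  expect_equal(half_cutoff(freqs, 17 * vals), half_cutoff(freqs, vals))
  # no crossing -> NA
  expect_true(is.na(half_cutoff(freqs, c(10, 9, 8))))
  expect_error(half_cutoff(c(10, 20), c(1, 2)), "reference")
})

test_that("transmission_sweep averages each metric over trials", {
  g <- sim_grid(0.1, 1000)
  comb <- seq(0, 990, by = 10)
  runner <- function(F, trial) list(grid = g, spike_times = comb)
  sw <- transmission_sweep(runner, c(5, 100), n_trials = 3)
  expect_s3_class(sw, "transmission_curve")
  expect_equal(sw$fc_f[sw$frequency_hz == 100], 200)
  expect_equal(attr(sw, "n_trials"), 3)
  # deterministic runner: averaging over trials changes nothing
  sw1 <- transmission_sweep(runner, c(5, 100), n_trials = 1)
  expect_equal(sw$fc_f, sw1$fc_f)
})

test_that("spectrogram tracks a stepped input frequency", {
  g <- sim_grid(0.1, 2000)
  sched <- data.frame(duration_ms = c(1000, 1000), F_hz = c(10, 50))
  set.seed(8)
  # dense deterministic rate-following train: spikes at rate peaks
  sp <- poisson_spikes(g, stepped_frequency_profile(sched, PR = 900))
  m <- spectrogram(g, sp, bin_length = 200, frequencies = c(10, 50))
  expect_equal(dim(m), c(2, 10))
  early <- m[, 1:5]
  late <- m[, 6:10]
  expect_true(all(early["10", ] > early["50", ]))
  expect_true(all(late["50", ] > late["10", ]))
  # stationary case: every bin peaks at the modulation frequency
  sp10 <- poisson_spikes(g, rate_profile(PR = 900, F = 10))
  m10 <- spectrogram(g, sp10, 200, c(10, 50))
  expect_true(all(m10["10", ] > m10["50", ]))
  # empty train: all zero
  expect_true(all(spectrogram(g, numeric(0), 200, c(10, 50)) == 0))
  expect_error(spectrogram(g, sp, 300, 10), "divide")
})
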