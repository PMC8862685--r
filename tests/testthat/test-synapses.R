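test_that("kernel normalization matches a dense-grid search of the peak", {
  for (taus in list(c(1, 20), c(1, 50), c(0.7, 1.6), c(3.2, 100))) {
    o <- oracle_kernel_peak(taus[1], taus[2])
    B <- kernel_normalization(taus[1], taus[2])
    expect_equal(B, 1 / o$peak, tolerance = 1e-6)
    expect_equal(kernel_peak_time(taus[1], taus[2]), o$t_peak,
                 tolerance = 1e-3)
    expect_gte(B, 1)
  }
  # frozen values from the oracle
  expect_equal(kernel_normalization(1, 20), 1.2324, tolerance = 1e-4)
  expect_equal(kernel_normalization(1, 50), 1.1052, tolerance = 1e-4)
  expect_error(kernel_normalization(20, 20), "tau_rise")
})

test_that("single-spike trace peaks at P_max at the analytic peak time", {
  g <- sim_grid(0.01, 100)
  k <- syn_kernel(P_max = 1.21, tau_rise = 1, tau_fall = 20, V_syn = 0)
  tr <- conductance_from_spikes(g, 0, k)
  expect_equal(max(tr), 1.21, tolerance = 1e-4)
  expect_equal(g$times[which.max(tr)], kernel_peak_time(1, 20),
               tolerance = 0.02)
  expect_true(all(tr >= 0))
})

test_that("conductance superposition is linear and matches brute force", {
  g <- sim_grid(0.1, 300)
  k <- syn_kernel(P_max = 0.5, tau_rise = 1, tau_fall = 20, V_syn = 0,
                  delay = 1)
  a <- c(10, 50.5, 120)
  b <- c(11, 80)
  tr_union <- conductance_from_spikes(g, sort(c(a, b)), k)
  tr_sum <- conductance_from_spikes(g, a, k) + conductance_from_spikes(g, b, k)
  expect_equal(tr_union, tr_sum, tolerance = 1e-9)
  brute <- oracle_conductance(g, sort(c(a, b)), 0.5, 1, 20, delay = 1)
  expect_equal(tr_union, brute, tolerance = 1e-6)
})

test_that("kernel integral matches quadrature of the generated trace", {
  g <- sim_grid(0.1, 2000)  # ~100 fall time constants
  k <- syn_kernel(P_max = 1.21, tau_rise = 1, tau_fall = 20, V_syn = 0)
  tr <- conductance_from_spikes(g, 0, k)
  expect_equal(sum(tr) * g$dt, kernel_integral(k), tolerance = 5e-3)
})

test_that("E/I balancing reproduces all published weight pairs", {
  rows <- model_parameters()$triad_tau_fall_i_rows
  for (i in seq_len(nrow(rows))) {
    got <- balanced_inhibitory_peak(rows$P_max_e_us[i], c(1, 20),
                                    c(1, rows$tau_fall_i_ms[i]))
    expect_equal(signif(got, 3), signif(rows$P_max_i_us[i], 3),
                 tolerance = 5e-3)
  }
  expect_equal(balanced_inhibitory_peak(0.7, c(1, 20), c(1, 20)), 0.7)
})

test_that("depression amplitudes follow the two-factor recursion", {
  ampa <- depression_preset("AMPA")
  expect_equal(depression_amplitudes(0, ampa), ampa$A0)
  # two spikes 50 ms apart: frozen from direct evaluation of the recursion
  amps <- depression_amplitudes(c(0, 50), ampa)
  expect_equal(amps[2], 0.3396, tolerance = 1e-3)
  # full recovery after long silence
  long <- depression_amplitudes(
    c(0, 50, 50 + 30 * max(ampa$tau_d1, ampa$tau_d2)), ampa)
  expect_equal(long[3], ampa$A0, tolerance = 1e-6)
})

test_that("depression is non-increasing on a constant-ISI train and matches
           an event-by-event simulation", {
  for (rec in c("AMPA", "NMDA", "GABA")) {
    p <- depression_preset(rec)
    train <- seq(0, 2000, by = 25)
    amps <- depression_amplitudes(train, p)
    expect_true(all(diff(amps) <= 1e-12))
    # fixed-point convergence
    expect_lt(abs(amps[length(amps)] - amps[length(amps) - 1]), 1e-4)
    # brute-force fine-clock simulation agrees
    short <- c(0, 18, 44, 100, 103, 400)
    expect_equal(depression_amplitudes(short, p),
                 oracle_depression(short, p, dt = 0.005),
                 tolerance = 1e-3)
  }
})

test_that("FFEI projection reduces to FFE when inhibition is absent", {
  g <- sim_grid(0.1, 500)
  e <- syn_kernel(P_max = 0.5, tau_rise = 1, tau_fall = 20, V_syn = 0)
  i0 <- syn_kernel(P_max = 0, tau_rise = 1, tau_fall = 20, V_syn = -80,
                   delay = 1, alpha = 1.25)
  sp <- c(10, 30, 31, 200)
  expect_length(make_ffei_projection(g, sp, e, i0), 1)
  expect_length(make_ffei_projection(g, sp, e, NULL), 1)
  expect_equal(make_ffei_projection(g, sp, e, i0)[[1]]$g,
               conductance_from_spikes(g, sp, e))
  # mixed-sign negative swaps the leading kernel
  i <- syn_kernel(P_max = 0.5, tau_rise = 1, tau_fall = 20, V_syn = -80,
                  delay = 1, alpha = 1.25)
  neg <- make_ffei_projection(g, sp, e, i, mixed_sign_negative = TRUE)
  expect_equal(neg[[1]]$V_syn, -80)
  expect_equal(neg[[2]]$V_syn, 0)
})
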