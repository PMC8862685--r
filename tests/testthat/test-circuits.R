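test_that("FFEI with zero inhibition is spike-identical to FFE", {
  ffe <- run_triad(F = 20, mode = "ffe", P_max_e = 0.3, n_trials = 2,
                   seed = 5, duration = 2000)
  ffei0 <- run_triad(F = 20, mode = "ffei", P_max_e = 0.3, P_max_i = 0,
                     n_trials = 2, seed = 5, duration = 2000)
  # alpha = 0 disables inhibition through the current scaling instead
  ffei_a0 <- run_triad(F = 20, mode = "ffei", P_max_e = 0.3, P_max_i = 0.3,
                       alpha = 0, n_trials = 2, seed = 5, duration = 2000)
  for (k in 1:2) {
    expect_identical(ffei0$trials[[k]]$spike_times,
                     ffe$trials[[k]]$spike_times)
    expect_identical(ffei_a0$trials[[k]]$spike_times,
                     ffe$trials[[k]]$spike_times)
  }
})

test_that("triad FFEI output locks to the input modulation", {
  res <- run_triad(F = 50, n_trials = 3, seed = 2, duration = 3000)
  m <- sapply(res$trials, function(tr) {
    tm <- transmission_metrics(tr$grid, tr$spike_times, 50)
    c(tm$fc_f, tm$fc_norm)
  })
  expect_gt(mean(m[1, ]), 30)   # strong component at F
  expect_gt(mean(m[2, ]), 5)    # far above a frequency-nonspecific output
})

test_that("default inhibitory weight is balanced from the fall time", {
  k25 <- ffeisim:::triad_kernels("ffei", 0.883, NULL, 25, 1, 1.25)
  expect_equal(signif(k25$i$P_max, 3), 0.723, tolerance = 5e-3)
  k20 <- ffeisim:::triad_kernels("ffei", NULL, NULL, 20, 1, 1.25)
  expect_equal(k20$i$P_max, k20$e$P_max)
  expect_error(run_triad(mode = "nonsense", n_trials = 1), "arg")
})

test_that("unconnected multilevel network ignores the input frequency", {
  rate_and_norm <- function(F) {
    res <- run_multilevel(F = F, mode = "nc", n_trials = 3, seed = 3,
                          duration = 3000)
    rates <- sapply(res$trials, function(tr) {
      length(tr$neurons$A4) / 3
    })
    norms <- sapply(res$trials, function(tr) {
      transmission_metrics(tr$grid, tr$neurons$A4, F)$fc_norm
    })
    c(rate = mean(rates), norm = mean(norms))
  }
  lo <- rate_and_norm(5)
  hi <- rate_and_norm(80)
  expect_gt(lo["rate"], 0)
  # firing statistics do not depend on the (unconnected) input frequency
  expect_lt(abs(lo["rate"] - hi["rate"]) / lo["rate"], 0.2)
  # no frequency preference: normalized transmission near 1
  expect_lt(lo["norm"], 3)
  expect_lt(hi["norm"], 3)
})

test_that("multilevel FFEI relays the modulation to level A4", {
  res <- run_multilevel(F = 5, mode = "ffei", n_trials = 2, seed = 4,
                        duration = 3000)
  fc <- sapply(res$trials, function(tr) {
    fourier_coefficient(tr$grid, tr$neurons$A4, 5)
  })
  nc <- run_multilevel(F = 5, mode = "nc", n_trials = 2, seed = 4,
                       duration = 3000)
  fc_nc <- sapply(nc$trials, function(tr) {
    fourier_coefficient(tr$grid, tr$neurons$A4, 5)
  })
  expect_gt(mean(fc), 2 * mean(fc_nc))
})

test_that("cortical interneuron is silenced at high input frequencies", {
  hi <- run_cortical_circuit(F = 90, n_trials = 1, seed = 3,
                             duration = 2000)
  lo <- run_cortical_circuit(F = 5, n_trials = 1, seed = 3,
                             duration = 2000)
  expect_length(hi$trials[[1]]$neurons$interneuron, 0)
  expect_gt(length(lo$trials[[1]]$neurons$interneuron), 10)
  # with a silent interneuron the FFEI circuit equals the FFE control
  ffe <- run_cortical_circuit(F = 90, mode = "ffe", n_trials = 1, seed = 3,
                              duration = 2000)
  expect_identical(hi$trials[[1]]$neurons$output,
                   ffe$trials[[1]]$neurons$output)
})

test_that("AMPA-only input kinetics let the interneuron follow 90 Hz", {
  res <- run_cortical_circuit(F = 90, n_trials = 1, seed = 3,
                              duration = 2000, ampa_only_to_I = TRUE)
  expect_gt(length(res$trials[[1]]$neurons$interneuron), 10)
})

test_that("XOR circuit is silent without input and responds at 2F", {
  silent <- run_xor(F = 5, PR = 0, n_trials = 1, seed = 1, duration = 1000)
  expect_length(silent$trials[[1]]$neurons$a2, 0)
  res <- run_xor(F = 5, mode = "mixed", n_trials = 2, seed = 1,
                 duration = 2000)
  fc <- sapply(res$trials, function(tr) {
    fourier_coefficient(tr$grid, tr$neurons$a2, c(5, 10))
  })
  # anti-phase inputs: output dominated by twice the input frequency
  expect_gt(mean(fc[2, ]), mean(fc[1, ]))
})

test_that("mixed-sign XOR beats single-sign at high frequency", {
  hi_m <- run_xor(F = 40, mode = "mixed", n_trials = 2, seed = 6,
                  duration = 2000)
  hi_s <- run_xor(F = 40, mode = "single", n_trials = 2, seed = 6,
                  duration = 2000)
  fc_m <- mean(sapply(hi_m$trials, function(tr) {
    fourier_coefficient(tr$grid, tr$neurons$a2, 80)
  }))
  fc_s <- mean(sapply(hi_s$trials, function(tr) {
    fourier_coefficient(tr$grid, tr$neurons$a2, 80)
  }))
  expect_gt(fc_m, fc_s)
})

test_that("receptor mixtures: AMPA-only locks better at high F than
           AMPA+NMDA, and GABA arms restore locking", {
  norm_at <- function(cond, F, dep = FALSE) {
    res <- run_receptor_mixture(cond, F = F, depressing = dep,
                                n_trials = 2, seed = 2, duration = 3000)
    mean(sapply(res$trials, function(tr) {
      transmission_metrics(tr$grid, tr$spike_times, F,
                           t_start = tr$analysis_start)$fc_norm
    }))
  }
  f_hi <- 80
  ampa <- norm_at("AMPA", f_hi)
  an <- norm_at("AMPA+NMDA", f_hi)
  ang <- norm_at("AMPA+NMDA+GABA", f_hi)
  expect_gt(ampa, an)
  expect_gt(ang, an)
})

test_that("depressing triad synapses favour the paired E/I arrangement", {
  norm_at <- function(cond, F) {
    res <- run_receptor_mixture(cond, F = F, depressing = TRUE,
                                n_trials = 2, seed = 2, duration = 4000)
    mean(sapply(res$trials, function(tr) {
      transmission_metrics(tr$grid, tr$spike_times, F,
                           t_start = tr$analysis_start)$fc_norm
    }))
  }
  expect_gt(norm_at("AMPA+NMDA+GABAA+GABAB", 40), norm_at("AMPA+NMDA", 40))
})
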