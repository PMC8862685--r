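# Independent brute-force oracles, kept free of the implementation paths
# they check.

# Dense-grid search for the unnormalized kernel maximum.
oracle_kernel_peak <- function(tau_rise, tau_fall, t_max = 200,
                               dt = 1e-4) {
  tt <- seq(0, t_max, by = dt)
  u <- exp(-tt / tau_fall) - exp(-tt / tau_rise)
  list(peak = max(u), t_peak = tt[which.max(u)])
}

# Direct complex DFT sum over spikes (no FFT).
oracle_fc <- function(dt_ms, L_ms, spike_times_ms, F) {
  dt_s <- dt_ms / 1000
  L_s <- L_ms / 1000
  t_s <- round(spike_times_ms / dt_ms) * dt_ms / 1000
  (2 / L_s) * Mod(sum(exp(-2i * pi * F * t_s)))
}

# Event-by-event depression simulation on a fine clock.
oracle_depression <- function(spike_times, p, dt = 0.001) {
  D1 <- 1; D2 <- 1; t_now <- 0
  amps <- numeric(length(spike_times))
  for (j in seq_along(spike_times)) {
    n_sub <- round((spike_times[j] - t_now) / dt)
    for (s in seq_len(n_sub)) {
      D1 <- D1 + dt * (1 - D1) / p$tau_d1
      D2 <- D2 + dt * (1 - D2) / p$tau_d2
    }
    t_now <- spike_times[j]
    amps[j] <- p$A0 * D1 * D2
    D1 <- D1 * p$d1
    D2 <- D2 * p$d2
  }
  amps
}

# Brute-force conductance superposition: explicit loop over spikes/steps.
oracle_conductance <- function(grid, spike_times, P_max, tau_rise, tau_fall,
                               delay = 0) {
  B <- 1 / oracle_kernel_peak(tau_rise, tau_fall)$peak
  g <- numeric(grid$n_steps)
  for (s in spike_times) {
    dtj <- grid$times - (s + delay)
    on <- dtj >= 0
    g[on] <- g[on] + P_max * B * (exp(-dtj[on] / tau_fall) -
                                  exp(-dtj[on] / tau_rise))
  }
  g
}

# Per-step window XOR by explicit counting.
oracle_xor <- function(grid, i1, i2, t_bin) {
  half <- round(t_bin / 2 / grid$dt) * grid$dt
  vapply(grid$times, function(t) {
    a <- sum(i1 >= t - half & i1 <= t + half) > 0
    b <- sum(i2 >= t - half & i2 <= t + half) > 0
    xor(a, b)
  }, logical(1))
}
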