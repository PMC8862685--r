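#' Per-step spike counts of a train
#'
#' Converts spike times to the per-step count sequence underlying the rate
#' signal `R(t)`: a spike in a step contributes `1/dt` Hz to that step, so
#' the Fourier sum over `R(t)` reduces to a sum over counts.
#'
#' @param grid A [sim_grid()].
#' @param spike_times Spike times (ms).
#' @return Integer vector of counts per grid step.
#' @export
spike_counts <- function(grid, spike_times) {
  counts <- integer(grid$n_steps)
  if (length(spike_times)) {
    idx <- as.integer(round(spike_times / grid$dt)) + 1L
    idx <- idx[idx >= 1L & idx <= grid$n_steps]
    tab <- tabulate(idx, nbins = grid$n_steps)
    counts <- tab
  }
  counts
}

# Restrict counts to the analysis window [t_start, duration); returns
# list(counts, L_s, dt_s).
window_counts <- function(grid, spike_times, t_start = 0) {
  counts <- spike_counts(grid, spike_times)
  if (t_start > 0) {
    k0 <- as.integer(round(t_start / grid$dt)) + 1L
    counts <- counts[k0:grid$n_steps]
  }
  list(counts = counts, dt_s = grid$dt / 1000,
       L_s = length(counts) * grid$dt / 1000)
}

#' Fourier coefficient of a spike train at one frequency
#'
#' Magnitude of the scaled discrete Fourier sum of the firing-rate signal,
#' \deqn{FC_F = |(2\Delta t/L) \sum_t R(t) e^{-2\pi i F t}|}
#' with `R(t)` in Hz and `t` in seconds, giving units of Hz. For `F` on the
#' FFT grid (multiples of `1/L`) this equals `2/L` times the FFT magnitude
#' of the spike-count sequence. At `F = 0` it equals twice the mean rate.
#'
#' @param grid A [sim_grid()].
#' @param spike_times Spike times (ms).
#' @param F Frequency (Hz), scalar or vector.
#' @param t_start Discard output before this time (ms) from the analysis.
#' @return Fourier coefficient magnitude(s), Hz.
#' @export
fourier_coefficient <- function(grid, spike_times, F, t_start = 0) {
  w <- window_counts(grid, spike_times, t_start)
  idx <- which(w$counts > 0)
  if (!length(idx)) return(rep(0, length(F)))
  t_s <- (idx - 1) * w$dt_s
  c_k <- w$counts[idx]
  vapply(F, function(f) {
    (2 / w$L_s) * Mod(sum(c_k * exp(-2i * pi * f * t_s)))
  }, numeric(1))
}

#' Mean Fourier coefficient over the full frequency grid
#'
#' Averages the Fourier coefficient over `F = 0, 1/L, 2/L, ..., 1/dt`
#' (inclusive of both endpoints; magnitudes above the Nyquist frequency are
#' aliases of conjugate bins). Computed with one FFT of the per-step spike
#' counts. Set `include_dc = FALSE` to drop the `F = 0` term.
#'
#' @inheritParams fourier_coefficient
#' @param include_dc Include the `F = 0` coefficient in the mean (default
#'   `TRUE`, matching the stated grid).
#' @return `FC_avg` in Hz.
#' @export
mean_coefficient <- function(grid, spike_times, t_start = 0,
                             include_dc = TRUE) {
  w <- window_counts(grid, spike_times, t_start)
  n <- length(w$counts)
  mags <- (2 / w$L_s) * Mod(stats::fft(w$counts))
  # grid 0..1/dt in steps of 1/L is n+1 terms; bin n aliases to bin 0
  full <- c(mags, mags[1])
  if (!include_dc) full <- full[-1]
  mean(full)
}

#' Transmission metrics of one output spike train
#'
#' @inheritParams fourier_coefficient
#' @param F Input modulation frequency (Hz) at which locking is measured.
#' @return A list with `fc_f`, `fc_avg` and `fc_norm` (`fc_f / fc_avg`,
#'   0 when `fc_avg` is 0).
#' @export
transmission_metrics <- function(grid, spike_times, F, t_start = 0) {
  fc_f <- fourier_coefficient(grid, spike_times, F, t_start)
  fc_avg <- mean_coefficient(grid, spike_times, t_start)
  fc_norm <- if (fc_avg > 0) fc_f / fc_avg else 0
  list(fc_f = fc_f, fc_avg = fc_avg, fc_norm = fc_norm)
}

#' Half-maximum cutoff frequency of a transmission curve
#'
#' Frequency at which a transmission measure first falls to half its value
#' at the reference frequency (default 5 Hz), interpolated linearly in
#' log-frequency between adjacent sweep points; the first downward crossing
#' is taken. Invariant to rescaling all values by a constant.
#'
#' @param frequencies Sorted sweep frequencies (Hz), including `ref_freq`.
#' @param values Transmission values per frequency.
#' @param ref_freq Reference frequency (Hz).
#' @return Cutoff frequency (Hz), or `NA` if the curve never crosses half
#'   its reference value within the sweep.
#' @export
half_cutoff <- function(frequencies, values, ref_freq = 5) {
  stopifnot(length(frequencies) == length(values))
  o <- order(frequencies)
  frequencies <- frequencies[o]
  values <- values[o]
  i_ref <- which(frequencies == ref_freq)
  if (!length(i_ref)) stop("sweep must include the reference frequency",
                           call. = FALSE)
  target <- values[i_ref[1]] / 2
  above <- values >= target
  for (i in seq_along(frequencies)[-1]) {
    if (frequencies[i] <= ref_freq) next
    if (above[i - 1] && !above[i]) {
      lf <- log(frequencies[c(i - 1, i)])
      v <- values[c(i - 1, i)]
      return(exp(lf[1] + (target - v[1]) * (lf[2] - lf[1]) / (v[2] - v[1])))
    }
  }
  NA_real_
}

#' Frequency sweep of a simulated circuit
#'
#' Runs `runner(F, trial)` for each frequency and trial, computes the
#' Fourier coefficient at `F`, the whole-spectrum mean and their ratio for
#' every trial, and averages each metric separately across trials (the
#' 10-trial protocol). `runner` must return a list with elements `grid` and
#' `spike_times` (an output spike train); trial seeds are handled by the
#' caller via `set.seed` or a seed baked into `runner`.
#'
#' @param runner Function of `(F, trial)` returning
#'   `list(grid, spike_times)`.
#' @param frequencies Sweep frequencies (Hz); must include `ref_freq` for
#'   cutoff normalization.
#' @param n_trials Trials per frequency (default 10).
#' @param ref_freq Reference frequency for the half-maximum cutoff.
#' @param t_start Analysis window start (ms).
#' @param measure_freq Optional function of `F` giving the output frequency
#'   at which locking is measured (e.g. `function(F) 2 * F` for the XOR
#'   circuit); default identity.
#' @return An object of class `transmission_curve`: data.frame with columns
#'   `frequency_hz`, `fc_f`, `fc_avg`, `fc_norm`, plus attributes
#'   `half_cutoff` (on `fc_norm`), `half_cutoff_fc` (on `fc_f`), `n_trials`
#'   and `ref_freq`.
#' @export
transmission_sweep <- function(runner, frequencies, n_trials = 10,
                               ref_freq = 5, t_start = 0,
                               measure_freq = identity) {
  stopifnot(ref_freq %in% frequencies)
  frequencies <- sort(frequencies)
  rows <- lapply(frequencies, function(F) {
    m <- vapply(seq_len(n_trials), function(trial) {
      out <- runner(F, trial)
      tm <- transmission_metrics(out$grid, out$spike_times,
                                 measure_freq(F), t_start)
      c(tm$fc_f, tm$fc_avg, tm$fc_norm)
    }, numeric(3))
    data.frame(frequency_hz = F, fc_f = mean(m[1, ]),
               fc_avg = mean(m[2, ]), fc_norm = mean(m[3, ]))
  })
  curve <- do.call(rbind, rows)
  structure(curve,
            class = c("transmission_curve", "data.frame"),
            half_cutoff = half_cutoff(curve$frequency_hz, curve$fc_norm,
                                      ref_freq),
            half_cutoff_fc = half_cutoff(curve$frequency_hz, curve$fc_f,
                                         ref_freq),
            n_trials = n_trials, ref_freq = ref_freq)
}

#' @export
print.transmission_curve <- function(x, ...) {
  cat(sprintf("<transmission_curve> %d frequencies, %d trials each\n",
              nrow(x), attr(x, "n_trials")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("half-maximum cutoff (fc_norm): %s Hz; (fc_f): %s Hz\n",
              format(attr(x, "half_cutoff"), digits = 4),
              format(attr(x, "half_cutoff_fc"), digits = 4)))
  invisible(x)
}

#' Write a transmission curve as CSV
#'
#' @param curve A [transmission_sweep()] result.
#' @param path Output CSV path.
#' @export
write_transmission_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Time-binned normalized Fourier spectrum of a spike train
#'
#' Splits the train into consecutive bins of `bin_length` ms and computes
#' `FC(F)/FC_avg` per bin with `L = bin_length`, giving a spectrogram of
#' how the output's frequency content tracks a changing input.
#'
#' @param grid A [sim_grid()].
#' @param spike_times Spike times (ms).
#' @param bin_length Bin length (ms); must divide the grid duration.
#' @param frequencies Frequencies (Hz) at which to evaluate each bin.
#' @return Matrix of normalized coefficients, `length(frequencies)` rows by
#'   number of bins, with dimnames giving frequencies and bin start times.
#' @export
spectrogram <- function(grid, spike_times, bin_length, frequencies) {
  n_bins <- grid$duration / bin_length
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin_length must divide the grid duration", call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  sub <- sim_grid(dt = grid$dt, duration = bin_length)
  out <- matrix(0, nrow = length(frequencies), ncol = n_bins,
                dimnames = list(frequencies,
                                (seq_len(n_bins) - 1) * bin_length))
  for (b in seq_len(n_bins)) {
    t0 <- (b - 1) * bin_length
    sp <- spike_times[spike_times >= t0 & spike_times < t0 + bin_length] - t0
    fc <- fourier_coefficient(sub, sp, frequencies)
    fc_avg <- mean_coefficient(sub, sp)
    out[, b] <- if (fc_avg > 0) fc / fc_avg else 0
  }
  out
}
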