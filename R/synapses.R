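#' Synaptic kernel parameters
#'
#' A conductance synapse modeled as a normalized difference of exponentials:
#' one presynaptic spike at time `s` contributes
#' \deqn{P_{max} B (\exp(-\Delta t/\tau_{fall}) - \exp(-\Delta t/\tau_{rise}))}
#' for \eqn{\Delta t = t - (s + delay) \ge 0}, where `B` normalizes the peak
#' of the kernel to `P_max`.
#'
#' @param P_max Peak conductance (uS).
#' @param tau_rise,tau_fall Rise and fall time constants (ms); requires
#'   `0 < tau_rise < tau_fall`.
#' @param V_syn Reversal potential (mV): 0 for excitatory, -80 for
#'   inhibitory synapses here.
#' @param delay Onset delay Delta (ms) between the presynaptic spike and
#'   kernel onset.
#' @param alpha Current-scaling coefficient in the LIF equation (1 for
#'   excitatory synapses; inhibitory kernels default to 1.25 in the triad
#'   model).
#' @param depression Optional [depression_params()] applied per spike.
#' @return An object of class `syn_kernel`.
#' @export
syn_kernel <- function(P_max, tau_rise = 1, tau_fall = 20, V_syn = 0,
                       delay = 0, alpha = 1, depression = NULL) {
  if (!is.finite(tau_rise) || !is.finite(tau_fall) ||
      tau_rise <= 0 || tau_fall <= tau_rise) {
    stop("require 0 < tau_rise < tau_fall", call. = FALSE)
  }
  if (!is.finite(P_max) || P_max < 0) stop("P_max must be >= 0", call. = FALSE)
  if (!is.finite(delay) || delay < 0) stop("delay must be >= 0", call. = FALSE)
  structure(list(P_max = P_max, tau_rise = tau_rise, tau_fall = tau_fall,
                 V_syn = V_syn, delay = delay, alpha = alpha,
                 depression = depression),
            class = "syn_kernel")
}

#' @export
print.syn_kernel <- function(x, ...) {
  cat(sprintf(
    "<syn_kernel> P_max = %g uS, tau = (%g, %g) ms, V_syn = %g mV, delay = %g ms, alpha = %g%s\n",
    x$P_max, x$tau_rise, x$tau_fall, x$V_syn, x$delay, x$alpha,
    if (is.null(x$depression)) "" else ", depressing"))
  invisible(x)
}

#' Peak-normalization factor of a difference-of-exponentials kernel
#'
#' Returns `B` such that the maximum over `t >= 0` of
#' `B * (exp(-t/tau_fall) - exp(-t/tau_rise))` equals 1. The analytic peak
#' time is `t* = (tau_fall * tau_rise / (tau_fall - tau_rise)) *
#' log(tau_fall / tau_rise)`.
#'
#' @param tau_rise,tau_fall Time constants (ms), `0 < tau_rise < tau_fall`.
#' @return The dimensionless normalization factor `B >= 1`.
#' @examples
#' kernel_normalization(1, 20)  # ~1.2325
#' @export
kernel_normalization <- function(tau_rise, tau_fall) {
  if (!(tau_rise > 0 && tau_fall > tau_rise)) {
    stop("require 0 < tau_rise < tau_fall", call. = FALSE)
  }
  t_peak <- kernel_peak_time(tau_rise, tau_fall)
  1 / (exp(-t_peak / tau_fall) - exp(-t_peak / tau_rise))
}

#' Analytic peak time of the difference-of-exponentials kernel
#' @inheritParams kernel_normalization
#' @return Peak time after kernel onset (ms).
#' @export
kernel_peak_time <- function(tau_rise, tau_fall) {
  (tau_fall * tau_rise / (tau_fall - tau_rise)) * log(tau_fall / tau_rise)
}

#' Integral of a single-spike kernel
#'
#' The integrated conductance of one kernel event is
#' `P_max * B * (tau_fall - tau_rise)` (in uS * ms); this is the quantity
#' equated when balancing excitation against inhibition.
#'
#' @param kernel A [syn_kernel()].
#' @return Integrated conductance (uS * ms).
#' @export
kernel_integral <- function(kernel) {
  B <- kernel_normalization(kernel$tau_rise, kernel$tau_fall)
  kernel$P_max * B * (kernel$tau_fall - kernel$tau_rise)
}

#' Inhibitory peak conductance that balances a given excitatory kernel
#'
#' Chooses `P_max,i` so that the integrated conductance of one inhibitory
#' kernel equals that of one excitatory kernel:
#' \deqn{P_{max,i} = P_{max,e} (B_e/B_i)
#'       (\tau_{fall,e}-\tau_{rise,e}) / (\tau_{fall,i}-\tau_{rise,i})}
#'
#' @param P_max_e Excitatory peak conductance (uS).
#' @param tau_e,tau_i Length-2 vectors `c(rise, fall)` in ms.
#' @return Balanced inhibitory peak conductance (uS).
#' @examples
#' balanced_inhibitory_peak(0.222, c(1, 20), c(1, 50))  # ~0.096
#' @export
balanced_inhibitory_peak <- function(P_max_e, tau_e, tau_i) {
  B_e <- kernel_normalization(tau_e[1], tau_e[2])
  B_i <- kernel_normalization(tau_i[1], tau_i[2])
  P_max_e * (B_e / B_i) * (tau_e[2] - tau_e[1]) / (tau_i[2] - tau_i[1])
}

#' Two-factor short-term depression parameters
#'
#' Per-spike amplitude `A = A0 * D1 * D2`. After each presynaptic spike,
#' each factor is multiplied by its decrement (`D_i <- D_i * d_i`) and then
#' recovers exponentially toward 1 with time constant `tau_di`
#' (`D_i(t) = 1 + (D_i - 1) * exp(-(t - t_prev)/tau_di)`). The amplitude of
#' a spike is read before that spike's decrement is applied.
#'
#' @param A0 Undepressed amplitude scale.
#' @param d1,d2 Multiplicative decrements per spike (0 < d <= ~1).
#' @param tau_d1,tau_d2 Recovery time constants, in ms here (Table values
#'   given in seconds are converted by the preset registry).
#' @return An object of class `depression_params`.
#' @export
depression_params <- function(A0, d1, tau_d1, d2, tau_d2) {
  stopifnot(d1 > 0, d2 > 0, tau_d1 > 0, tau_d2 > 0, A0 > 0)
  structure(list(A0 = A0, d1 = d1, tau_d1 = tau_d1, d2 = d2, tau_d2 = tau_d2),
            class = "depression_params")
}

#' Per-spike amplitudes under two-factor depression
#'
#' @param spike_times Ordered spike times (ms).
#' @param p A [depression_params()].
#' @return Numeric vector of amplitudes, one per spike; the first spike of a
#'   fully recovered synapse has amplitude `A0`.
#' @export
depression_amplitudes <- function(spike_times, p) {
  stopifnot(inherits(p, "depression_params"))
  n <- length(spike_times)
  if (n == 0) return(numeric(0))
  if (is.unsorted(spike_times)) stop("spike times must be ordered", call. = FALSE)
  amps <- numeric(n)
  D1 <- 1
  D2 <- 1
  t_prev <- -Inf
  for (j in seq_len(n)) {
    dt_j <- spike_times[j] - t_prev
    D1 <- 1 + (D1 - 1) * exp(-dt_j / p$tau_d1)
    D2 <- 1 + (D2 - 1) * exp(-dt_j / p$tau_d2)
    amps[j] <- p$A0 * D1 * D2
    D1 <- D1 * p$d1
    D2 <- D2 * p$d2
    t_prev <- spike_times[j]
  }
  amps
}

# Causal linear convolution via FFT, truncated to length(x).
conv_causal <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nfft <- 2^ceiling(log2(n + m - 1))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(k, numeric(nfft - m))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Conductance trace from a spike train
#'
#' Linear superposition of the synaptic kernel over spikes: each spike `j`
#' (optionally scaled by a per-spike amplitude, e.g. from depression)
#' contributes the normalized kernel starting `delay` ms after the spike.
#'
#' @param grid A [sim_grid()].
#' @param spike_times Spike times (ms) within `[0, duration)`.
#' @param kernel A [syn_kernel()].
#' @param amplitudes Optional per-spike scale; defaults to 1. If the kernel
#'   carries `depression` parameters and `amplitudes` is `NULL`, depression
#'   amplitudes are computed from the spike train.
#' @return Non-negative conductance trace (uS) aligned to the grid.
#' @export
conductance_from_spikes <- function(grid, spike_times, kernel,
                                    amplitudes = NULL) {
  stopifnot(inherits(grid, "sim_grid"), inherits(kernel, "syn_kernel"))
  n <- grid$n_steps
  if (length(spike_times) == 0 || kernel$P_max == 0) return(numeric(n))
  if (is.null(amplitudes)) {
    amplitudes <- if (is.null(kernel$depression)) {
      rep(1, length(spike_times))
    } else {
      depression_amplitudes(spike_times, kernel$depression)
    }
  }
  stopifnot(length(amplitudes) == length(spike_times))
  idx <- as.integer(round((spike_times + kernel$delay) / grid$dt)) + 1L
  keep <- idx >= 1L & idx <= n
  if (!any(keep)) return(numeric(n))
  impulses <- numeric(n)
  tab <- tapply(amplitudes[keep], idx[keep], sum)
  impulses[as.integer(names(tab))] <- as.numeric(tab)
  B <- kernel_normalization(kernel$tau_rise, kernel$tau_fall)
  tt <- (seq_len(n) - 1) * grid$dt
  kern <- kernel$P_max * B * (exp(-tt / kernel$tau_fall) -
                              exp(-tt / kernel$tau_rise))
  pmax(conv_causal(impulses, kern), 0)
}

#' Paired feed-forward E/I projection from one spike train
#'
#' Builds the conductance terms of the FFEI motif: an excitatory kernel and
#' an inhibitory kernel driven by the same presynaptic spike train, the
#' inhibitory copy shifted by its onset delay. With `mixed_sign_negative =
#' TRUE` the roles are swapped (inhibition leads, delayed excitatory copy),
#' the "-" input of the mixed-sign XOR circuit.
#'
#' @param grid A [sim_grid()].
#' @param spike_times Presynaptic spike times (ms).
#' @param e_kernel,i_kernel [syn_kernel()] objects for the excitatory and
#'   inhibitory arms. Set `i_kernel$P_max = 0` (or pass `i_kernel = NULL`)
#'   for a plain FFE projection.
#' @param mixed_sign_negative Swap which kernel leads.
#' @return A list of conductance terms (`g`, `V_syn`, `alpha`) suitable for
#'   [integrate_lif()].
#' @export
make_ffei_projection <- function(grid, spike_times, e_kernel, i_kernel = NULL,
                                 mixed_sign_negative = FALSE) {
  kernels <- if (mixed_sign_negative) list(i_kernel, e_kernel)
             else list(e_kernel, i_kernel)
  terms <- list()
  for (k in kernels) {
    if (is.null(k) || k$P_max == 0) next
    terms[[length(terms) + 1]] <- list(
      g = conductance_from_spikes(grid, spike_times, k),
      V_syn = k$V_syn, alpha = k$alpha)
  }
  terms
}
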