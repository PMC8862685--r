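#' Firing-rate profile for inhomogeneous Poisson inputs
#'
#' The feed-forward drive is a Poisson process with rectified sinusoidal
#' rate \eqn{r(t) = rectify(PR \sin(2\pi F t + phase))}, where `PR` is the
#' peak rate (100 Hz in most experiments) and `F` the input modulation
#' frequency. Also supports a constant rate and a stepped-frequency
#' schedule (piecewise rectified sine, phase restarting at 0 at each
#' plateau boundary).
#'
#' @param kind One of `"rectified-sine"`, `"constant"`, `"stepped"`.
#' @param PR Peak rate (Hz) for sinusoidal kinds; the constant rate for
#'   `"constant"`.
#' @param F Modulation frequency (Hz).
#' @param phase Phase offset (radians).
#' @param schedule For `"stepped"`: data.frame with columns `duration_ms`
#'   and `F_hz`, applied in order.
#' @return An object of class `rate_profile`.
#' @export
rate_profile <- function(kind = c("rectified-sine", "constant", "stepped"),
                         PR = 100, F = 5, phase = 0, schedule = NULL) {
  kind <- match.arg(kind)
  stopifnot(PR >= 0)
  if (kind == "stepped") {
    stopifnot(is.data.frame(schedule),
              all(c("duration_ms", "F_hz") %in% names(schedule)),
              all(schedule$duration_ms > 0))
  }
  structure(list(kind = kind, PR = PR, F = F, phase = phase,
                 schedule = schedule),
            class = "rate_profile")
}

#' Build a stepped-frequency rate profile
#'
#' @param schedule data.frame with columns `duration_ms` and `F_hz`.
#' @param PR Peak rate (Hz).
#' @return A `"stepped"` [rate_profile()].
#' @export
stepped_frequency_profile <- function(schedule, PR = 100) {
  rate_profile("stepped", PR = PR, schedule = schedule)
}

#' Evaluate a rate profile on grid times
#'
#' @param profile A [rate_profile()].
#' @param times_ms Times in ms.
#' @return Rates in Hz (non-negative).
#' @export
rate_eval <- function(profile, times_ms) {
  t_s <- times_ms / 1000
  switch(profile$kind,
    "constant" = rep(profile$PR, length(times_ms)),
    "rectified-sine" =
      pmax(profile$PR * sin(2 * pi * profile$F * t_s + profile$phase), 0),
    "stepped" = {
      r <- numeric(length(times_ms))
      edges <- c(0, cumsum(profile$schedule$duration_ms))
      for (i in seq_len(nrow(profile$schedule))) {
        in_seg <- times_ms >= edges[i] & times_ms < edges[i + 1]
        # phase restarts at each plateau boundary
        local_s <- (times_ms[in_seg] - edges[i]) / 1000
        r[in_seg] <- pmax(profile$PR *
          sin(2 * pi * profile$schedule$F_hz[i] * local_s), 0)
      }
      r
    })
}

#' Generate an inhomogeneous Poisson spike train
#'
#' Per grid step, at most one spike: a spike occurs iff a uniform draw is
#' less than `r(t) * dt` (rate in spikes/s, `dt` converted to s). Uses the
#' current R random number stream; call `set.seed()` or pass `seed` for
#' reproducibility.
#'
#' @param grid A [sim_grid()].
#' @param profile A [rate_profile()].
#' @param seed Optional integer seed (sets the global RNG).
#' @return Spike times (ms) on the grid.
#' @export
poisson_spikes <- function(grid, profile, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rate_eval(profile, grid$times) * grid$dt / 1000
  if (any(p >= 1)) stop("rate * dt >= 1: grid too coarse for this rate",
                        call. = FALSE)
  grid$times[stats::runif(grid$n_steps) < p]
}

#' Summed spike counts of N independent Poisson inputs
#'
#' For an ensemble of `n_inputs` independent Poisson processes sharing one
#' rate profile, the per-step summed spike count is Binomial(n_inputs,
#' r(t) dt). Used for background-noise ensembles and the 100-input
#' cortical drive, where only the summed conductance matters.
#'
#' @param grid A [sim_grid()].
#' @param profile A [rate_profile()].
#' @param n_inputs Number of independent inputs.
#' @param seed Optional integer seed.
#' @return Integer vector of per-step summed counts, aligned to the grid.
#' @export
poisson_count_sum <- function(grid, profile, n_inputs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rate_eval(profile, grid$times) * grid$dt / 1000
  if (any(p >= 1)) stop("rate * dt >= 1: grid too coarse for this rate",
                        call. = FALSE)
  stats::rbinom(grid$n_steps, n_inputs, p)
}

#' Background-noise rate balanced to the feed-forward drive
#'
#' Each noisy background input fires at the mean rate of the rectified
#' sinusoidal feed-forward input: `FR = PR / pi` (the mean of
#' `rectify(PR * sin)` over a cycle).
#'
#' @param PR Peak rate of the feed-forward input (Hz).
#' @return Balanced per-input background rate (Hz).
#' @examples
#' balanced_noise_rate(100)  # 31.83 Hz
#' @export
balanced_noise_rate <- function(PR) {
  stopifnot(PR >= 0)
  PR / pi
}

#' Summed conductance of a noisy background ensemble
#'
#' `n_inputs` independent homogeneous Poisson trains at rate `FR`, each
#' through the same excitatory kernel, summed into one conductance trace.
#'
#' @param grid A [sim_grid()].
#' @param kernel A [syn_kernel()] (defaults elsewhere: 2.26 nS peak,
#'   tau 1/20 ms).
#' @param n_inputs Number of inputs (default 50).
#' @param FR Per-input rate (Hz; default `balanced_noise_rate(100)`).
#' @return A conductance term list (`g`, `V_syn`, `alpha`) for
#'   [integrate_lif()].
#' @export
noise_conductance <- function(grid, kernel, n_inputs = 50,
                              FR = balanced_noise_rate(100)) {
  counts <- poisson_count_sum(grid, rate_profile("constant", PR = FR),
                              n_inputs)
  idx <- which(counts > 0)
  g <- conductance_from_spikes(grid, grid$times[idx], kernel,
                               amplitudes = counts[idx])
  list(g = g, V_syn = kernel$V_syn, alpha = kernel$alpha)
}

#' Rectified sinusoidal current waveform
#'
#' @param grid A [sim_grid()].
#' @param amplitude Peak current (nA); 8.38 nA in the current-injection
#'   comparison experiment.
#' @param F Modulation frequency (Hz).
#' @return Current trace (nA) aligned to the grid, non-negative.
#' @export
rectified_current <- function(grid, amplitude, F) {
  stopifnot(amplitude >= 0)
  pmax(amplitude * sin(2 * pi * F * grid$times / 1000), 0)
}
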