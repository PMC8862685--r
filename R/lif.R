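#' Leaky integrate-and-fire membrane parameters
#'
#' Membrane constants for the LIF neuron
#' \deqn{dV_m/dt = -(V_m - V_e)/\tau_m - (R_m/\tau_m) \sum_n \alpha_n P_n(t)
#'       (V_m - V_{syn,n}) + (R_m/\tau_m) I_{inj}(t)}
#' integrated with forward Euler on the simulation grid. When `V_m` reaches
#' `V_thresh` a spike is recorded and `V_m` is set to `V_reset`.
#'
#' Defaults are the relay-neuron values used throughout: `tau_m` 10 ms,
#' `R_m` 10 MOhm, `V_e` -75 mV, `V_reset` -80 mV, `V_thresh` -40 mV.
#' Cortical-circuit interneurons use `V_thresh = -48` mV.
#'
#' @param tau_m Membrane time constant (ms).
#' @param R_m Membrane resistance (MOhm).
#' @param V_e Leak reversal potential (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param V_thresh Spike threshold (mV); may be `Inf` to disable spiking.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 10, R_m = 10, V_e = -75,
                       V_reset = -80, V_thresh = -40) {
  vals <- c(tau_m = tau_m, R_m = R_m, V_e = V_e, V_reset = V_reset)
  if (any(!is.finite(vals))) stop("non-finite LIF parameter", call. = FALSE)
  if (is.na(V_thresh)) stop("non-finite LIF parameter", call. = FALSE)
  if (tau_m <= 0 || R_m <= 0) stop("tau_m and R_m must be positive", call. = FALSE)
  if (!(V_reset <= V_e && V_e < V_thresh)) {
    stop("require V_reset <= V_e < V_thresh", call. = FALSE)
  }
  structure(list(tau_m = tau_m, R_m = R_m, V_e = V_e,
                 V_reset = V_reset, V_thresh = V_thresh),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "<lif_params> tau_m = %g ms, R_m = %g MOhm, V_e = %g mV, V_reset = %g mV, V_thresh = %g mV\n",
    x$tau_m, x$R_m, x$V_e, x$V_reset, x$V_thresh))
  invisible(x)
}

#' Integrate a leaky integrate-and-fire neuron
#'
#' Forward-Euler integration of the LIF equation with conductance-based
#' synaptic input and optional injected current. Each conductance term is a
#' list with elements `g` (conductance trace in uS, aligned to the grid),
#' `V_syn` (reversal potential, mV) and `alpha` (current-scaling
#' coefficient; 1 for excitatory synapses).
#'
#' Units are ms / mV / MOhm / uS / nA throughout, so that
#' mV = MOhm * nA = MOhm * uS * mV. The initial condition is
#' `V_m(0) = V_e`; the threshold is tested after each Euler update, at most
#' one spike per step, the reset is applied on the same step, and
#' integration resumes from `V_reset` on the next step (see the methods
#' vignette on the sensitivity of strong-synapse responses to this
#' bookkeeping at coarse time steps).
#'
#' @param grid A [sim_grid()].
#' @param params A [lif_params()].
#' @param conductance_terms List of conductance terms as described above.
#' @param injected Optional injected current trace (nA) aligned to the grid.
#' @param record_v If `TRUE`, keep the full voltage trace.
#' @return An object of class `lif_state` with `spike_times` (ms, strictly
#'   increasing) and, when recorded, `V_m` (mV per grid step).
#' @examples
#' g <- sim_grid(dt = 0.1, duration = 200)
#' st <- integrate_lif(g, lif_params(), injected = rep(5, g$n_steps))
#' diff(st$spike_times)  # ~ tau_m * log(55 / 15)
#' @export
integrate_lif <- function(grid, params, conductance_terms = list(),
                          injected = NULL, record_v = FALSE) {
  stopifnot(inherits(grid, "sim_grid"), inherits(params, "lif_params"))
  n <- grid$n_steps
  g_sum <- numeric(0)
  gv_sum <- numeric(0)
  if (length(conductance_terms)) {
    g_sum <- numeric(n)
    gv_sum <- numeric(n)
    for (term in conductance_terms) {
      assert_grid_trace(grid, term$g, "conductance trace")
      alpha <- if (is.null(term$alpha)) 1 else term$alpha
      if (!is.finite(alpha) || !is.finite(term$V_syn)) {
        stop("non-finite conductance term parameter", call. = FALSE)
      }
      g_sum <- g_sum + alpha * term$g
      gv_sum <- gv_sum + alpha * term$g * term$V_syn
    }
  }
  if (!is.null(injected)) assert_grid_trace(grid, injected, "injected current")
  res <- lif_euler_cpp(grid$dt, n, params$V_e,
                       params$tau_m, params$R_m, params$V_e,
                       params$V_thresh, params$V_reset,
                       g_sum, gv_sum,
                       if (is.null(injected)) numeric(0) else injected,
                       record_v)
  structure(list(spike_times = res$spike_times,
                 V_m = if (record_v) res$V_m else NULL,
                 grid = grid),
            class = "lif_state")
}

#' @export
print.lif_state <- function(x, ...) {
  cat(sprintf("<lif_state> %d spikes over %g ms (mean rate %.2f Hz)\n",
              length(x$spike_times), x$grid$duration,
              1000 * length(x$spike_times) / x$grid$duration))
  invisible(x)
}

#' Closed-form interspike interval of an LIF neuron under constant current
#'
#' For constant injected current `I` with steady state
#' `V_e + R_m * I > V_thresh`, the tonic interspike interval is
#' `tau_m * log((V_e + R_m I - V_reset) / (V_e + R_m I - V_thresh))`.
#' Used as an analytic cross-check of the Euler integrator.
#'
#' @param params A [lif_params()].
#' @param I Constant current (nA).
#' @return Interval in ms (`Inf` if the neuron cannot reach threshold).
#' @export
lif_isi_constant_current <- function(params, I) {
  vss <- params$V_e + params$R_m * I
  if (vss <= params$V_thresh) return(Inf)
  params$tau_m * log((vss - params$V_reset) / (vss - params$V_thresh))
}
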