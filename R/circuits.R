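# Circuit builders: wire stimuli, synapses and LIF neurons into each
# architecture and run single trials; run_* wrappers handle trials/seeding.

new_circuit_result <- function(trials, architecture, params, seed) {
  structure(list(trials = trials, architecture = architecture,
                 params = params, seed = seed),
            class = "circuit_result")
}

#' @export
print.circuit_result <- function(x, ...) {
  cat(sprintf("<circuit_result> %s: %d trial(s), neurons: %s\n",
              x$architecture, length(x$trials),
              paste(names(x$trials[[1]]$neurons), collapse = ", ")))
  invisible(x)
}

triad_kernels <- function(mode, P_max_e, P_max_i, tau_fall_i, delay, alpha) {
  d <- model_parameters()$triad_ffei
  if (mode == "ffe") {
    e <- syn_kernel(P_max = if (is.null(P_max_e))
                      model_parameters()$triad_ffe$P_max_us else P_max_e,
                    tau_rise = 1, tau_fall = 20, V_syn = 0)
    return(list(e = e, i = NULL))
  }
  if (is.null(P_max_e)) P_max_e <- d$P_max_e_us
  if (is.null(P_max_i)) {
    P_max_i <- if (tau_fall_i == d$tau_fall_e_ms) P_max_e else
      balanced_inhibitory_peak(P_max_e, c(1, 20), c(1, tau_fall_i))
  }
  list(e = syn_kernel(P_max = P_max_e, tau_rise = 1, tau_fall = 20,
                      V_syn = 0),
       i = syn_kernel(P_max = P_max_i, tau_rise = 1, tau_fall = tau_fall_i,
                      V_syn = d$V_syn_i_mv, delay = delay, alpha = alpha))
}

triad_trial <- function(grid, F, PR, mode, kernels, lif = lif_from_preset(),
                        noise = FALSE, noise_scale = 1, injected = NULL,
                        record_v = FALSE) {
  input <- poisson_spikes(grid, rate_profile(PR = PR, F = F))
  terms <- make_ffei_projection(grid, input, kernels$e, kernels$i)
  if (noise) {
    nd <- model_parameters()$noise_default
    nk <- syn_kernel(P_max = nd$P_max_noise_us * noise_scale,
                     tau_rise = nd$tau_rise_ms, tau_fall = nd$tau_fall_ms,
                     V_syn = 0)
    terms[[length(terms) + 1]] <-
      noise_conductance(grid, nk, nd$n_inputs, nd$FR_hz)
  }
  out <- integrate_lif(grid, lif, terms, injected = injected,
                       record_v = record_v)
  list(grid = grid, neurons = list(input = input,
                                   output = out$spike_times),
       V_m = out$V_m, spike_times = out$spike_times)
}

#' Simulate the triad-synapse circuit
#'
#' One Poisson input with rectified sinusoidal rate drives paired
#' excitatory and (for FFEI) delayed inhibitory kernels onto a single LIF
#' output neuron. The triad interneuron is not an explicit spiking cell:
#' the inhibitory kernel is driven directly by the input train with onset
#' delay `delay`, abstracting the dendro-dendritic contact.
#'
#' @param F Input modulation frequency (Hz).
#' @param PR Peak input rate (Hz).
#' @param mode `"ffei"` (paired E/I) or `"ffe"` (excitation alone).
#' @param n_trials Number of independent trials.
#' @param seed Master seed; trial `k` uses a derived sub-seed.
#' @param duration Trial length (ms).
#' @param dt Time step (ms).
#' @param P_max_e,P_max_i Peak conductances (uS); defaults to the standard
#'   weights (1.21/1.21 uS FFEI, 0.080 uS FFE). When `tau_fall_i` differs
#'   from 20 ms and `P_max_i` is not given, it is set by
#'   [balanced_inhibitory_peak()].
#' @param tau_fall_i Inhibitory fall time constant (ms).
#' @param delay Inhibitory onset delay Delta (ms).
#' @param alpha Inhibitory current scaling.
#' @param noise Add the 50-input background-noise ensemble.
#' @param noise_scale Scale factor on the per-input noise conductance.
#' @param V_e Leak reversal override (mV).
#' @param record_v Keep voltage traces.
#' @return A `circuit_result` with per-trial `input` and `output` spike
#'   trains.
#' @export
run_triad <- function(F = 5, PR = 100, mode = c("ffei", "ffe"),
                      n_trials = 10, seed = 1, duration = 5000, dt = 0.1,
                      P_max_e = NULL, P_max_i = NULL, tau_fall_i = 20,
                      delay = 1, alpha = 1.25, noise = FALSE,
                      noise_scale = 1, V_e = NULL, record_v = FALSE) {
  mode <- match.arg(mode)
  grid <- sim_grid(dt = dt, duration = duration)
  kernels <- triad_kernels(mode, P_max_e, P_max_i, tau_fall_i, delay, alpha)
  lif <- lif_from_preset(V_e = V_e)
  trials <- lapply(seq_len(n_trials), function(k) {
    set.seed(derive_seed(seed, 1, k))
    triad_trial(grid, F, PR, mode, kernels, lif, noise, noise_scale,
                record_v = record_v)
  })
  new_circuit_result(trials, paste0("triad-", mode),
                     list(F = F, PR = PR, kernels = kernels), seed)
}

#' Runner factory for triad sweeps
#'
#' Returns a `function(F, trial)` suitable for [transmission_sweep()],
#' seeding each (frequency, trial) cell deterministically from `seed`.
#'
#' @inheritParams run_triad
#' @param ... Passed to the kernel construction (`P_max_e`, `P_max_i`,
#'   `tau_fall_i`, `delay`, `alpha`).
#' @param noise,noise_scale,V_e As in [run_triad()].
#' @return A closure `(F, trial) -> list(grid, spike_times)`.
#' @export
triad_runner <- function(mode = c("ffei", "ffe"), PR = 100, seed = 1,
                         duration = 5000, dt = 0.1, P_max_e = NULL,
                         P_max_i = NULL, tau_fall_i = 20, delay = 1,
                         alpha = 1.25, noise = FALSE, noise_scale = 1,
                         V_e = NULL) {
  mode <- match.arg(mode)
  grid <- sim_grid(dt = dt, duration = duration)
  kernels <- triad_kernels(mode, P_max_e, P_max_i, tau_fall_i, delay, alpha)
  lif <- lif_from_preset(V_e = V_e)
  function(F, trial) {
    set.seed(derive_seed(seed, round(F * 64), trial))
    triad_trial(grid, F, PR, mode, kernels, lif, noise, noise_scale)
  }
}

#' Simulate a rectified-current injection control
#'
#' Direct injection of a rectified sinusoidal current into the default LIF
#' neuron (no synapses), the membrane-filtering control against which FFEI
#' transmission is compared.
#'
#' @inheritParams run_triad
#' @param amplitude Peak current (nA); default 8.38 nA.
#' @return A `circuit_result` (deterministic: no randomness).
#' @export
run_current_injection <- function(F = 5, amplitude = 8.38, n_trials = 1,
                                  seed = 1, duration = 5000, dt = 0.1,
                                  record_v = FALSE) {
  grid <- sim_grid(dt = dt, duration = duration)
  I <- rectified_current(grid, amplitude, F)
  trials <- lapply(seq_len(n_trials), function(k) {
    out <- integrate_lif(grid, lif_from_preset(), injected = I,
                         record_v = record_v)
    list(grid = grid, neurons = list(output = out$spike_times),
         V_m = out$V_m, spike_times = out$spike_times)
  })
  new_circuit_result(trials, "current-injection",
                     list(F = F, amplitude = amplitude), seed)
}

multilevel_trial <- function(grid, F, PR, mode, P_e, P_i, delay, alpha,
                             noise_kernel, n_noise, FR) {
  d <- model_parameters()$multilevel
  lif <- lif_from_preset()
  e_kernel <- if (mode != "nc")
    syn_kernel(P_max = P_e, tau_rise = 1, tau_fall = 20, V_syn = 0) else NULL
  i_kernel <- if (mode == "ffei")
    syn_kernel(P_max = P_i, tau_rise = 1, tau_fall = 20, V_syn = -80,
               delay = delay, alpha = alpha) else NULL
  input <- poisson_spikes(grid, rate_profile(PR = PR, F = F))
  pre <- input
  neurons <- list(input = input)
  for (level in 1:4) {
    terms <- list(noise_conductance(grid, noise_kernel, n_noise, FR))
    if (mode != "nc") {
      terms <- c(terms, make_ffei_projection(grid, pre, e_kernel, i_kernel))
    }
    st <- integrate_lif(grid, lif, terms)
    neurons[[paste0("A", level)]] <- st$spike_times
    pre <- st$spike_times
  }
  list(grid = grid, neurons = neurons,
       spike_times = neurons$A4)
}

#' Simulate the four-level hierarchical network
#'
#' Four LIF cells in a chain (levels A1-A4). Level A1 receives the external
#' rectified-sinusoid Poisson input through the chosen projection; each
#' level also receives its own independent 50-input background-noise
#' ensemble. Inter-level projections use the same motif: `"ffei"` (paired E
#' and delayed I kernels per presynaptic spike), `"ffe"` (E kernel only),
#' or `"nc"` (no connections, noise only).
#'
#' @inheritParams run_triad
#' @param mode `"ffei"`, `"ffe"` or `"nc"`.
#' @param P_max_e,P_max_i Projection weights (uS); defaults 0.717/0.717
#'   FFEI and 0.032 FFE; the weakest calibration uses 0.359/0.016.
#' @return A `circuit_result` with per-trial `input` and `A1`..`A4` trains.
#' @export
run_multilevel <- function(F = 5, PR = 100, mode = c("ffei", "ffe", "nc"),
                           n_trials = 10, seed = 1, duration = 5000,
                           dt = 0.1, P_max_e = NULL, P_max_i = NULL,
                           delay = 1, alpha = 1.25) {
  mode <- match.arg(mode)
  runner <- multilevel_runner(mode = mode, PR = PR, seed = seed,
                              duration = duration, dt = dt,
                              P_max_e = P_max_e, P_max_i = P_max_i,
                              delay = delay, alpha = alpha)
  trials <- lapply(seq_len(n_trials), function(k) runner(F, k))
  new_circuit_result(trials, paste0("multilevel-", mode),
                     list(F = F, PR = PR), seed)
}

#' Runner factory for multilevel sweeps
#' @inheritParams run_multilevel
#' @return A closure `(F, trial) -> list(grid, spike_times)` returning the
#'   level-A4 output train.
#' @export
multilevel_runner <- function(mode = c("ffei", "ffe", "nc"), PR = 100,
                              seed = 1, duration = 5000, dt = 0.1,
                              P_max_e = NULL, P_max_i = NULL, delay = 1,
                              alpha = 1.25) {
  mode <- match.arg(mode)
  d <- model_parameters()$multilevel
  nd <- model_parameters()$noise_default
  if (is.null(P_max_e)) {
    P_max_e <- if (mode == "ffei") d$P_max_ei_us else d$P_max_ffe_us
  }
  if (is.null(P_max_i)) P_max_i <- P_max_e
  grid <- sim_grid(dt = dt, duration = duration)
  noise_kernel <- syn_kernel(P_max = nd$P_max_noise_us,
                             tau_rise = nd$tau_rise_ms,
                             tau_fall = nd$tau_fall_ms, V_syn = 0)
  function(F, trial) {
    set.seed(derive_seed(seed, round(F * 64), trial))
    multilevel_trial(grid, F, PR, mode, P_max_e, P_max_i, delay, alpha,
                     noise_kernel, nd$n_inputs, nd$FR_hz)
  }
}

cortical_trial <- function(grid, F, PR, mode, lif_e, lif_i, p,
                           tau_fall_e_in, tau_fall_i_in, record_v = FALSE) {
  counts <- poisson_count_sum(grid, rate_profile(PR = PR, F = F),
                              p$n_inputs)
  idx <- which(counts > 0)
  t_in <- grid$times[idx]
  amps <- counts[idx]
  ke <- syn_kernel(P_max = p$input_to_e_us, tau_rise = p$tau_rise_ms,
                   tau_fall = tau_fall_e_in, V_syn = 0)
  gE <- conductance_from_spikes(grid, t_in, ke, amplitudes = amps)
  e_terms <- list(list(g = gE, V_syn = 0, alpha = 1))
  neurons <- list()
  if (mode == "ffei") {
    ki <- syn_kernel(P_max = p$input_to_i_us, tau_rise = p$tau_rise_ms,
                     tau_fall = tau_fall_i_in, V_syn = 0)
    gI_in <- conductance_from_spikes(grid, t_in, ki, amplitudes = amps)
    i_state <- integrate_lif(grid, lif_i,
                             list(list(g = gI_in, V_syn = 0, alpha = 1)))
    k_ie <- syn_kernel(P_max = p$i_to_e_us, tau_rise = p$tau_rise_ms,
                       tau_fall = p$tau_fall_ms, V_syn = -80,
                       alpha = p$alpha_i)
    e_terms[[2]] <- list(
      g = conductance_from_spikes(grid, i_state$spike_times, k_ie),
      V_syn = -80, alpha = p$alpha_i)
    neurons$interneuron <- i_state$spike_times
  }
  e_state <- integrate_lif(grid, lif_e, e_terms, record_v = record_v)
  neurons$output <- e_state$spike_times
  list(grid = grid, neurons = neurons, V_m = e_state$V_m,
       spike_times = e_state$spike_times)
}

#' Simulate the 100-input cortical circuit
#'
#' 100 independent Poisson inputs with a shared rate profile synapse onto a
#' cortical excitatory LIF cell (2 nS each) and, in FFEI mode, onto an
#' explicit LIF interneuron (0.6 nS each, threshold -48 mV) whose spikes
#' drive a 100 nS inhibitory conductance (alpha = 1.25) onto the excitatory
#' cell. There is no explicit inhibitory delay: the lag emerges from the
#' interneuron's dynamics. `"ffe"` mode omits the interneuron.
#'
#' @inheritParams run_triad
#' @param tau_m_I Interneuron membrane time constant (ms).
#' @param ampa_only_to_I Use fast (1.6 ms fall) input kinetics to the
#'   interneuron with the matching weight set (3 nS to E, 4.08 nS to I),
#'   modelling AMPA-dominated input to the interneuron.
#' @return A `circuit_result` with per-trial `interneuron` (FFEI only) and
#'   `output` spike trains.
#' @export
run_cortical_circuit <- function(F = 5, PR = 100, mode = c("ffei", "ffe"),
                                 n_trials = 10, seed = 1, duration = 5000,
                                 dt = 0.1, tau_m_I = 10,
                                 ampa_only_to_I = FALSE, record_v = FALSE) {
  mode <- match.arg(mode)
  runner <- cortical_runner(mode = mode, PR = PR, seed = seed,
                            duration = duration, dt = dt, tau_m_I = tau_m_I,
                            ampa_only_to_I = ampa_only_to_I,
                            record_v = record_v)
  trials <- lapply(seq_len(n_trials), function(k) runner(F, k))
  new_circuit_result(trials, paste0("cortical-", mode),
                     list(F = F, PR = PR, tau_m_I = tau_m_I), seed)
}

#' Runner factory for cortical-circuit sweeps
#' @inheritParams run_cortical_circuit
#' @return A closure `(F, trial) -> list(grid, spike_times)` returning the
#'   excitatory cell's output train.
#' @export
cortical_runner <- function(mode = c("ffei", "ffe"), PR = 100, seed = 1,
                            duration = 5000, dt = 0.1, tau_m_I = 10,
                            ampa_only_to_I = FALSE, record_v = FALSE) {
  mode <- match.arg(mode)
  p <- model_parameters()$cortical
  tau_fall_e_in <- p$tau_fall_ms
  tau_fall_i_in <- p$tau_fall_ms
  if (ampa_only_to_I) {
    mod <- model_parameters()$cortical_ampa_to_i
    p$input_to_e_us <- mod$input_to_e_us
    p$input_to_i_us <- mod$input_to_i_us
    tau_fall_i_in <- mod$tau_fall_i_input_ms
  }
  grid <- sim_grid(dt = dt, duration = duration)
  lif_e <- lif_from_preset("lif_default")
  lif_i <- lif_from_preset("lif_interneuron", tau_m = tau_m_I)
  function(F, trial) {
    set.seed(derive_seed(seed, round(F * 64), trial))
    cortical_trial(grid, F, PR, mode, lif_e, lif_i, p,
                   tau_fall_e_in, tau_fall_i_in, record_v)
  }
}

xor_pair_kernels <- function(P_max, delay, alpha) {
  list(e = syn_kernel(P_max = P_max, tau_rise = 1, tau_fall = 20, V_syn = 0),
       i = syn_kernel(P_max = P_max, tau_rise = 1, tau_fall = 20,
                      V_syn = -80, delay = delay, alpha = alpha))
}

xor_trial <- function(grid, F, PR, mode, p, phase_shift) {
  i1 <- poisson_spikes(grid, rate_profile(PR = PR, F = F, phase = 0))
  i2 <- poisson_spikes(grid, rate_profile(PR = PR, F = F,
                                          phase = phase_shift))
  lif <- lif_from_preset()
  if (mode == "mixed") {
    kp <- xor_pair_kernels(p$P_max_mixed_us, p$delta_ms, p$alpha)
    plus <- function(sp) make_ffei_projection(grid, sp, kp$e, kp$i)
    minus <- function(sp) make_ffei_projection(grid, sp, kp$e, kp$i,
                                               mixed_sign_negative = TRUE)
  } else {
    ke <- syn_kernel(P_max = p$P_max_single_us, tau_rise = 1, tau_fall = 20,
                     V_syn = 0)
    ki <- syn_kernel(P_max = p$P_max_single_us, tau_rise = 1, tau_fall = 20,
                     V_syn = -80, alpha = p$alpha)
    plus <- function(sp) list(list(g = conductance_from_spikes(grid, sp, ke),
                                   V_syn = 0, alpha = 1))
    minus <- function(sp) list(list(g = conductance_from_spikes(grid, sp, ki),
                                    V_syn = -80, alpha = p$alpha))
  }
  a1_cell1 <- integrate_lif(grid, lif, c(plus(i1), minus(i2)))$spike_times
  a1_cell2 <- integrate_lif(grid, lif, c(minus(i1), plus(i2)))$spike_times
  a2 <- integrate_lif(grid, lif, c(plus(a1_cell1), plus(a1_cell2)))$spike_times
  list(grid = grid,
       neurons = list(i1 = i1, i2 = i2, a1_cell1 = a1_cell1,
                      a1_cell2 = a1_cell2, a2 = a2),
       spike_times = a2)
}

#' Simulate the two-layer XOR circuit
#'
#' Two rectified-sinusoid Poisson inputs (default anti-phase) drive a
#' two-cell first layer: cell 1 receives +i1 and -i2, cell 2 receives -i1
#' and +i2. In mixed-sign mode "+" is an excitatory kernel followed by an
#' identical delayed inhibitory copy and "-" is its mirror (inhibition
#' leading); in single-sign mode each pair is replaced by its leading
#' kernel alone at the single-sign weight. The second-layer cell receives
#' "+" projections from both first-layer cells and should respond at twice
#' the input frequency for anti-phase inputs.
#'
#' @inheritParams run_triad
#' @param mode `"mixed"` or `"single"`.
#' @param phase_shift Relative phase of the two inputs (radians; default
#'   `pi`, anti-phase).
#' @return A `circuit_result` with per-trial `i1`, `i2`, `a1_cell1`,
#'   `a1_cell2` and `a2` spike trains.
#' @export
run_xor <- function(F = 5, PR = 100, mode = c("mixed", "single"),
                    n_trials = 10, seed = 1, duration = 5000, dt = 0.02,
                    phase_shift = pi) {
  mode <- match.arg(mode)
  runner <- xor_runner(mode = mode, PR = PR, seed = seed,
                       duration = duration, dt = dt,
                       phase_shift = phase_shift)
  trials <- lapply(seq_len(n_trials), function(k) runner(F, k))
  new_circuit_result(trials, paste0("xor-", mode),
                     list(F = F, PR = PR, phase_shift = phase_shift), seed)
}

#' Runner factory for XOR sweeps
#' @inheritParams run_xor
#' @return A closure `(F, trial) -> list(grid, spike_times)` returning the
#'   layer-A2 output train; pair with `measure_freq = function(F) 2 * F` in
#'   [transmission_sweep()] for anti-phase inputs.
#' @export
xor_runner <- function(mode = c("mixed", "single"), PR = 100, seed = 1,
                       duration = 5000, dt = 0.02, phase_shift = pi) {
  mode <- match.arg(mode)
  p <- model_parameters()$xor
  grid <- sim_grid(dt = dt, duration = duration)
  function(F, trial) {
    set.seed(derive_seed(seed, round(F * 64), trial))
    xor_trial(grid, F, PR, mode, p, phase_shift)
  }
}

receptor_condition_kernels <- function(condition, depressing) {
  mp <- model_parameters()
  dep <- function(name) if (depressing) depression_preset(name) else NULL
  if (condition %in% c("AMPA", "AMPA+NMDA", "AMPA+NMDA+GABA")) {
    blk <- mp$receptor_fig7[[condition]]
    kernels <- list(syn_kernel(P_max = blk$P_max_AMPA_us,
                               tau_rise = blk$tau_AMPA_ms[1],
                               tau_fall = blk$tau_AMPA_ms[2], V_syn = 0,
                               depression = dep("AMPA")))
    if (!is.null(blk$P_max_NMDA_us)) {
      kernels <- c(kernels, list(syn_kernel(P_max = blk$P_max_NMDA_us,
                                            tau_rise = blk$tau_NMDA_ms[1],
                                            tau_fall = blk$tau_NMDA_ms[2],
                                            V_syn = 0,
                                            depression = dep("NMDA"))))
    }
    if (condition == "AMPA+NMDA+GABA") {
      # GABA-like arm: delayed inhibitory copies of both excitatory kernels
      kernels <- c(kernels, list(
        syn_kernel(P_max = blk$P_max_AMPA_us, tau_rise = blk$tau_AMPA_ms[1],
                   tau_fall = blk$tau_AMPA_ms[2], V_syn = -80,
                   delay = blk$delta_ms, alpha = blk$alpha,
                   depression = dep("GABA")),
        syn_kernel(P_max = blk$P_max_NMDA_us, tau_rise = blk$tau_NMDA_ms[1],
                   tau_fall = blk$tau_NMDA_ms[2], V_syn = -80,
                   delay = blk$delta_ms, alpha = blk$alpha,
                   depression = dep("GABA"))))
    }
    return(kernels)
  }
  blk <- mp$receptor_fig8[[condition]]
  kernels <- list(
    syn_kernel(P_max = blk$P_max_AMPA_us, tau_rise = blk$tau_AMPA_ms[1],
               tau_fall = blk$tau_AMPA_ms[2], V_syn = 0,
               depression = dep("AMPA")),
    syn_kernel(P_max = blk$P_max_NMDA_us, tau_rise = blk$tau_NMDA_ms[1],
               tau_fall = blk$tau_NMDA_ms[2], V_syn = 0,
               depression = dep("NMDA")))
  if (condition == "AMPA+NMDA+GABAA+GABAB") {
    kernels <- c(kernels, list(
      syn_kernel(P_max = blk$P_max_GABAA_us, tau_rise = blk$tau_GABAA_ms[1],
                 tau_fall = blk$tau_GABAA_ms[2], V_syn = -80,
                 delay = blk$delta_ms, alpha = blk$alpha,
                 depression = dep("GABA")),
      syn_kernel(P_max = blk$P_max_GABAB_us, tau_rise = blk$tau_GABAB_ms[1],
                 tau_fall = blk$tau_GABAB_ms[2], V_syn = -80,
                 delay = blk$delta_ms, alpha = blk$alpha,
                 depression = dep("GABA"))))
  }
  kernels
}

#' Simulate triad circuits with explicit receptor mixtures
#'
#' Triad wiring (one Poisson input, kernels driven directly by the input
#' train) with kernels for specific receptor channels: fast AMPA, slow
#' NMDA, and inhibitory arms (a "GABA-like" delayed copy of the excitatory
#' kinetics, or explicit GABA_A/GABA_B kernels in the depressing variant).
#' Depressing conditions apply two-factor depression per receptor and are
#' conventionally analysed from 1 s onward (`analysis_start`).
#'
#' @inheritParams run_triad
#' @param condition One of `"AMPA"`, `"AMPA+NMDA"`, `"AMPA+NMDA+GABA"`,
#'   `"AMPA+NMDA"` with `depressing = TRUE`, or
#'   `"AMPA+NMDA+GABAA+GABAB"` (depressing).
#' @param depressing Apply two-factor short-term depression per receptor.
#' @param noise Add the 50-input background-noise ensemble.
#' @return A `circuit_result`; trials carry `analysis_start` (ms) metadata.
#' @export
run_receptor_mixture <- function(condition = c("AMPA", "AMPA+NMDA",
                                               "AMPA+NMDA+GABA",
                                               "AMPA+NMDA+GABAA+GABAB"),
                                 F = 5, PR = NULL, depressing = FALSE,
                                 n_trials = 10, seed = 1, duration = 5000,
                                 dt = 0.1, noise = FALSE) {
  condition <- match.arg(condition)
  if (condition == "AMPA+NMDA+GABAA+GABAB") depressing <- TRUE
  fig8 <- condition == "AMPA+NMDA+GABAA+GABAB" ||
    (depressing && condition == "AMPA+NMDA")
  if (is.null(PR)) {
    PR <- if (fig8) model_parameters()$receptor_fig8$PR_hz else 100
  }
  analysis_start <- if (depressing)
    model_parameters()$receptor_fig8$analysis_start_ms else 0
  kernels <- receptor_condition_kernels(condition, depressing)
  grid <- sim_grid(dt = dt, duration = duration)
  lif <- lif_from_preset()
  nd <- model_parameters()$noise_default
  trials <- lapply(seq_len(n_trials), function(k) {
    set.seed(derive_seed(seed, 7, k))
    input <- poisson_spikes(grid, rate_profile(PR = PR, F = F))
    terms <- lapply(kernels, function(kern) {
      list(g = conductance_from_spikes(grid, input, kern),
           V_syn = kern$V_syn, alpha = kern$alpha)
    })
    if (noise) {
      nk <- syn_kernel(P_max = nd$P_max_noise_us, tau_rise = nd$tau_rise_ms,
                       tau_fall = nd$tau_fall_ms, V_syn = 0)
      terms <- c(terms, list(noise_conductance(grid, nk, nd$n_inputs,
                                               nd$FR_hz)))
    }
    st <- integrate_lif(grid, lif, terms)
    list(grid = grid, neurons = list(input = input,
                                     output = st$spike_times),
         spike_times = st$spike_times, analysis_start = analysis_start)
  })
  new_circuit_result(trials, paste0("receptor-", condition),
                     list(F = F, PR = PR, depressing = depressing,
                          analysis_start = analysis_start), seed)
}
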