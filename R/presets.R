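#' Model parameter registry
#'
#' Named parameter sets mirroring the default and per-experiment tables of
#' the triad-synapse and cortical-circuit models, stored verbatim with
#' units in field names (ms, mV, MOhm, uS, nA, Hz). Conductances quoted in
#' nS in the tables are stored in uS.
#'
#' @return A named list of parameter blocks.
#' @export
model_parameters <- function() {
  list(
    lif_default = list(tau_m_ms = 10, R_m_mohm = 10, V_e_mv = -75,
                       V_reset_mv = -80, V_thresh_mv = -40),
    lif_interneuron = list(tau_m_ms = 10, R_m_mohm = 10, V_e_mv = -75,
                           V_reset_mv = -80, V_thresh_mv = -48),
    triad_ffei = list(P_max_e_us = 1.21, P_max_i_us = 1.21,
                      V_syn_e_mv = 0, V_syn_i_mv = -80,
                      tau_rise_ms = 1, tau_fall_e_ms = 20, tau_fall_i_ms = 20,
                      delta_ms = 1, alpha = 1.25),
    triad_ffe = list(P_max_us = 0.080, V_syn_mv = 0,
                     tau_rise_ms = 1, tau_fall_ms = 20),
    # tau_fall_i (ms) -> weight pairs keeping 5 Hz output near 75 Hz
    triad_tau_fall_i_rows = data.frame(
      tau_fall_i_ms = c(25, 30, 50),
      P_max_e_us = c(0.883, 0.581, 0.222),
      P_max_i_us = c(0.723, 0.403, 0.096)),
    # matched FFEI/FFE strength ladder (weak to strong)
    triad_strength_rows = data.frame(
      P_max_ei_us = c(0.498, 0.911, 1.21, 1.46, 1.59),
      P_max_ffe_us = c(0.032, 0.054, 0.080, 0.120, 0.160)),
    current_injection = list(amplitude_na = 8.38),
    noise_default = list(n_inputs = 50, FR_hz = 100 / pi,
                         P_max_noise_us = 0.00226,
                         tau_rise_ms = 1, tau_fall_ms = 20),
    # inhibitory delay (ms) -> weight pairs
    triad_delay_rows = data.frame(
      delta_ms = c(2, 5, 10, 20),
      P_max_ei_us = c(0.671, 0.328, 0.204, 0.132)),
    multilevel = list(P_max_ei_us = 0.717, P_max_ffe_us = 0.032,
                      weakest_P_max_ei_us = 0.359,
                      weakest_P_max_ffe_us = 0.016,
                      delta_ms = 1, alpha = 1.25),
    multilevel_strength_rows = data.frame(
      P_max_ei_us = c(0.359, 0.595, 0.717, 0.799, 0.835),
      P_max_ffe_us = c(0.016, 0.024, 0.032, 0.047, 0.055)),
    xor = list(dt_ms = 0.02, P_max_mixed_us = 1.31, P_max_single_us = 0.066,
               delta_ms = 1, alpha = 1.25),
    cortical = list(n_inputs = 100,
                    input_to_e_us = 0.002, input_to_i_us = 0.0006,
                    i_to_e_us = 0.1, alpha_i = 1.25,
                    tau_rise_ms = 1, tau_fall_ms = 20,
                    tau_m_i_ms = 10),
    cortical_ampa_to_i = list(input_to_e_us = 0.003,
                              input_to_i_us = 0.00408,
                              tau_fall_i_input_ms = 1.6),
    receptor_fig7 = list(
      AMPA = list(P_max_AMPA_us = 0.679,
                  tau_AMPA_ms = c(0.7, 0.72)),
      `AMPA+NMDA` = list(P_max_AMPA_us = 0.051, P_max_NMDA_us = 0.026,
                         tau_AMPA_ms = c(0.7, 0.72),
                         tau_NMDA_ms = c(3.2, 100)),
      `AMPA+NMDA+GABA` = list(P_max_AMPA_us = 0.798, P_max_NMDA_us = 0.399,
                              tau_AMPA_ms = c(0.7, 0.72),
                              tau_NMDA_ms = c(3.2, 100),
                              delta_ms = 1, alpha = 1.25)),
    receptor_fig8 = list(
      `AMPA+NMDA` = list(P_max_AMPA_us = 13.80, P_max_NMDA_us = 1.380,
                         tau_AMPA_ms = c(0.7, 1.6),
                         tau_NMDA_ms = c(3.2, 90)),
      `AMPA+NMDA+GABAA+GABAB` = list(
        P_max_AMPA_us = 28.20, P_max_NMDA_us = 2.820,
        P_max_GABAA_us = 2.845, P_max_GABAB_us = 1.067,
        tau_AMPA_ms = c(0.7, 1.6), tau_NMDA_ms = c(3.2, 90),
        tau_GABAA_ms = c(0.6, 6), tau_GABAB_ms = c(30, 150),
        delta_ms = 1, alpha = 1),
      PR_hz = 50, trial_ms = 5000, analysis_start_ms = 1000),
    # two-factor depression fits; recovery times converted from s to ms
    depression = list(
      AMPA = list(A0 = 0.997, d1 = 0.593, tau_d1_ms = 2876,
                  d2 = 0.403, tau_d2_ms = 155),
      NMDA = list(A0 = 1.000, d1 = 0.664, tau_d1_ms = 158,
                  d2 = 0.734, tau_d2_ms = 3962),
      GABA = list(A0 = 1.002, d1 = 0.228, tau_d1_ms = 141,
                  d2 = 0.393, tau_d2_ms = 1477))
  )
}

#' Look up a depression parameter set by receptor name
#'
#' @param receptor `"AMPA"`, `"NMDA"` or `"GABA"` (used for both GABA_A and
#'   GABA_B).
#' @return A [depression_params()] object (time constants in ms).
#' @export
depression_preset <- function(receptor = c("AMPA", "NMDA", "GABA")) {
  receptor <- match.arg(receptor)
  p <- model_parameters()$depression[[receptor]]
  depression_params(A0 = p$A0, d1 = p$d1, tau_d1 = p$tau_d1_ms,
                    d2 = p$d2, tau_d2 = p$tau_d2_ms)
}

lif_from_preset <- function(block = "lif_default", tau_m = NULL, V_e = NULL) {
  p <- model_parameters()[[block]]
  lif_params(tau_m = if (is.null(tau_m)) p$tau_m_ms else tau_m,
             R_m = p$R_m_mohm,
             V_e = if (is.null(V_e)) p$V_e_mv else V_e,
             V_reset = p$V_reset_mv, V_thresh = p$V_thresh_mv)
}

# Deterministic per-(frequency, trial) sub-seed from one master seed.
derive_seed <- function(master, i, j = 0) {
  ((as.numeric(master) %% 97651) * 20011 + i * 104729 + j * 1009) %%
    2147483629 + 1
}
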