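#' Neuron model parameters
#'
#' Parameters of the two-compartment pyramidal cell (soma + dendrite) and the
#' single-compartment inhibitory integrate-and-fire cell. Units follow the
#' usual convention for conductance-based point models: capacitance in pF,
#' conductance in nS, voltage in mV, current in pA, time in ms, so that
#' `dV/dt = I/C` is in mV/ms without further conversion.
#'
#' Defaults are the layer-5 pyramidal cell fit used throughout: somatic
#' membrane time constant `C_s/g_l = 20` ms, dendritic `C_d/g_l_d = 7` ms,
#' sigmoidal dendritic calcium nonlinearity centred at `E_d = -38` mV with
#' slope `D_d = 6` mV, dendrite-to-soma coupling `g_s = 1300` pA, local
#' dendritic gain `g_d = 1200` pA, and a rescaling factor `lambda_scale`
#' that keeps coupling and adaptation currents consistent with the original
#' 370 pF soma the model was fitted with.
#'
#' @param C_s,C_d somatic / dendritic capacitance (pF).
#' @param g_l,g_l_d somatic / dendritic leak conductance (nS).
#' @param E_l leak reversal potential (mV).
#' @param v_reset post-spike reset potential (mV); the membrane is held
#'   there for the refractory period.
#' @param E_I inhibitory reversal potential (mV). Excitatory reversal is 0 mV.
#' @param v_theta,v_theta_I spiking thresholds of E and I cells (mV).
#' @param tau_m,tau_m_I membrane time constants (ms); informational, implied
#'   by `C/g_l`.
#' @param c_d amplitude of the back-propagating action potential (bAP)
#'   current pulse into the dendrite (pA).
#' @param a_omega_d dendritic subthreshold adaptation strength (nS).
#' @param b_omega_s somatic spike-triggered adaptation increment (pA,
#'   negative = hyperpolarising).
#' @param tau_omega_s,tau_omega_d adaptation recovery time constants (ms).
#' @param tau_syn_s,tau_syn_d synaptic conductance decay time constants of
#'   the somatic-compartment (and inhibitory-cell) and dendritic-compartment
#'   synapses (ms).
#' @param g_s dendrite-to-soma coupling of the calcium nonlinearity (pA).
#' @param g_d local dendritic nonlinearity gain (pA).
#' @param E_d half-activation voltage of the calcium nonlinearity (mV).
#' @param D_d slope of the calcium nonlinearity (mV).
#' @param lambda_scale dimensionless rescaling of somatic coupling and
#'   adaptation currents.
#' @param t_ref absolute refractory period of E and I cells (ms).
#' @param bAP_delay,bAP_duration delay and duration of the bAP current
#'   pulse after a somatic spike (ms).
#' @return A named list of class `"neuron_params"`.
#' @export
neuron_params <- function(C_s = 200, C_d = 170,
                          g_l = 10, g_l_d = 170 / 7,
                          E_l = -70, E_I = -80, v_reset = -70,
                          v_theta = -50, v_theta_I = -50,
                          tau_m = 20, tau_m_I = 10,
                          c_d = 2600,
                          a_omega_d = -13, b_omega_s = -200,
                          tau_omega_s = 100, tau_omega_d = 30,
                          tau_syn_s = 16, tau_syn_d = 7,
                          g_s = 1300, g_d = 1200,
                          E_d = -38, D_d = 6,
                          lambda_scale = 0.54,
                          t_ref = 8.3,
                          bAP_delay = 0.5, bAP_duration = 2.0) {
  p <- list(C_s = C_s, C_d = C_d, g_l = g_l, g_l_d = g_l_d,
            E_l = E_l, E_I = E_I, v_reset = v_reset,
            v_theta = v_theta, v_theta_I = v_theta_I,
            tau_m = tau_m, tau_m_I = tau_m_I, c_d = c_d,
            a_omega_d = a_omega_d, b_omega_s = b_omega_s,
            tau_omega_s = tau_omega_s, tau_omega_d = tau_omega_d,
            tau_syn_s = tau_syn_s, tau_syn_d = tau_syn_d,
            g_s = g_s, g_d = g_d, E_d = E_d, D_d = D_d,
            lambda_scale = lambda_scale, t_ref = t_ref,
            bAP_delay = bAP_delay, bAP_duration = bAP_duration)
  pos <- c("C_s", "C_d", "g_l", "g_l_d", "tau_m", "tau_m_I",
           "tau_omega_s", "tau_omega_d", "tau_syn_s", "tau_syn_d",
           "D_d", "t_ref")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("neuron_params: '%s' must be strictly positive", nm))
  }
  if (p$E_I >= p$v_theta)
    stop("neuron_params: E_I must be below the spiking threshold v_theta")
  if (p$lambda_scale <= 0 || p$lambda_scale > 1)
    stop("neuron_params: lambda_scale must be in (0, 1]")
  structure(p, class = "neuron_params")
}

#' Network architecture parameters
#'
#' Population sizes, external Poisson drive, connection probabilities and
#' initial synaptic weights of the balanced network: `N_E` two-compartment
#' pyramidal cells, `N_I` inhibitory cells, a shared pool of `N_poisson`
#' Poisson sources at `rate_poisson` Hz fanned out with probability
#' `p_connect`. All recurrent projections use `p_connect` except
#' E-to-E perisomatic synapses, which use `p_EE_soma` (slightly lower
#' because pyramidal cells also receive excitation on their dendrite).
#'
#' Weight naming is `w_<target><source>`: e.g. `w_EI` is the I-to-E somatic
#' weight, `w_EI_d` its dendritic counterpart, `w_EP` the Poisson-to-E
#' weight. All weights in nS.
#'
#' @param N_E,N_I,N_poisson population sizes.
#' @param rate_poisson rate of each external Poisson source (Hz).
#' @param p_connect generic connection probability.
#' @param p_EE_soma E-to-E perisomatic connection probability.
#' @param w_EP,w_IP,w_EE,w_EE_d,w_IE,w_II,w_EI,w_EI_d synaptic weights (nS).
#' @return A named list of class `"network_params"`.
#' @export
network_params <- function(N_E = 1000, N_I = 250, N_poisson = 1000,
                           rate_poisson = 2,
                           p_connect = 0.1, p_EE_soma = 0.09,
                           w_EP = 1.6, w_IP = 1.6,
                           w_EE = 1.8, w_EE_d = 1.8,
                           w_IE = 4.0, w_II = 6.0,
                           w_EI = 8.0, w_EI_d = 4.0) {
  p <- list(N_E = as.integer(N_E), N_I = as.integer(N_I),
            N_poisson = as.integer(N_poisson), rate_poisson = rate_poisson,
            p_connect = p_connect, p_EE_soma = p_EE_soma,
            w_EP = w_EP, w_IP = w_IP, w_EE = w_EE, w_EE_d = w_EE_d,
            w_IE = w_IE, w_II = w_II, w_EI = w_EI, w_EI_d = w_EI_d)
  if (p$N_E < 1 || p$N_I < 1 || p$N_poisson < 1)
    stop("network_params: population sizes must be >= 1")
  for (nm in c("p_connect", "p_EE_soma")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1)
      stop(sprintf("network_params: '%s' must be in (0, 1]", nm))
  }
  w <- unlist(p[grep("^w_", names(p))])
  if (any(w < 0)) stop("network_params: weights must be >= 0")
  if (p$rate_poisson < 0) stop("network_params: rate_poisson must be >= 0")
  structure(p, class = "network_params")
}

#' Plasticity rule parameters
#'
#' Parameters of the triplet spike-timing-dependent plasticity rule, the
#' dendritic calcium-spike potentiation, the transmitter-induced depression
#' and the homeostatic modulation of the depression amplitude.
#'
#' Perisomatic synapses potentiate at each postsynaptic spike by
#' `eta * w0 * A_plus * z_plus * z_slow` (triplet rule) and depress at each
#' presynaptic spike by `eta * w0 * A_minus(s_bar) * z_minus`, where
#' `A_minus = A_plus * tau_plus * tau_slow / (tau_minus * kappa) * s_bar^2`
#' tracks the low-pass-filtered postsynaptic rate `s_bar` (filter time
#' constant `tau_homeo`, target rate `kappa`). Dendritic synapses use the
#' same triplet rule with the back-propagating action potential as the
#' postsynaptic event, plus a fixed calcium-spike potentiation `A_Ca` when
#' the dendritic voltage exceeds `theta_Ca` at a presynaptic spike, minus a
#' constant transmitter-induced depression `alpha` per presynaptic spike.
#'
#' @param A_plus triplet potentiation amplitude (dimensionless).
#' @param A_Ca calcium-spike potentiation amplitude (dimensionless).
#' @param alpha transmitter-induced depression per presynaptic spike
#'   (dimensionless, scaled like the other amplitudes).
#' @param theta_bAP dendritic voltage threshold for bAP detection (mV).
#' @param theta_Ca dendritic voltage threshold for Ca potentiation (mV).
#' @param tau_plus,tau_minus,tau_slow trace time constants (ms).
#' @param w_max maximum synaptic weight (nS).
#' @param eta base learning rate (dimensionless).
#' @param kappa homeostatic target rate (Hz); `NA` means "calibrate from
#'   the warm-up phase" (see [run_simulation()]).
#' @param tau_homeo homeostatic filter time constant (s).
#' @param bAP_refractory minimum interval between bAP events (ms).
#' @param bAP_window maximum soma-spike-to-bAP latency (ms).
#' @return A named list of class `"plasticity_params"`.
#' @export
plasticity_params <- function(A_plus = 6.5e-3, A_Ca = 7.2e-2, alpha = 1e-4,
                              theta_bAP = -50, theta_Ca = -40,
                              tau_plus = 16.8, tau_minus = 33.7,
                              tau_slow = 114,
                              w_max = 10, eta = 5,
                              kappa = NA_real_, tau_homeo = 10,
                              bAP_refractory = 5.8, bAP_window = 3.0) {
  p <- list(A_plus = A_plus, A_Ca = A_Ca, alpha = alpha,
            theta_bAP = theta_bAP, theta_Ca = theta_Ca,
            tau_plus = tau_plus, tau_minus = tau_minus, tau_slow = tau_slow,
            w_max = w_max, eta = eta, kappa = kappa, tau_homeo = tau_homeo,
            bAP_refractory = bAP_refractory, bAP_window = bAP_window)
  if (p$w_max <= 0) stop("plasticity_params: w_max must be > 0")
  for (nm in c("tau_plus", "tau_minus", "tau_slow", "tau_homeo")) {
    if (p[[nm]] <= 0)
      stop(sprintf("plasticity_params: '%s' must be > 0", nm))
  }
  if (p$A_plus < 0 || p$A_Ca < 0 || p$alpha < 0)
    stop("plasticity_params: amplitudes must be >= 0")
  if (!is.na(p$kappa) && p$kappa <= 0)
    stop("plasticity_params: kappa, when given, must be > 0")
  structure(p, class = "plasticity_params")
}

#' Plasticity-gate configuration
#'
#' Per-neuron multiplicative/additive gates on the excitatory population:
#' excitability factors `gamma_soma` / `gamma_dend` multiplying the total
#' excitatory conductance of each compartment, inhibition factors scaling
#' inhibitory synaptic increments onto each compartment, an additive
#' spiking-threshold shift, and learning-rate factors per compartment.
#' The default is the identity configuration (all factors 1, shift 0).
#'
#' Scalars are recycled to length `n_E`. `subpopulation_mask` records which
#' neurons a non-identity gate was applied to (see [apply_gates()]).
#'
#' @param n_E number of excitatory neurons.
#' @param gamma_soma,gamma_dend excitability factors (>= 0).
#' @param inh_scale_soma,inh_scale_dend inhibition factors (>= 0).
#' @param v_theta_shift additive threshold shift (mV).
#' @param eta_soma,eta_dend learning-rate factors (>= 0).
#' @param subpopulation_mask logical vector of gated neurons.
#' @return A named list of class `"gating_config"`.
#' @export
gating_config <- function(n_E,
                          gamma_soma = 1, gamma_dend = 1,
                          inh_scale_soma = 1, inh_scale_dend = 1,
                          v_theta_shift = 0,
                          eta_soma = 1, eta_dend = 1,
                          subpopulation_mask = TRUE) {
  n_E <- as.integer(n_E)
  rec <- function(x) {
    x <- rep_len(as.numeric(x), n_E)
    x
  }
  g <- list(gamma_soma = rec(gamma_soma), gamma_dend = rec(gamma_dend),
            inh_scale_soma = rec(inh_scale_soma),
            inh_scale_dend = rec(inh_scale_dend),
            v_theta_shift = rec(v_theta_shift),
            eta_soma = rec(eta_soma), eta_dend = rec(eta_dend),
            subpopulation_mask = rep_len(as.logical(subpopulation_mask), n_E),
            n_E = n_E)
  for (nm in c("gamma_soma", "gamma_dend", "inh_scale_soma",
               "inh_scale_dend", "eta_soma", "eta_dend")) {
    if (any(g[[nm]] < 0))
      stop(sprintf("gating_config: '%s' must be >= 0", nm))
  }
  structure(g, class = "gating_config")
}

#' Simulation configuration
#'
#' @param dt integration time step (ms).
#' @param duration main-phase (plasticity-on) duration (s).
#' @param tau_homeo homeostatic filter time constant (s); overrides the
#'   value in `plasticity_params` when not `NA`.
#' @param warmup_factor warm-up duration as a multiple of `tau_homeo`.
#' @param warmup_floor minimum warm-up duration (s), guarding the target
#'   rate estimate when `tau_homeo` is small.
#' @param warmup_override when not `NA`, use exactly this warm-up (s);
#'   a zero warm-up requires a preset `kappa` for plasticity-on runs.
#' @param rate_bin width of the population-rate bins (s).
#' @param baseline_window baseline-averaging window for the explosion
#'   factor (s); runs shorter than this fall back to their first quarter.
#' @param snapshot_interval interval between weight-change snapshots (s).
#' @param record_currents record per-neuron mean somatic synaptic currents
#'   (sampled at 1 ms).
#' @param record_bAP keep per-neuron bAP event times in the result.
#' @param record_voltages integer vector of E-neuron indices whose state
#'   variables are recorded every time step (for diagnostics/tests).
#' @param stop_on_explosion abort the main phase once a completed rate bin
#'   exceeds `stop_factor` times the baseline rate (after the baseline
#'   window); the run is flagged and counts as exploded.
#' @param stop_factor early-stop multiple of the baseline rate.
#' @param plasticity_on master switch for all weight updates.
#' @param syn_tau_mapping how the two synaptic decay constants map onto
#'   conductances: `"compartment"` (somatic 16 ms / dendritic 7 ms for
#'   both synapse types, the default) or `"type"` (excitatory 16 ms /
#'   inhibitory 7 ms in every compartment). See the methods vignette.
#' @return A named list of class `"sim_config"`.
#' @export
sim_config <- function(dt = 0.1, duration = 200,
                       tau_homeo = NA_real_,
                       warmup_factor = 3, warmup_floor = 15,
                       warmup_override = NA_real_,
                       rate_bin = 1, baseline_window = 50,
                       snapshot_interval = 1,
                       record_currents = FALSE, record_bAP = TRUE,
                       record_voltages = integer(0),
                       stop_on_explosion = FALSE, stop_factor = 3,
                       plasticity_on = TRUE,
                       syn_tau_mapping = c("compartment", "type")) {
  if (dt <= 0) stop("sim_config: dt must be > 0")
  if (duration <= 0) stop("sim_config: duration must be > 0")
  syn_tau_mapping <- match.arg(syn_tau_mapping)
  structure(list(dt = dt, duration = duration, tau_homeo = tau_homeo,
                 warmup_factor = warmup_factor, warmup_floor = warmup_floor,
                 warmup_override = warmup_override,
                 rate_bin = rate_bin, baseline_window = baseline_window,
                 snapshot_interval = snapshot_interval,
                 record_currents = record_currents, record_bAP = record_bAP,
                 record_voltages = as.integer(record_voltages),
                 stop_on_explosion = stop_on_explosion,
                 stop_factor = stop_factor,
                 plasticity_on = plasticity_on,
                 syn_tau_mapping = syn_tau_mapping),
            class = "sim_config")
}
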