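#' Dendritic calcium nonlinearity
#'
#' Sigmoidal activation of the dendritic calcium channels,
#' `1 / (1 + exp(-(V_d - E_d) / D_d))`, in (0, 1) and strictly increasing
#' in `V_d`. Its output current is injected locally (gain `g_d`) and into
#' the soma (coupling `g_s`, rescaled by `lambda_scale`).
#'
#' @param V_d dendritic membrane potential (mV), vectorised.
#' @param params a [neuron_params()] object.
#' @return Activation in (0, 1).
#' @export
dendritic_nonlinearity <- function(V_d, params = neuron_params()) {
  1 / (1 + exp(-(V_d - params$E_d) / params$D_d))
}

#' Back-propagating action potential current kernel
#'
#' Rectangular kernel of the bAP current: 1 while `t` lies within
#' `[t_hat + bAP_delay, t_hat + bAP_delay + bAP_duration]` of any somatic
#' spike time `t_hat`, summed over spikes (pulses superpose; within the
#' network the 8.3 ms somatic refractory period precludes overlap).
#'
#' @param t evaluation time (ms), scalar.
#' @param t_spikes somatic spike times (ms).
#' @param params a [neuron_params()] object.
#' @return Number of active pulses at `t` (0 or 1 under refractoriness).
#' @export
bap_kernel <- function(t, t_spikes, params = neuron_params()) {
  if (length(t_spikes) == 0) return(0)
  lo <- t_spikes + params$bAP_delay
  hi <- lo + params$bAP_duration
  sum(t >= lo - 1e-9 & t <= hi + 1e-9)
}

#' One forward-Euler step of the two-compartment pyramidal cell
#'
#' Advances somatic and dendritic voltages and the two adaptation
#' variables by one time step, given the instantaneous synaptic
#' conductances, then applies threshold, reset and refractory logic.
#' All arguments are vectorised over neurons.
#'
#' The somatic membrane equation integrates leak, excitatory conductance
#' (reversal 0 mV) scaled by the excitability gate `gamma_soma`,
#' inhibitory conductance, and the rescaled dendro-somatic coupling plus
#' somatic adaptation, `lambda_scale * (g_s * sigma(V_d) + omega_s)`. The
#' dendritic equation integrates leak, gated excitation, inhibition, the
#' local nonlinearity `g_d * sigma(V_d)`, the bAP current `c_d * K(t)` and
#' dendritic adaptation. Somatic spikes reset `V_s` to `E_l` and clamp it
#' there for `t_ref` ms; `omega_s` jumps by `b_omega_s` at each spike;
#' `omega_d` relaxes toward `a_omega_d * (V_d - E_l)`.
#'
#' @param state list with numeric vectors `V_s`, `V_d`, `omega_s`,
#'   `omega_d`, `refractory_until` and scalar `t` (ms).
#' @param inputs list with conductance vectors `g_E_soma`, `g_I_soma`,
#'   `g_E_dend`, `g_I_dend` (nS) and logical/numeric `bap_active`
#'   (the kernel value `K(t)` per neuron).
#' @param params a [neuron_params()] object.
#' @param gates a [gating_config()] object (identity by default).
#' @param dt time step (ms).
#' @return Updated `state` plus `spikes`, the integer indices of neurons
#'   that crossed threshold on this step.
#' @export
step_pyramidal <- function(state, inputs, params = neuron_params(),
                           gates = NULL, dt = 0.1) {
  n <- length(state$V_s)
  if (is.null(gates)) gates <- gating_config(n)
  sig <- dendritic_nonlinearity(state$V_d, params)
  I_s <- -params$g_l * (state$V_s - params$E_l) -
    gates$gamma_soma * inputs$g_E_soma * state$V_s -
    inputs$g_I_soma * (state$V_s - params$E_I) +
    params$lambda_scale * (params$g_s * sig + state$omega_s)
  I_d <- -params$g_l_d * (state$V_d - params$E_l) -
    gates$gamma_dend * inputs$g_E_dend * state$V_d -
    inputs$g_I_dend * (state$V_d - params$E_I) +
    params$g_d * sig + params$c_d * as.numeric(inputs$bap_active) +
    state$omega_d
  V_s <- state$V_s + dt * I_s / params$C_s
  V_d <- state$V_d + dt * I_d / params$C_d
  omega_s <- state$omega_s - dt * state$omega_s / params$tau_omega_s
  omega_d <- state$omega_d + dt *
    (-state$omega_d + params$a_omega_d * (state$V_d - params$E_l)) /
    params$tau_omega_d
  if (any(!is.finite(V_s)) || any(!is.finite(V_d)))
    stop("step_pyramidal: non-finite voltage (integration failure)")
  t_new <- state$t + dt
  refr <- t_new < state$refractory_until - 1e-9
  V_s[refr] <- params$E_l
  spikes <- which(!refr & V_s > params$v_theta + gates$v_theta_shift)
  if (length(spikes)) {
    V_s[spikes] <- params$E_l
    omega_s[spikes] <- omega_s[spikes] + params$b_omega_s
    state$refractory_until[spikes] <- t_new + params$t_ref
    state$last_spike[spikes] <- t_new
  }
  state$V_s <- V_s; state$V_d <- V_d
  state$omega_s <- omega_s; state$omega_d <- omega_d
  state$t <- t_new
  state$spikes <- spikes
  state
}

#' One forward-Euler step of the inhibitory leaky integrate-and-fire cell
#'
#' Single compartment, threshold `v_theta_I`, same refractory period and
#' reset as the pyramidal soma, no adaptation, no gates.
#'
#' @param state list with `V`, `refractory_until`, `t`.
#' @param inputs list with `g_E`, `g_I` (nS).
#' @param params a [neuron_params()] object. The inhibitory capacitance is
#'   `g_l * tau_m_I`.
#' @param dt time step (ms).
#' @return Updated state plus `spikes` indices.
#' @export
step_inhibitory <- function(state, inputs, params = neuron_params(),
                            dt = 0.1) {
  C_I <- params$g_l * params$tau_m_I
  I <- -params$g_l * (state$V - params$E_l) -
    inputs$g_E * state$V -
    inputs$g_I * (state$V - params$E_I)
  V <- state$V + dt * I / C_I
  if (any(!is.finite(V)))
    stop("step_inhibitory: non-finite voltage (integration failure)")
  t_new <- state$t + dt
  refr <- t_new < state$refractory_until - 1e-9
  V[refr] <- params$E_l
  spikes <- which(!refr & V > params$v_theta_I)
  if (length(spikes)) {
    V[spikes] <- params$E_l
    state$refractory_until[spikes] <- t_new + params$t_ref
  }
  state$V <- V
  state$t <- t_new
  state$spikes <- spikes
  state
}

#' Exponential synaptic conductance decay
#'
#' Exact decay `g * exp(-dt / tau)` over one step; conductances jump at
#' presynaptic spike arrivals (see [run_simulation()]) and decay
#' exponentially in between.
#'
#' @param g conductance (nS), vectorised.
#' @param dt elapsed time (ms).
#' @param tau decay time constant (ms).
#' @return Decayed conductance, never negative.
#' @export
decay_conductance <- function(g, dt, tau) {
  g * exp(-dt / tau)
}

#' Stepped update of a spike trace
#'
#' Advances an exponentially decaying trace by one step (exact decay over
#' `dt`) and adds 1 per driving event. Perisomatic-rule postsynaptic
#' traces are driven by somatic spikes, dendritic-rule postsynaptic traces
#' by bAP events, presynaptic traces by presynaptic spikes.
#'
#' @param z trace value(s).
#' @param dt elapsed time (ms).
#' @param tau trace time constant (ms).
#' @param n_events number of driving events at the end of the step.
#' @return Updated trace.
#' @export
update_trace <- function(z, dt, tau, n_events = 0) {
  z * exp(-dt / tau) + n_events
}

#' Closed-form trace value from an event list
#'
#' Event-driven evaluation of a spike trace: the sum of
#' `exp(-(t - t_f)/tau)` over past event times `t_f`. With
#' `before_event = TRUE`, events at exactly `t` are excluded,
#' implementing the convention that a spike's own increment is not seen
#' by the plasticity update it triggers.
#'
#' @param t evaluation time (ms).
#' @param event_times event times (ms).
#' @param tau time constant (ms).
#' @param before_event exclude events at `t` itself.
#' @return Trace value at `t`.
#' @export
trace_at <- function(t, event_times, tau, before_event = TRUE) {
  keep <- if (before_event) event_times < t - 1e-9 else event_times <= t + 1e-9
  sum(exp(-(t - event_times[keep]) / tau))
}

#' Homeostatic depression amplitude
#'
#' The depression amplitude grows quadratically with the low-pass-filtered
#' postsynaptic rate:
#' `A_minus = A_plus * tau_plus * tau_slow / (tau_minus * kappa) * s_bar^2`
#' (trace time constants in seconds, rates in Hz). At `s_bar == kappa` the
#' expected triplet potentiation and homeostatic depression cancel for
#' independent Poisson pre/post activity at rate `kappa`, making `kappa`
#' the fixed point of the mean weight drift.
#'
#' @param s_bar filtered postsynaptic rate (Hz), vectorised.
#' @param plasticity a [plasticity_params()] object with `kappa` set.
#' @return Depression amplitude (dimensionless).
#' @export
homeostatic_amplitude <- function(s_bar, plasticity) {
  if (is.na(plasticity$kappa) || plasticity$kappa <= 0)
    stop("homeostatic_amplitude: kappa must be set and > 0")
  if (any(s_bar < 0)) stop("homeostatic_amplitude: s_bar must be >= 0")
  k <- (plasticity$A_plus * (plasticity$tau_plus / 1000) *
          (plasticity$tau_slow / 1000)) /
    ((plasticity$tau_minus / 1000) * plasticity$kappa)
  k * s_bar^2
}

#' Leaky rate estimate update
#'
#' Low-pass filter of the spike train with time constant `tau_homeo`
#' (seconds): exact exponential decay over `dt` plus an impulse of weight
#' `1/tau_homeo` per spike, so that a steady rate `r` drives `s_bar`
#' toward `r` Hz.
#'
#' @param s_bar current estimate (Hz), vectorised.
#' @param n_spikes spikes in this step per neuron.
#' @param tau_homeo filter time constant (s).
#' @param dt elapsed time (ms).
#' @return Updated estimate (Hz).
#' @export
update_rate_estimate <- function(s_bar, n_spikes, tau_homeo, dt) {
  s_bar * exp(-dt / (tau_homeo * 1000)) + n_spikes / tau_homeo
}

#' Perisomatic (triplet-rule) weight deltas
#'
#' Unclipped weight changes of the triplet rule for one synapse at one
#' event, using trace values taken just before the event's own increment:
#' at a postsynaptic spike `eta_gate * eta * w0 * A_plus * z_plus * z_slow`,
#' at a presynaptic spike `-eta_gate * eta * w0 * A_minus * z_minus`.
#'
#' @param event `"post"` or `"pre"`.
#' @param z_plus presynaptic trace at the event.
#' @param z_slow slow postsynaptic trace just before the event.
#' @param z_minus fast postsynaptic trace at the event.
#' @param A_minus homeostatic depression amplitude (see
#'   [homeostatic_amplitude()]).
#' @param w0 initial weight of the synapse (nS).
#' @param plasticity a [plasticity_params()] object.
#' @param eta_gate per-neuron learning-rate gate factor.
#' @return Weight change (nS), unclipped.
#' @export
plasticity_delta_perisomatic <- function(event, z_plus = 0, z_slow = 0,
                                         z_minus = 0, A_minus = 0,
                                         w0 = 1.8,
                                         plasticity = plasticity_params(),
                                         eta_gate = 1) {
  if (event == "post") {
    eta_gate * plasticity$eta * w0 * plasticity$A_plus * z_plus * z_slow
  } else if (event == "pre") {
    -eta_gate * plasticity$eta * w0 * A_minus * z_minus
  } else stop("plasticity_delta_perisomatic: event must be 'pre' or 'post'")
}

#' Dendritic weight deltas
#'
#' Unclipped weight changes of the dendritic rule: at a bAP event the
#' triplet potentiation (with bAP-driven postsynaptic traces); at a
#' presynaptic spike the homeostatic depression, the calcium-spike
#' potentiation `A_Ca * [V_d > theta_Ca]`, and the transmitter-induced
#' depression `alpha`. The entire per-event delta scales with the
#' per-neuron dendritic learning-rate gate, so a closed gate
#' (`eta_gate = 0`) freezes the synapse completely.
#'
#' @param event `"bAP"` or `"pre"`.
#' @param z_plus,z_slow,z_minus traces as in
#'   [plasticity_delta_perisomatic()] (postsynaptic traces driven by bAP
#'   events).
#' @param A_minus homeostatic depression amplitude.
#' @param V_d dendritic voltage at the presynaptic spike (mV).
#' @param w0 initial weight (nS).
#' @param plasticity a [plasticity_params()] object.
#' @param eta_gate per-neuron dendritic learning-rate gate factor.
#' @return Weight change (nS), unclipped.
#' @export
plasticity_delta_dendritic <- function(event, z_plus = 0, z_slow = 0,
                                       z_minus = 0, A_minus = 0,
                                       V_d = -70, w0 = 1.8,
                                       plasticity = plasticity_params(),
                                       eta_gate = 1) {
  if (event == "bAP") {
    eta_gate * plasticity$eta * w0 * plasticity$A_plus * z_plus * z_slow
  } else if (event == "pre") {
    ca <- as.numeric(V_d > plasticity$theta_Ca)
    eta_gate * (plasticity$eta * w0 *
                  (-A_minus * z_minus + plasticity$A_Ca * ca) -
                  plasticity$alpha)
  } else stop("plasticity_delta_dendritic: event must be 'pre' or 'bAP'")
}

#' Detect a back-propagating action potential
#'
#' A bAP event occurs when the dendritic voltage exceeds `theta_bAP`, a
#' somatic spike occurred within the last `bAP_window` ms, and no bAP
#' occurred within the last `bAP_refractory` ms.
#'
#' @param V_d dendritic voltage (mV), vectorised.
#' @param t current time (ms).
#' @param last_spike last somatic spike time per neuron (ms; `-Inf` if
#'   none).
#' @param last_bAP last bAP time per neuron (ms; `-Inf` if none).
#' @param plasticity a [plasticity_params()] object.
#' @return Logical vector of neurons emitting a bAP at `t`.
#' @export
detect_bAP <- function(V_d, t, last_spike, last_bAP,
                       plasticity = plasticity_params()) {
  V_d > plasticity$theta_bAP &
    (t - last_spike) <= plasticity$bAP_window + 1e-9 &
    (t - last_spike) >= -1e-9 &
    (t - last_bAP) >= plasticity$bAP_refractory - 1e-9
}
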