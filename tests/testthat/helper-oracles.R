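# Independent event-driven oracles used to cross-check both the exported
# step operations and the compiled engine. They evaluate traces in closed
# form (sums of exponentials over event times) and apply the learning
# rules event by event, with no shared code with the implementation path.

# Perisomatic triplet-rule weight trajectory for one synapse.
# A_minus may be a constant or a function of time (s_bar held fixed in
# most tests). Returns the full per-event delta list and the final weight.
oracle_perisomatic <- function(pre, post, w0 = 1.8, w_init = w0,
                               A_minus = 0, eta_gate = 1,
                               pp = plasticity_params(), w_max = pp$w_max) {
  events <- rbind(
    data.frame(t = pre, kind = rep("pre", length(pre))),
    data.frame(t = post, kind = rep("post", length(post))))
  events <- events[order(events$t), , drop = FALSE]
  w <- w_init
  deltas <- numeric(0)
  for (k in seq_len(nrow(events))) {
    t <- events$t[k]
    if (events$kind[k] == "post") {
      zp <- trace_at(t, pre, pp$tau_plus, before_event = TRUE)
      # the post spike's own increment is excluded (t - epsilon)
      zs <- trace_at(t, post, pp$tau_slow, before_event = TRUE)
      dw <- eta_gate * pp$eta * w0 * pp$A_plus * zp * zs
    } else {
      zm <- trace_at(t, post, pp$tau_minus, before_event = TRUE)
      dw <- -eta_gate * pp$eta * w0 * A_minus * zm
    }
    w_new <- min(max(w + dw, 0), w_max)
    deltas <- c(deltas, w_new - w)
    w <- w_new
  }
  list(w = w, deltas = deltas)
}

# Dendritic-rule weight trajectory: bAP events act as the postsynaptic
# spikes; V_d_at_pre gives the dendritic voltage seen at each presynaptic
# spike (recycled).
oracle_dendritic <- function(pre, bap, V_d_at_pre = -70, w0 = 1.8,
                             w_init = w0, A_minus = 0, eta_gate = 1,
                             pp = plasticity_params(), w_max = pp$w_max) {
  V_d_at_pre <- rep_len(V_d_at_pre, length(pre))
  events <- rbind(
    data.frame(t = pre, kind = rep("pre", length(pre)), vd = V_d_at_pre),
    if (length(bap)) data.frame(t = bap, kind = "bap", vd = NA_real_))
  events <- events[order(events$t), , drop = FALSE]
  w <- w_init
  deltas <- numeric(0)
  for (k in seq_len(nrow(events))) {
    t <- events$t[k]
    if (events$kind[k] == "bap") {
      zp <- trace_at(t, pre, pp$tau_plus, before_event = TRUE)
      zs <- trace_at(t, bap, pp$tau_slow, before_event = TRUE)
      dw <- eta_gate * pp$eta * w0 * pp$A_plus * zp * zs
    } else {
      zm <- trace_at(t, bap, pp$tau_minus, before_event = TRUE)
      ca <- as.numeric(events$vd[k] > pp$theta_Ca)
      dw <- eta_gate * (pp$eta * w0 * (-A_minus * zm + pp$A_Ca * ca) -
                          pp$alpha)
    }
    w_new <- min(max(w + dw, 0), w_max)
    deltas <- c(deltas, w_new - w)
    w <- w_new
  }
  list(w = w, deltas = deltas)
}

# A tiny network whose engine runs are fast enough for unit tests.
tiny_net <- function(N_E = 20, N_I = 5, N_poisson = 50, rate = 2) {
  network_params(N_E = N_E, N_I = N_I, N_poisson = N_poisson,
                 rate_poisson = rate)
}

# Forward-Euler reference integration of one pyramidal cell with frozen
# synaptic conductances, independent of both step_pyramidal and the
# engine (plain scalar arithmetic).
euler_pyramidal_ref <- function(V_s0, V_d0, n_steps, dt,
                                g = list(E_s = 0, I_s = 0, E_d = 0, I_d = 0),
                                np = neuron_params()) {
  V_s <- numeric(n_steps); V_d <- numeric(n_steps)
  vs <- V_s0; vd <- V_d0; os <- 0; od <- 0
  for (k in seq_len(n_steps)) {
    sig <- 1 / (1 + exp(-(vd - np$E_d) / np$D_d))
    Is <- -np$g_l * (vs - np$E_l) - g$E_s * vs - g$I_s * (vs - np$E_I) +
      np$lambda_scale * (np$g_s * sig + os)
    Id <- -np$g_l_d * (vd - np$E_l) - g$E_d * vd - g$I_d * (vd - np$E_I) +
      np$g_d * sig + od
    os_n <- os - dt * os / np$tau_omega_s
    od_n <- od + dt * (-od + np$a_omega_d * (vd - np$E_l)) / np$tau_omega_d
    vs <- vs + dt * Is / np$C_s
    vd <- vd + dt * Id / np$C_d
    os <- os_n; od <- od_n
    V_s[k] <- vs; V_d[k] <- vd
  }
  list(V_s = V_s, V_d = V_d)
}
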