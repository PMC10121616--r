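#' @useDynLib dendgate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# pack a projection into 0-based CSR (by source); plastic projections also
# get CSC (by target) with indices into the CSR-ordered weight vector
.pack_projection <- function(p, n_src, n_tgt, plastic = FALSE) {
  src <- p$src; tgt <- p$tgt
  # build_connectivity returns edges ordered by (src, tgt) already
  off <- c(0L, cumsum(tabulate(src, nbins = n_src)))
  out <- list(off = as.integer(off), tgt = as.integer(tgt - 1L), w = p$w)
  if (plastic) {
    out$w_init <- rep(p$w, length(tgt))
    oc <- order(tgt, src)
    csc_off <- c(0L, cumsum(tabulate(tgt, nbins = n_tgt)))
    out$csc_off <- as.integer(csc_off)
    out$csc_src <- as.integer(src[oc] - 1L)
    out$csc_widx <- as.integer(oc - 1L)
  }
  out
}

.pack_connectivity <- function(conn) {
  net <- conn$net
  list(
    pe = .pack_projection(conn$pe, net$N_poisson, net$N_E),
    pi = .pack_projection(conn$pi, net$N_poisson, net$N_I),
    ee_soma = .pack_projection(conn$ee_soma, net$N_E, net$N_E, plastic = TRUE),
    ee_dend = .pack_projection(conn$ee_dend, net$N_E, net$N_E, plastic = TRUE),
    ei = .pack_projection(conn$ei, net$N_E, net$N_I),
    ie_soma = .pack_projection(conn$ie_soma, net$N_I, net$N_E),
    ie_dend = .pack_projection(conn$ie_dend, net$N_I, net$N_E),
    ii = .pack_projection(conn$ii, net$N_I, net$N_I)
  )
}

#' Derive deterministic child seeds from a master seed
#'
#' Connectivity, initial conditions and the Poisson input draw from
#' independent child streams of one master seed, so that two runs
#' differing only in gate settings share identical wiring and inputs.
#'
#' @param seed master seed (integer).
#' @return Named integer vector with `connectivity`, `init`, `poisson`.
#' @export
child_seeds <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 3)
  c(connectivity = s[1], init = s[2], poisson = s[3])
}

#' Run one network simulation
#'
#' Executes the full protocol: a warm-up phase of
#' `max(warmup_factor * tau_homeo, warmup_floor)` seconds with plasticity
#' off, calibration of the homeostatic target rate `kappa` as the mean
#' population rate over the warm-up's last 2 s (unless `plasticity$kappa`
#' is already set), then the plasticity-on main phase of `sim$duration`
#' seconds. Fully deterministic given `seed` (see [child_seeds()]).
#'
#' A runaway (exploding) network is not an error: rate saturation at the
#' refractory limit is recorded like any other outcome, since explosions
#' are what the stability analysis measures. Only numerical
#' non-finiteness aborts.
#'
#' @param net a [network_params()] object (e.g. from [make_fixture()]).
#' @param neuron a [neuron_params()] object.
#' @param plasticity a [plasticity_params()] object.
#' @param gates a [gating_config()] object; default identity.
#' @param sim a [sim_config()] object.
#' @param seed master seed.
#' @param conn optional pre-built [build_connectivity()] result (overrides
#'   the connectivity child stream).
#' @param input optional pre-built [generate_poisson()] result; must cover
#'   warm-up plus main duration.
#' @return A list of class `"dendgate_run"`: spike records (`spikes_E`,
#'   `spikes_I`, `bap` data.frames with `time` in ms and 1-based ids,
#'   main-phase times relative to plasticity onset at 0), `rate` (
#'   data.frame `t_bin`, `rate_hz` per completed bin), `kappa` (Hz),
#'   final weight vectors with their edge lists, cumulative absolute and
#'   net weight change per compartment, per-snapshot trajectories,
#'   optional current means and voltage traces, `early_stopped`,
#'   `t_end` (s of main phase simulated), and a config echo.
#' @export
run_simulation <- function(net, neuron = neuron_params(),
                           plasticity = plasticity_params(),
                           gates = NULL, sim = sim_config(),
                           seed = 1L, conn = NULL, input = NULL) {
  stopifnot(inherits(net, "network_params"))
  if (is.null(gates)) gates <- gating_config(net$N_E)
  if (gates$n_E != net$N_E)
    stop("run_simulation: gates built for a different N_E")
  if (!is.na(sim$tau_homeo)) plasticity$tau_homeo <- sim$tau_homeo

  seeds <- child_seeds(seed)
  if (is.null(conn)) conn <- build_connectivity(net, seeds[["connectivity"]])

  # plasticity-off runs need no warm-up: kappa is never used
  warmup_s <- if (!is.na(sim$warmup_override)) sim$warmup_override
  else if (!sim$plasticity_on || plasticity$eta == 0) 0
  else max(sim$warmup_factor * plasticity$tau_homeo, sim$warmup_floor)
  if (warmup_s < 2 && sim$plasticity_on && plasticity$eta != 0 &&
      is.na(plasticity$kappa))
    stop("run_simulation: kappa calibration needs a warm-up of >= 2 s")
  total_s <- warmup_s + sim$duration

  if (is.null(input)) {
    input <- generate_poisson(net$N_poisson, net$rate_poisson, total_s,
                              seeds[["poisson"]])
  } else if (input$duration < total_s * 1000 - 1e-6) {
    stop("run_simulation: supplied input does not cover the run duration")
  }

  old <- .Random.seed_save()
  set.seed(seeds[["init"]])
  draw_v <- function(n, th) {
    v <- stats::rnorm(n, -70, 10)
    while (any(bad <- v > th)) v[bad] <- stats::rnorm(sum(bad), -70, 10)
    v
  }
  init <- list(V_s = draw_v(net$N_E, neuron$v_theta),
               V_d = rep(-70, net$N_E),
               V_I = draw_v(net$N_I, neuron$v_theta_I))
  .Random.seed_restore(old)

  taus <- .syn_tau_map(neuron, sim$syn_tau_mapping)
  csim <- list(dt = sim$dt,
               tau_E_soma = taus[["E_soma"]], tau_I_soma = taus[["I_soma"]],
               tau_E_dend = taus[["E_dend"]], tau_I_dend = taus[["I_dend"]],
               warmup_ms = warmup_s * 1000,
               main_ms = sim$duration * 1000,
               bin_ms = sim$rate_bin * 1000,
               baseline_bins = as.integer(
                 round(.baseline_window_s(sim) / sim$rate_bin)),
               snapshot_ms = sim$snapshot_interval * 1000,
               record_currents = sim$record_currents,
               record_bAP = sim$record_bAP,
               record_voltages = as.integer(sim$record_voltages - 1L),
               stop_on_explosion = sim$stop_on_explosion,
               stop_factor = sim$stop_factor,
               plasticity_on = sim$plasticity_on)

  raw <- sim_run_cpp(unclass(neuron), unclass(plasticity), unclass(gates),
                     .pack_connectivity(conn),
                     list(time = input$time,
                          source = as.integer(input$source - 1L)),
                     init, csim)

  warm_ms <- warmup_s * 1000
  mainE <- raw$spike_E_time > warm_ms
  mainI <- raw$spike_I_time > warm_ms
  n_bins <- length(raw$bin_counts)
  rate <- data.frame(
    t_bin = (seq_len(n_bins) - 0.5) * sim$rate_bin,
    rate_hz = raw$bin_counts / (net$N_E * sim$rate_bin))

  structure(list(
    spikes_E = data.frame(time = raw$spike_E_time[mainE] - warm_ms,
                          neuron = raw$spike_E_id[mainE]),
    spikes_I = data.frame(time = raw$spike_I_time[mainI] - warm_ms,
                          neuron = raw$spike_I_id[mainI]),
    spikes_E_warmup = data.frame(time = raw$spike_E_time[!mainE],
                                 neuron = raw$spike_E_id[!mainE]),
    bap = data.frame(time = raw$bap_time - warm_ms, neuron = raw$bap_id),
    rate = rate,
    kappa = raw$kappa,
    W_soma = raw$W_soma, W_dend = raw$W_dend,
    W0_soma = rep(conn$ee_soma$w, length(raw$W_soma)),
    W0_dend = rep(conn$ee_dend$w, length(raw$W_dend)),
    edges_soma = data.frame(src = conn$ee_soma$src, tgt = conn$ee_soma$tgt),
    edges_dend = data.frame(src = conn$ee_dend$src, tgt = conn$ee_dend$tgt),
    cum_abs_soma = raw$cum_abs_soma, cum_net_soma = raw$cum_net_soma,
    cum_abs_dend = raw$cum_abs_dend, cum_net_dend = raw$cum_net_dend,
    snapshots = as.data.frame(raw$snapshots),
    currents = raw$currents,
    voltages = raw$voltages,
    early_stopped = raw$early_stopped,
    t_end = (raw$t_end_ms - warm_ms) / 1000,
    warmup_s = warmup_s,
    net = net, sim = sim, gates = gates,
    tau_homeo = plasticity$tau_homeo,
    seed = seed),
    class = "dendgate_run")
}

# The two printed synaptic decay constants admit two readings; see the
# methods vignette. "compartment" (default): tau_syn_s governs all
# somatic-compartment (and inhibitory-cell) synapses, tau_syn_d all
# dendritic ones. "type": tau_syn_s is the excitatory and tau_syn_d the
# inhibitory decay constant, in both compartments and in inhibitory cells.
.syn_tau_map <- function(neuron, mapping) {
  if (identical(mapping, "type")) {
    c(E_soma = neuron$tau_syn_s, I_soma = neuron$tau_syn_d,
      E_dend = neuron$tau_syn_s, I_dend = neuron$tau_syn_d)
  } else {
    c(E_soma = neuron$tau_syn_s, I_soma = neuron$tau_syn_s,
      E_dend = neuron$tau_syn_d, I_dend = neuron$tau_syn_d)
  }
}

.baseline_window_s <- function(sim) {
  if (sim$duration < sim$baseline_window) sim$duration / 4
  else sim$baseline_window
}

#' @export
print.dendgate_run <- function(x, ...) {
  cat(sprintf(
    "<dendgate_run> N_E=%d N_I=%d tau=%gs kappa=%.3f Hz duration=%gs%s\n",
    x$net$N_E, x$net$N_I, x$tau_homeo, x$kappa, x$t_end,
    if (x$early_stopped) " [stopped: explosion]" else ""))
  if (nrow(x$rate))
    cat(sprintf("  mean rate %.2f Hz, max bin %.2f Hz; |dW| soma %.3g nS, dend %.3g nS\n",
                mean(x$rate$rate_hz), max(x$rate$rate_hz),
                x$cum_abs_soma, x$cum_abs_dend))
  invisible(x)
}

#' Construct a concrete gate configuration
#'
#' Translates an experiment-level gate description ("double the learning
#' rate in the dendrite", "15% more excitability in a quarter of the
#' cells") into a per-neuron [gating_config()]. The gated subpopulation
#' for `subset = "quarter"` is the first `ceiling(n_E/4)` neuron indices;
#' since connectivity is an exchangeable random graph, which quarter is
#' gated is immaterial.
#'
#' @param n_E number of excitatory neurons.
#' @param gate one of `"eta"` (learning rate), `"gamma"` (excitability),
#'   `"threshold"` (additive shift, mV), `"inhibition"` (scale on
#'   inhibitory weights).
#' @param value gate value: a factor for `eta`/`gamma`/`inhibition`, a
#'   shift in mV for `threshold`.
#' @param compartment `"soma"`, `"dendrite"` or `"both"` (threshold gates
#'   are somatic by nature and accept `"both"`/`"soma"` only).
#' @param subset `"all"` or `"quarter"`.
#' @param base an existing [gating_config()] to modify.
#' @return A [gating_config()].
#' @export
apply_gates <- function(n_E, gate, value, compartment = "both",
                        subset = "all", base = NULL) {
  gate <- match.arg(gate, c("eta", "gamma", "threshold", "inhibition"))
  compartment <- match.arg(compartment, c("both", "soma", "dendrite"))
  subset <- match.arg(subset, c("all", "quarter"))
  g <- if (is.null(base)) gating_config(n_E) else base
  idx <- if (subset == "all") seq_len(n_E) else seq_len(ceiling(n_E / 4))
  mask <- rep(FALSE, n_E); mask[idx] <- TRUE
  soma <- compartment %in% c("both", "soma")
  dend <- compartment %in% c("both", "dendrite")
  if (gate == "eta") {
    if (soma) g$eta_soma[idx] <- value
    if (dend) g$eta_dend[idx] <- value
  } else if (gate == "gamma") {
    if (soma) g$gamma_soma[idx] <- value
    if (dend) g$gamma_dend[idx] <- value
  } else if (gate == "inhibition") {
    if (soma) g$inh_scale_soma[idx] <- value
    if (dend) g$inh_scale_dend[idx] <- value
  } else { # threshold
    if (compartment == "dendrite")
      stop("apply_gates: the spiking threshold is somatic")
    g$v_theta_shift[idx] <- value
  }
  g$subpopulation_mask <- mask
  g
}

#' Schedule the bAP current window for a spike
#'
#' Returns the grid-aligned time window during which the bAP current
#' pulse of amplitude `c_d` is active in the dendrite, i.e.
#' `[spike + bAP_delay, spike + bAP_delay + bAP_duration]`.
#'
#' @param spike_time somatic spike time (ms).
#' @param params a [neuron_params()] object.
#' @return Numeric vector `c(on, off)` in ms.
#' @export
schedule_bAP <- function(spike_time, params = neuron_params()) {
  c(on = spike_time + params$bAP_delay,
    off = spike_time + params$bAP_delay + params$bAP_duration)
}
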