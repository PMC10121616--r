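# Engine tests: the compiled clock-driven loop is cross-checked against
# pure-R forward-Euler integration and event-driven plasticity replay.

test_that("pyramidal step has the leak-only membrane time constant", {
  np <- neuron_params(g_s = 0, g_d = 0) # decouple the nonlinearity
  st <- list(V_s = -60, V_d = -60, omega_s = 0, omega_d = 0,
             refractory_until = -Inf, last_spike = -Inf, t = 0)
  inp <- list(g_E_soma = 0, g_I_soma = 0, g_E_dend = 0, g_I_dend = 0,
              bap_active = FALSE)
  dt <- 0.01
  for (k in seq_len(2000)) st <- step_pyramidal(st, inp, np, dt = dt)
  # after tau_m = 20 ms the deviation from rest has decayed e-fold;
  # note the dendrite relaxes with its own tau and feeds omega_d
  expect_equal(st$V_s + 70, 10 * exp(-1), tolerance = 2e-3)
  expect_length(st$spikes, 0)
})

test_that("pyramidal step respects threshold, reset and refractoriness", {
  np <- neuron_params()
  st <- list(V_s = c(-49, -49), V_d = c(-70, -70), omega_s = c(0, 0),
             omega_d = c(0, 0), refractory_until = c(-Inf, 100),
             last_spike = c(-Inf, -Inf), t = 0)
  inp <- list(g_E_soma = c(50, 50), g_I_soma = 0, g_E_dend = 0,
              g_I_dend = 0, bap_active = FALSE)
  st <- step_pyramidal(st, inp, np, dt = 0.1)
  expect_identical(st$spikes, 1L) # neuron 2 is refractory
  expect_equal(st$V_s[1], -70)
  expect_equal(st$V_s[2], -70) # clamped at reset during refractoriness
  expect_equal(st$omega_s[1], np$b_omega_s, tolerance = 1e-12)
  expect_equal(st$refractory_until[1], 0.1 + 8.3)
})

test_that("inhibitory step decays with tau_m_I and spikes at threshold", {
  np <- neuron_params()
  st <- list(V = -60, refractory_until = -Inf, t = 0)
  inp <- list(g_E = 0, g_I = 0)
  for (k in seq_len(1000)) st <- step_inhibitory(st, inp, np, dt = 0.01)
  expect_equal(st$V + 70, 10 * exp(-1), tolerance = 2e-3) # 10 ms constant
  # fixed point at rest
  st2 <- step_inhibitory(list(V = -70, refractory_until = -Inf, t = 0),
                         inp, np, dt = 0.1)
  expect_equal(st2$V, -70)
  # crossing threshold emits a spike and resets
  st3 <- list(V = -50.5, refractory_until = -Inf, t = 0)
  st3 <- step_inhibitory(st3, list(g_E = 30, g_I = 0), np, dt = 0.1)
  expect_identical(st3$spikes, 1L)
  expect_equal(st3$V, -70)
})

test_that("conductance decay is exactly exponential and non-negative", {
  expect_equal(decay_conductance(1.6, 16, 16), 1.6 * exp(-1),
               tolerance = 1e-14)
  expect_identical(decay_conductance(0, 5, 16), 0)
  g <- decay_conductance(runif(50, 0, 10), 0.1, 7)
  expect_true(all(g >= 0))
})

test_that("voltage integration converges linearly under step halving", {
  # frozen synaptic input, 100 ms, forward Euler at dt, dt/2, dt/4
  g <- list(E_s = 3, I_s = 10, E_d = 1, I_d = 4)
  sol <- lapply(c(0.1, 0.05, 0.025), function(dt)
    euler_pyramidal_ref(-60, -60, round(100 / dt), dt, g))
  v1 <- sol[[1]]$V_s[length(sol[[1]]$V_s)]
  v2 <- sol[[2]]$V_s[length(sol[[2]]$V_s)]
  v3 <- sol[[3]]$V_s[length(sol[[3]]$V_s)]
  # successive refinements differ by a factor ~2 (first-order scheme)
  expect_equal((v1 - v2) / (v2 - v3), 2, tolerance = 0.25)
})

test_that("engine voltages match the R reference on an input-free neuron", {
  # one E cell, no external input: dynamics reduce to the coupled
  # soma/dendrite equations from the Gaussian initial condition
  net <- network_params(N_E = 1, N_I = 1, N_poisson = 1, rate_poisson = 0)
  run <- run_simulation(net, sim = sim_config(
    duration = 0.2, plasticity_on = FALSE, record_voltages = 1), seed = 5)
  # replicate the initial condition from the init child stream
  seeds <- child_seeds(5)
  set.seed(seeds[["init"]])
  v0 <- stats::rnorm(1, -70, 10)
  while (v0 > -50) v0 <- stats::rnorm(1, -70, 10)
  ref <- euler_pyramidal_ref(v0, -70, 2000, 0.1)
  expect_equal(as.numeric(run$voltages$V_s[1, ]), ref$V_s, tolerance = 1e-9)
  expect_equal(as.numeric(run$voltages$V_d[1, ]), ref$V_d, tolerance = 1e-9)
})

test_that("engine runs are reproducible and gate-neutral at identity", {
  net <- tiny_net(N_E = 40, N_I = 10, N_poisson = 100, rate = 10)
  sim <- sim_config(duration = 2, tau_homeo = 0.5, warmup_override = 3)
  pl <- plasticity_params(kappa = 5)
  r1 <- run_simulation(net, plasticity = pl, sim = sim, seed = 7)
  r2 <- run_simulation(net, plasticity = pl, sim = sim, seed = 7)
  expect_identical(r1$spikes_E, r2$spikes_E)
  expect_identical(r1$spikes_I, r2$spikes_I)
  expect_identical(r1$W_soma, r2$W_soma)
  # explicit identity gating takes the same code path and the same result
  g_id <- apply_gates(net$N_E, "eta", 1, "both", "all")
  r3 <- run_simulation(net, plasticity = pl, gates = g_id, sim = sim,
                       seed = 7)
  expect_identical(r1$spikes_E, r3$spikes_E)
  expect_identical(r1$W_dend, r3$W_dend)
})

test_that("closed learning-rate gates leave weights bit-identical", {
  net <- tiny_net(N_E = 40, N_I = 10, N_poisson = 100, rate = 10)
  sim <- sim_config(duration = 2, tau_homeo = 0.5, warmup_override = 3)
  pl <- plasticity_params(kappa = 5)
  g0 <- gating_config(net$N_E, eta_soma = 0, eta_dend = 0)
  r <- run_simulation(net, plasticity = pl, gates = g0, sim = sim, seed = 7)
  expect_gt(nrow(r$spikes_E), 0) # the network did fire
  expect_identical(r$W_soma, r$W0_soma)
  expect_identical(r$W_dend, r$W0_dend)
  expect_identical(r$cum_abs_soma + r$cum_abs_dend, 0)
  # base learning rate zero: plasticity fully off
  r0 <- run_simulation(net, plasticity = plasticity_params(eta = 0),
                       sim = sim_config(duration = 2), seed = 7)
  expect_identical(r0$W_soma, r0$W0_soma)
})

test_that("spike and bAP trains respect their refractory periods", {
  net <- tiny_net(N_E = 30, N_I = 8, N_poisson = 200, rate = 15)
  run <- run_simulation(net, sim = sim_config(
    duration = 4, plasticity_on = FALSE), seed = 13)
  expect_gt(nrow(run$spikes_E), 50)
  for (df in list(run$spikes_E, run$spikes_I)) {
    isis <- unlist(lapply(split(df$time, df$neuron), function(ts)
      diff(sort(ts))), use.names = FALSE)
    if (length(isis)) expect_gte(min(isis), 8.3 - 1e-6)
  }
  if (nrow(run$bap) > 0) {
    dbap <- unlist(lapply(split(run$bap$time, run$bap$neuron), function(ts)
      diff(sort(ts))), use.names = FALSE)
    if (length(dbap)) expect_gte(min(dbap), 5.8 - 1e-6)
  }
})

test_that("engine plasticity matches event-driven replay of its own record", {
  # run a driven network with preset kappa and zero warm-up, then rebuild
  # selected synapses' weight trajectories from the recorded spikes, bAPs
  # and dendritic voltages using the closed-form trace oracle
  net <- tiny_net(N_E = 25, N_I = 6, N_poisson = 150, rate = 12)
  pl <- plasticity_params(kappa = 4)
  tau_h <- 0.5
  sim <- sim_config(duration = 4, tau_homeo = tau_h, warmup_override = 0,
                    record_voltages = 1:net$N_E)
  run <- run_simulation(net, plasticity = pl, sim = sim, seed = 23)
  expect_gt(nrow(run$spikes_E), 30)

  sp <- split(run$spikes_E$time, factor(run$spikes_E$neuron, 1:net$N_E))
  bp <- split(run$bap$time, factor(run$bap$neuron, 1:net$N_E))
  tau_ms <- tau_h * 1000
  sbar_at <- function(i, t) { # pre-increment, exact exponential filter
    ts <- sp[[i]][sp[[i]] < t - 1e-9]
    sum(exp(-(t - ts) / tau_ms)) * 1000 / tau_ms
  }
  homeo_k <- pl$A_plus * (pl$tau_plus / 1000) * (pl$tau_slow / 1000) /
    ((pl$tau_minus / 1000) * pl$kappa)
  vd_at <- function(i, t) {
    run$voltages$V_d[i, which.min(abs(run$voltages$t - t))]
  }

  replay_soma <- function(j, i, w0) {
    pre <- sp[[j]]; post <- sp[[i]]
    ev <- rbind(data.frame(t = pre, kind = rep("pre", length(pre))),
                data.frame(t = post, kind = rep("post", length(post))))
    ev <- ev[order(ev$t, ev$kind == "pre"), , drop = FALSE] # post first at ties
    w <- w0
    for (k in seq_len(nrow(ev))) {
      t <- ev$t[k]
      dw <- if (ev$kind[k] == "post") {
        pl$eta * w0 * pl$A_plus * trace_at(t, pre, pl$tau_plus) *
          trace_at(t, post, pl$tau_slow)
      } else {
        -pl$eta * w0 * homeo_k * sbar_at(i, t)^2 *
          trace_at(t, post, pl$tau_minus)
      }
      w <- min(max(w + dw, 0), pl$w_max)
    }
    w
  }
  replay_dend <- function(j, i, w0) {
    pre <- sp[[j]]; bap <- bp[[i]]
    ev <- rbind(data.frame(t = pre, kind = rep("pre", length(pre))),
                data.frame(t = bap, kind = rep("bap", length(bap))))
    ev <- ev[order(ev$t, ev$kind == "pre"), , drop = FALSE]
    w <- w0
    for (k in seq_len(nrow(ev))) {
      t <- ev$t[k]
      dw <- if (ev$kind[k] == "bap") {
        pl$eta * w0 * pl$A_plus * trace_at(t, pre, pl$tau_plus) *
          trace_at(t, bap, pl$tau_slow)
      } else {
        ca <- if (vd_at(i, t) > pl$theta_Ca) pl$A_Ca else 0
        pl$eta * w0 * (-homeo_k * sbar_at(i, t)^2 *
                         trace_at(t, bap, pl$tau_minus) + ca) - pl$alpha
      }
      w <- min(max(w + dw, 0), pl$w_max)
    }
    w
  }

  set.seed(1)
  for (k in sample(nrow(run$edges_soma), 6)) {
    expect_equal(run$W_soma[k],
                 replay_soma(run$edges_soma$src[k], run$edges_soma$tgt[k],
                             run$W0_soma[k]),
                 tolerance = 1e-6)
  }
  for (k in sample(nrow(run$edges_dend), 6)) {
    expect_equal(run$W_dend[k],
                 replay_dend(run$edges_dend$src[k], run$edges_dend$tgt[k],
                             run$W0_dend[k]),
                 tolerance = 1e-6)
  }
  # global weight bounds on the full matrices
  expect_true(all(run$W_soma >= 0 & run$W_soma <= pl$w_max))
  expect_true(all(run$W_dend >= 0 & run$W_dend <= pl$w_max))
})

test_that("bAP scheduling matches the kernel window", {
  w <- schedule_bAP(100)
  expect_equal(unname(w), c(100.5, 102.5))
  np <- neuron_params()
  expect_equal(bap_kernel(101.7, 100, np), 1)
  expect_equal(bap_kernel(99.9, 100, np), 0)
})

test_that("gate construction covers the experiment vocabulary", {
  g <- apply_gates(100, "eta", 2, "dendrite", "all")
  expect_true(all(g$eta_dend == 2) && all(g$eta_soma == 1))
  g <- apply_gates(100, "gamma", 1.15, "soma", "all")
  expect_true(all(g$gamma_soma == 1.15) && all(g$gamma_dend == 1))
  g <- apply_gates(100, "inhibition", 0.7, "dendrite", "all")
  expect_true(all(g$inh_scale_dend == 0.7) && all(g$inh_scale_soma == 1))
  g <- apply_gates(100, "threshold", 2, "both", "all")
  expect_true(all(g$v_theta_shift == 2))
  g <- apply_gates(100, "eta", 2, "both", "quarter")
  expect_identical(sum(g$subpopulation_mask), 25L)
  expect_true(all(g$eta_dend[1:25] == 2) && all(g$eta_dend[26:100] == 1))
  expect_error(apply_gates(10, "nonsense", 1), "arg")
  expect_error(apply_gates(10, "threshold", 1, "dendrite"), "somatic")
})
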