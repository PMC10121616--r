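test_that("dendritic nonlinearity is the calibrated sigmoid", {
  np <- neuron_params()
  expect_equal(dendritic_nonlinearity(-38, np), 0.5)
  expect_equal(dendritic_nonlinearity(-32, np), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(dendritic_nonlinearity(-1e4, np), 0, tolerance = 1e-12)
  expect_equal(dendritic_nonlinearity(1e4, np), 1, tolerance = 1e-12)
  v <- seq(-90, 0, by = 0.5)
  act <- dendritic_nonlinearity(v, np)
  expect_true(all(diff(act) > 0))
  expect_true(all(act > 0 & act < 1))
})

test_that("bAP kernel is a 2 ms pulse delayed by 0.5 ms", {
  expect_equal(bap_kernel(100.3, 100.0), 0)
  expect_equal(bap_kernel(101.0, 100.0), 1)
  expect_equal(bap_kernel(102.6, 100.0), 0)
  expect_equal(bap_kernel(100.5, 100.0), 1) # inclusive bounds
  expect_equal(bap_kernel(102.5, 100.0), 1)
  expect_equal(bap_kernel(50, numeric(0)), 0)
  # pulses superpose
  expect_equal(bap_kernel(105.0, c(100.0, 104.0)), 1)
  expect_equal(bap_kernel(103.0, c(100.0, 102.0)), 1)
})

test_that("stepped traces match the closed-form event evaluation", {
  set.seed(7)
  for (case in 1:8) {
    tau <- sample(c(16.8, 33.7, 114), 1)
    n_ev <- sample(5:50, 1)
    dt <- 0.1
    ev_steps <- sort(sample.int(2000, n_ev))
    z <- 0
    for (k in 1:2000) {
      z <- update_trace(z, dt, tau, n_events = sum(ev_steps == k))
    }
    z_ref <- trace_at(2000 * dt, ev_steps * dt, tau, before_event = FALSE)
    expect_equal(z, z_ref, tolerance = 1e-10)
    expect_gte(z, 0)
  }
  # pure decay over one time constant
  expect_equal(update_trace(1, 16.8, 16.8), exp(-1), tolerance = 1e-12)
  # superposition of two spikes dt apart
  z2 <- trace_at(10, c(0, 10), 20, before_event = FALSE)
  expect_equal(z2, 1 + exp(-10 / 20), tolerance = 1e-12)
})

test_that("homeostatic depression amplitude follows the quadratic law", {
  pp <- plasticity_params(kappa = 5)
  expect_equal(homeostatic_amplitude(0, pp), 0)
  # direct arithmetic with the default amplitudes and time constants
  expect_equal(homeostatic_amplitude(5, pp),
               6.5e-3 * 0.0168 * 0.114 * 5 / 0.0337, tolerance = 1e-10)
  expect_equal(homeostatic_amplitude(5, pp), 1.847e-3, tolerance = 1e-3)
  expect_equal(homeostatic_amplitude(10, pp) / homeostatic_amplitude(5, pp),
               4, tolerance = 1e-12)
  expect_error(homeostatic_amplitude(1, plasticity_params()), "kappa")
  expect_error(homeostatic_amplitude(-1, pp), "s_bar")
})

test_that("rate estimate converges to the true rate and decays without spikes", {
  set.seed(11)
  tau_h <- 2 # s
  dt <- 1 # ms
  rate <- 8 # Hz
  s <- 0
  n_steps <- 40000 # 40 s
  for (k in seq_len(n_steps)) {
    n_sp <- stats::rpois(1, rate * dt / 1000)
    s <- update_rate_estimate(s, n_sp, tau_h, dt)
  }
  # stationary mean is the rate; sd of the filtered estimate ~ sqrt(r/(2 tau))
  expect_equal(s, rate, tolerance = 0.35)
  expect_equal(update_rate_estimate(4, 0, 2, 2000), 4 * exp(-1),
               tolerance = 1e-12)
})

test_that("perisomatic rule reproduces the worked pairing examples", {
  pp <- plasticity_params(kappa = 5)
  # first pairing: no prior post, so z_slow = 0 at the post and z_minus = 0
  # at the pre
  res <- oracle_perisomatic(pre = 0, post = 10, w_init = 1.8,
                            A_minus = homeostatic_amplitude(5, pp), pp = pp)
  expect_equal(res$w, 1.8)
  expect_true(all(res$deltas == 0))

  # pre at 0, posts at 10 and 20 ms: triplet potentiation at the second post
  res <- oracle_perisomatic(pre = 0, post = c(10, 20), w_init = 1.8,
                            A_minus = 0, pp = pp)
  expected <- 5 * 1.8 * 6.5e-3 * exp(-20 / 16.8) * exp(-10 / 114)
  expect_equal(sum(res$deltas), expected, tolerance = 1e-12)
  expect_equal(expected, 0.0163, tolerance = 2e-3)

  # the exported per-event delta agrees with the oracle's event arithmetic
  dw <- plasticity_delta_perisomatic(
    "post", z_plus = exp(-20 / 16.8), z_slow = exp(-10 / 114),
    w0 = 1.8, plasticity = pp)
  expect_equal(dw, expected, tolerance = 1e-12)

  # closed learning-rate gate
  res0 <- oracle_perisomatic(pre = c(0, 5, 30), post = c(10, 20, 31),
                             w_init = 1.8, A_minus = 1e-3, eta_gate = 0,
                             pp = pp)
  expect_identical(res0$w, 1.8)
})

test_that("dendritic rule reproduces the Ca-spike and depression examples", {
  pp <- plasticity_params(kappa = 5)
  # presynaptic spike with depolarised dendrite: Ca potentiation minus the
  # transmitter-induced depression
  res <- oracle_dendritic(pre = 0, bap = numeric(0), V_d_at_pre = -35,
                          w_init = 1.8, A_minus = 0, pp = pp)
  expect_equal(res$deltas[1], 5 * 1.8 * 7.2e-2 - 1e-4, tolerance = 1e-12)
  expect_equal(res$deltas[1], 0.6479, tolerance = 1e-4)

  # hyperpolarised dendrite: transmitter-induced depression only
  res <- oracle_dendritic(pre = 0, bap = numeric(0), V_d_at_pre = -45,
                          w_init = 1.8, A_minus = 0, pp = pp)
  expect_equal(res$deltas[1], -1e-4, tolerance = 1e-9)

  dw <- plasticity_delta_dendritic("pre", V_d = -35, w0 = 1.8,
                                   plasticity = pp)
  expect_equal(dw, 5 * 1.8 * 7.2e-2 - 1e-4, tolerance = 1e-12)

  # saturation at w_max
  res <- oracle_dendritic(pre = c(0, 5, 10, 15, 20, 25), bap = numeric(0),
                          V_d_at_pre = -30, w_init = 9.9, A_minus = 0,
                          pp = pp)
  expect_equal(res$w, pp$w_max)
})

test_that("weights stay within [0, w_max] under random event sequences", {
  set.seed(3)
  pp <- plasticity_params(kappa = 5)
  for (case in 1:5) {
    pre <- sort(runif(40, 0, 2000))
    post <- sort(runif(40, 0, 2000))
    res <- oracle_perisomatic(pre, post, w_init = runif(1, 0, 10),
                              A_minus = homeostatic_amplitude(8, pp),
                              pp = pp)
    w_traj <- cumsum(res$deltas) + res$w - sum(res$deltas)
    expect_true(all(w_traj >= 0 & w_traj <= pp$w_max + 1e-12))
  }
})

test_that("bAP detection requires voltage, recency and refractoriness", {
  pp <- plasticity_params()
  expect_true(detect_bAP(-45, t = 100, last_spike = 99, last_bAP = 90, pp))
  expect_false(detect_bAP(-55, t = 100, last_spike = 99, last_bAP = 90, pp))
  expect_false(detect_bAP(-45, t = 100, last_spike = 99, last_bAP = 98, pp))
  expect_false(detect_bAP(-45, t = 100, last_spike = 96, last_bAP = 90, pp))
  # boundary: exactly at the window and refractory limits
  expect_true(detect_bAP(-45, t = 100, last_spike = 97, last_bAP = 94.2, pp))
})

test_that("parameter constructors validate their invariants", {
  expect_error(neuron_params(C_s = -1), "strictly positive")
  expect_error(neuron_params(E_I = -40), "E_I")
  expect_error(neuron_params(lambda_scale = 1.5), "lambda_scale")
  expect_error(network_params(p_connect = 0), "p_connect")
  expect_error(network_params(w_EE = -1), "weights")
  expect_error(plasticity_params(w_max = 0), "w_max")
  expect_error(plasticity_params(kappa = -2), "kappa")
  expect_error(gating_config(10, eta_soma = -1), "eta_soma")
  g <- gating_config(10)
  expect_true(all(g$gamma_soma == 1) && all(g$v_theta_shift == 0) &&
                all(g$subpopulation_mask))
  expect_length(g$eta_dend, 10)
})
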