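test_that("explosion factor reproduces the worked ratios and threshold rule", {
  # constant trace
  ef <- explosion_factor(rep(5, 100))
  expect_equal(ef$EF, 1)
  expect_true(ef$stable)
  # baseline 5 Hz over the first 50 bins, one 15.8 Hz bin later
  trace <- c(rep(5, 50), rep(5, 49), 15.8)
  ef <- explosion_factor(trace)
  expect_equal(ef$r_baseline, 5)
  expect_equal(ef$EF, 3.16)
  expect_false(ef$stable)
  # EF exactly 1.5 is classified stable
  ef <- explosion_factor(c(rep(4, 50), 6))
  expect_equal(ef$EF, 1.5)
  expect_true(ef$stable)
  # maximality over bins
  trace <- runif(120, 2, 4)
  ef <- explosion_factor(trace)
  expect_true(all(ef$EF >= trace / ef$r_baseline))
  # short runs fall back to a first-quarter baseline
  ef <- explosion_factor(rep(3, 40))
  expect_true(ef$shrunk_baseline)
  expect_equal(ef$baseline_used, 10)
  expect_error(explosion_factor(c(0, 0, 0, 1)), "zero baseline")
  expect_error(explosion_factor(3), "two rate bins")
})

test_that("critical tau takes the largest stable value below instability", {
  expect_equal(critical_tau(c(5, 10, 15, 20),
                            c(TRUE, TRUE, FALSE, FALSE)), 10)
  # a re-stabilised point above the first instability does not count
  expect_equal(critical_tau(c(5, 10, 15), c(TRUE, FALSE, TRUE)), 5)
  expect_true(is.na(critical_tau(c(5, 10), c(FALSE, FALSE))))
  expect_equal(critical_tau(c(5, 10), c(TRUE, TRUE)), 10)
  # order independence
  expect_equal(critical_tau(c(15, 5, 10), c(FALSE, TRUE, TRUE)), 10)
  expect_error(critical_tau(5, TRUE), "two grid points")
  # accepts stability_result lists
  res <- list(structure(list(stable = TRUE), class = "stability_result"),
              structure(list(stable = FALSE), class = "stability_result"))
  expect_equal(critical_tau(c(2, 4), res), 2)
})

test_that("spike statistics recover rates and interval variability", {
  # perfectly periodic train: CV 0
  per <- data.frame(time = seq(0, 10000, by = 100), neuron = 1)
  st <- spike_statistics(per, duration = 10, n_neurons = 2)
  expect_equal(st$rates[1], length(per$time) / 10)
  expect_equal(st$cv[1], 0)
  expect_true(is.na(st$cv[2])) # silent neuron
  expect_equal(st$rates[2], 0)

  # Poisson train: CV near 1
  set.seed(31)
  n <- 800
  ts <- cumsum(rexp(n, rate = 1 / 100)) # 10 Hz in ms
  st <- spike_statistics(data.frame(time = ts, neuron = 1),
                         duration = max(ts) / 1000, n_neurons = 1)
  expect_equal(st$cv[1], 1, tolerance = 0.1)

  # two spikes define an ISI but no CV
  st <- spike_statistics(data.frame(time = c(10, 30), neuron = 1),
                         duration = 1, n_neurons = 1)
  expect_true(is.na(st$cv[1]))
  expect_equal(st$isi, 20)
})

test_that("condition comparison is the pooled-variance t-test", {
  r <- compare_conditions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$p, 0.021312, tolerance = 1e-4)
  expect_equal(r$df, 4)
  # symmetry flips t, keeps p
  r2 <- compare_conditions(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # identical samples
  r3 <- compare_conditions(c(2, 2), c(2, 2))
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  expect_error(compare_conditions(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compare_conditions(1, c(2, 3)), ">= 2")
})

test_that("population rate bins spike counts correctly", {
  sp <- data.frame(time = c(100, 900, 1100, 1900, 2500), neuron = 1)
  tr <- population_rate(sp, n_neurons = 2, duration = 3, bin_s = 1)
  expect_equal(tr$rate_hz, c(1, 1, 0.5))
  expect_equal(tr$t_bin, c(0.5, 1.5, 2.5))
})

test_that("dendritic weight-change accounting distinguishes gross and net", {
  net <- tiny_net(N_E = 30, N_I = 8, N_poisson = 150, rate = 12)
  pl <- plasticity_params(kappa = 4)
  sim <- sim_config(duration = 3, tau_homeo = 5, warmup_override = 0)
  run <- run_simulation(net, plasticity = pl, sim = sim, seed = 9)
  expect_warning(tot <- baseline_dendritic_weight_change(run), "protocol")
  expect_gt(tot, 0)
  net_change <- suppressWarnings(
    baseline_dendritic_weight_change(run, signed = TRUE))
  expect_gte(tot, abs(net_change))
  # gross |dW| is non-decreasing over snapshots
  expect_true(all(diff(run$snapshots$cum_abs_dend) >= -1e-12))
  # closed dendritic gate: zero dendritic change
  g0 <- gating_config(net$N_E, eta_dend = 0)
  run0 <- run_simulation(net, plasticity = pl, gates = g0, sim = sim,
                         seed = 9)
  expect_identical(suppressWarnings(
    baseline_dendritic_weight_change(run0)), 0)
})

test_that("stable engine runs classify as stable with EF near one", {
  net <- tiny_net(N_E = 40, N_I = 10, N_poisson = 150, rate = 10)
  run <- run_simulation(net, sim = sim_config(
    duration = 8, plasticity_on = FALSE), seed = 17)
  ef <- explosion_factor(run)
  expect_true(ef$stable)
  expect_lt(ef$EF, 1.5)
  expect_equal(nrow(run$rate), 8)
})
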