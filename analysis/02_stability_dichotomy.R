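#!/usr/bin/env Rscript
# Stability of the plastic network as a function of the homeostatic time
# constant tau.
#
# Protocol per run: warm-up of 3*tau s (floor 15 s) with plasticity off,
# target rate kappa set from the warm-up's last 2 s, then a plasticity-on
# main phase. The explosion factor EF = r_max / r_baseline (1 s bins,
# first-50 s baseline) classifies each run: stable if EF <= 1.5.
#
# Two tau values bracket the published stability boundary: a fast
# homeostat (tau = 10 s) and a slow one (tau = 30 s). Both the full-size
# network and the quarter-scale fixture are run so the two operating
# points can be compared.
#
# Writes: results/dichotomy.csv  one row per (scale, tau, seed)

library(dendgate)

seeds <- c(1L, 2L, 3L)
duration <- 100 # s of plasticity-on dynamics
dir.create("results", showWarnings = FALSE)

rows <- list()
for (scale in c(1, 0.25)) {
  net <- if (scale == 1) network_params() else make_fixture(scale)
  for (tau in c(10, 30)) {
    for (seed in seeds) {
      run <- run_simulation(net, sim = sim_config(
        duration = duration, tau_homeo = tau,
        stop_on_explosion = TRUE, record_bAP = FALSE), seed = seed)
      ef <- explosion_factor(run)
      rows[[length(rows) + 1L]] <- data.frame(
        scale = scale, tau = tau, seed = seed, kappa = run$kappa,
        EF = ef$EF, r_baseline = ef$r_baseline, r_max = ef$r_max,
        stable = ef$stable,
        dW_dend = run$cum_abs_dend, dW_soma = run$cum_abs_soma)
      cat(sprintf("scale %.2f tau %2d seed %d: kappa %.2f Hz, EF %.3f (%s)\n",
                  scale, tau, seed, run$kappa, ef$EF,
                  if (ef$stable) "stable" else "exploded"))
    }
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/dichotomy.csv", row.names = FALSE)

for (sc in unique(out$scale)) {
  d <- out[out$scale == sc, ]
  cat(sprintf(
    "scale %.2f: median EF %.3f at tau=10 s, %.3f at tau=30 s\n", sc,
    median(d$EF[d$tau == 10]), median(d$EF[d$tau == 30])))
}
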