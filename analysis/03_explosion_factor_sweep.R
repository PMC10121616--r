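#!/usr/bin/env Rscript
# Explosion factor as a function of the homeostatic time constant and the
# plasticity gates (learning rate, excitability, threshold, inhibition),
# on the quarter-scale fixture.
#
# Each gate is swept over a small grid of values against a grid of
# homeostatic time constants; every (gate value, tau, seed) run yields an
# explosion factor, and the per-gate-value critical time constant is the
# largest stable tau below the first instability.
#
# Writes: results/ef_sweep_runs.csv      one row per run
#         results/ef_sweep_tau_crit.csv  tau_crit per gate value and seed

library(dendgate)

tau_grid <- c(15, 35, 70)
seeds <- c(1L, 2L, 3L)
duration <- 60
dir.create("results", showWarnings = FALSE)

conditions <- list(
  condition("base"),
  condition("eta_x2",
            gate = list(gate = "eta", value = 2,
                        compartment = "both", subset = "all")),
  condition("gamma_x1.15",
            gate = list(gate = "gamma", value = 1.15,
                        compartment = "both", subset = "all")),
  condition("threshold_-1mV",
            gate = list(gate = "threshold", value = -1,
                        compartment = "both", subset = "all")),
  condition("inhibition_x0.7",
            gate = list(gate = "inhibition", value = 0.7,
                        compartment = "both", subset = "all")))

spec <- experiment_spec(conditions, tau_grid = tau_grid, seeds = seeds,
                        scale = 0.25, duration = duration,
                        family = "gate_sweep")
report <- run_campaign(spec, out_dir = "results/ef_sweep_cache",
                       verbose = TRUE)

write.csv(report$runs, "results/ef_sweep_runs.csv", row.names = FALSE)
write.csv(report$tau_crit, "results/ef_sweep_tau_crit.csv",
          row.names = FALSE)

cat("\nmedian tau_crit by condition (s):\n")
agg <- aggregate(tau_crit ~ condition, data = report$tau_crit, FUN = median,
                 na.action = NULL)
print(agg, row.names = FALSE)
cat("\nEF distribution: fraction of runs in the (1.3, 2.0) gap:",
    sprintf("%.2f", mean(report$runs$EF > 1.3 & report$runs$EF < 2,
                         na.rm = TRUE)), "\n")
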