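#' Describe a campaign condition
#'
#' A condition bundles a gate setting (or none) with optional neuron
#' parameter overrides (e.g. the dendro-somatic coupling `g_s`).
#'
#' @param name condition label.
#' @param gate `NULL`, or a list with `gate`, `value`, `compartment`,
#'   `subset` as understood by [apply_gates()].
#' @param neuron_overrides named list of [neuron_params()] fields to
#'   override (e.g. `list(g_s = 1600)`).
#' @return A list of class `"campaign_condition"`.
#' @export
condition <- function(name, gate = NULL, neuron_overrides = list()) {
  structure(list(name = name, gate = gate,
                 neuron_overrides = neuron_overrides),
            class = "campaign_condition")
}

#' Specify an experiment campaign
#'
#' A campaign runs every (condition, tau, seed) combination through
#' [run_simulation()] and aggregates explosion factors, critical time
#' constants and dendritic weight changes.
#'
#' @param conditions list of [condition()] objects.
#' @param tau_grid homeostatic time constants to sweep (s).
#' @param seeds integer vector of master seeds.
#' @param scale network scale factor in (0, 1] (see [make_fixture()]).
#' @param duration main-phase duration per run (s).
#' @param family label of the experiment family.
#' @param stop_on_explosion abort exploding runs early (classification is
#'   unaffected; see [explosion_factor()]).
#' @return A list of class `"experiment_spec"`.
#' @export
experiment_spec <- function(conditions, tau_grid, seeds,
                            scale = 0.25, duration = 60,
                            family = "gate_sweep",
                            stop_on_explosion = TRUE) {
  if (length(tau_grid) == 0) stop("experiment_spec: empty tau grid")
  if (length(seeds) == 0) stop("experiment_spec: empty seed list")
  if (scale <= 0 || scale > 1) stop("experiment_spec: scale must be in (0, 1]")
  for (cn in conditions) stopifnot(inherits(cn, "campaign_condition"))
  structure(list(conditions = conditions, tau_grid = sort(tau_grid),
                 seeds = as.integer(seeds), scale = scale,
                 duration = duration, family = family,
                 stop_on_explosion = stop_on_explosion),
            class = "experiment_spec")
}

#' Run an experiment campaign
#'
#' Executes all (condition, tau, seed) runs of an [experiment_spec()].
#' Runs sharing a seed share identical connectivity, initial conditions
#' and Poisson input (gates draw no randomness), so condition differences
#' are attributable to gating alone. Exploded runs contribute their
#' explosion factor like any other run; only numerical failure is
#' recorded as a failed run. When `out_dir` is given, each completed
#' (condition, tau, seed) row is appended to `runs.csv` there and already
#' present rows are skipped, making interrupted campaigns resumable.
#'
#' @param spec an [experiment_spec()].
#' @param out_dir optional directory for resumable per-run rows.
#' @param verbose print per-run progress.
#' @return A list of class `"campaign_report"`: `runs` (one row per run:
#'   condition, tau, seed, EF, stable, r_baseline, r_max, kappa,
#'   dendritic and somatic |dW|), `tau_crit` (one row per condition and
#'   seed), and the spec.
#' @export
run_campaign <- function(spec, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  net <- make_fixture(spec$scale)
  done <- NULL
  runs_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    runs_file <- file.path(out_dir, "runs.csv")
    if (file.exists(runs_file))
      done <- utils::read.csv(runs_file, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (cn in spec$conditions) {
    neuron <- do.call(neuron_params, cn$neuron_overrides)
    gates <- if (is.null(cn$gate)) gating_config(net$N_E)
    else apply_gates(net$N_E, cn$gate$gate, cn$gate$value,
                     cn$gate$compartment, cn$gate$subset)
    for (tau in spec$tau_grid) {
      for (seed in spec$seeds) {
        prev <- NULL
        if (!is.null(done)) {
          hit <- done$condition == cn$name &
            abs(done$tau - tau) < 1e-9 & done$seed == seed
          if (any(hit)) prev <- done[which(hit)[1], , drop = FALSE]
        }
        if (!is.null(prev)) {
          rows[[length(rows) + 1L]] <- prev
          next
        }
        row <- tryCatch({
          run <- run_simulation(
            net, neuron = neuron, gates = gates, seed = seed,
            sim = sim_config(duration = spec$duration, tau_homeo = tau,
                             stop_on_explosion = spec$stop_on_explosion,
                             record_bAP = FALSE))
          ef <- explosion_factor(run)
          data.frame(condition = cn$name, tau = tau, seed = seed,
                     EF = ef$EF, stable = ef$stable,
                     r_baseline = ef$r_baseline, r_max = ef$r_max,
                     kappa = run$kappa,
                     dW_dend = run$cum_abs_dend, dW_soma = run$cum_abs_soma,
                     failed = FALSE, stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(condition = cn$name, tau = tau, seed = seed,
                     EF = NA_real_, stable = NA, r_baseline = NA_real_,
                     r_max = NA_real_, kappa = NA_real_,
                     dW_dend = NA_real_, dW_soma = NA_real_,
                     failed = TRUE, stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- row
        if (!is.null(runs_file))
          utils::write.table(row, runs_file, sep = ",", append = file.exists(runs_file),
                             col.names = !file.exists(runs_file),
                             row.names = FALSE)
        if (verbose)
          message(sprintf("%s tau=%g seed=%d: EF=%.3f%s", cn$name, tau,
                          seed, row$EF, if (isTRUE(row$failed)) " FAILED" else ""))
      }
    }
  }
  runs <- do.call(rbind, rows)
  tc <- do.call(rbind, lapply(split(
    runs, list(runs$condition, runs$seed), drop = TRUE), function(d) {
      ok <- !d$failed
      data.frame(condition = d$condition[1], seed = d$seed[1],
                 tau_crit = if (sum(ok) >= 2)
                   critical_tau(d$tau[ok], d$stable[ok]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(tc) <- NULL
  structure(list(runs = runs, tau_crit = tc, spec = spec),
            class = "campaign_report")
}

#' Check the directional findings on a campaign report
#'
#' Encodes the qualitative claims as median comparisons over seeds:
#' gating in the dendrite preserves a larger critical time constant than
#' the same gate perisomatically; gating a quarter of the neurons
#' preserves a larger critical time constant than gating all of them;
#' stronger dendro-somatic coupling (larger `g_s`) lowers the critical
#' time constant. Each check runs only if both of its condition labels
#' are present in the report. An `NA` critical time constant (no stable
#' tau) is ranked below every finite one via the lowest grid value.
#'
#' @param report a `campaign_report`.
#' @param pairs named list of `c(greater, smaller)` condition-label pairs
#'   to compare; the default covers the standard labels used by the
#'   campaign drivers (checks whose labels are absent from the report are
#'   skipped).
#' @return data.frame with one row per performed check: the two medians,
#'   `pass`, and `low_power` (fewer than 2 seeds).
#' @export
expected_directions <- function(report,
                                pairs = list(
                                  dendritic_vs_perisomatic =
                                    c("eta2_dendrite", "eta2_soma"),
                                  subpopulation_vs_global =
                                    c("gamma115_quarter", "gamma115_all"),
                                  subpopulation_vs_global_eta =
                                    c("eta2_quarter", "eta2_all"),
                                  weak_vs_strong_coupling =
                                    c("gs_1300", "gs_1600"))) {
  tc <- report$tau_crit
  floor_tau <- min(report$spec$tau_grid) / 2
  med <- function(cond) {
    v <- tc$tau_crit[tc$condition == cond]
    v[is.na(v)] <- floor_tau
    stats::median(v)
  }
  n_seeds <- function(cond) sum(tc$condition == cond)
  out <- list()
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (!all(p %in% tc$condition)) next
    out[[nm]] <- data.frame(
      check = nm, greater = p[1], smaller = p[2],
      median_greater = med(p[1]), median_smaller = med(p[2]),
      pass = med(p[1]) > med(p[2]),
      low_power = min(n_seeds(p[1]), n_seeds(p[2])) < 2,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
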