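#' Explosion factor and stability classification
#'
#' The explosion factor is the maximum binned population firing rate over
#' the whole main phase divided by the baseline rate, the mean rate over
#' the first `baseline` seconds. A run with `EF <= 1.5` is classified
#' stable, `EF > 1.5` unstable. For runs shorter than the baseline window
#' the baseline shrinks to the first quarter of the run (flagged in the
#' output).
#'
#' A run aborted by the early-explosion stop (see [sim_config()]) is
#' classified from the bins it completed; the stop triggers only at rates
#' that already exceed the instability threshold.
#'
#' @param run a `dendgate_run`, or a numeric vector of binned rates (Hz).
#' @param bin_s bin width (s), used when `run` is a plain vector.
#' @param baseline baseline window (s).
#' @return A list of class `"stability_result"`: `EF`, `r_max`,
#'   `r_baseline`, `stable`, `tau_homeo`, `baseline_used` (s),
#'   `shrunk_baseline` flag.
#' @export
explosion_factor <- function(run, bin_s = 1, baseline = 50) {
  if (inherits(run, "dendgate_run")) {
    rates <- run$rate$rate_hz
    bin_s <- run$sim$rate_bin
    tau <- run$tau_homeo
  } else {
    rates <- as.numeric(run)
    tau <- NA_real_
  }
  if (length(rates) < 2)
    stop("explosion_factor: need at least two rate bins")
  dur <- length(rates) * bin_s
  shrunk <- dur < baseline
  base_s <- if (shrunk) dur / 4 else baseline
  nb <- max(1L, as.integer(round(base_s / bin_s)))
  r_baseline <- mean(rates[seq_len(nb)])
  if (r_baseline <= 0)
    stop("explosion_factor: zero baseline rate")
  r_max <- max(rates)
  ef <- r_max / r_baseline
  structure(list(EF = ef, r_max = r_max, r_baseline = r_baseline,
                 stable = ef <= 1.5, tau_homeo = tau,
                 baseline_used = nb * bin_s, shrunk_baseline = shrunk),
            class = "stability_result")
}

#' Critical homeostatic time constant
#'
#' The largest homeostatic time constant at which the network is stable,
#' required additionally to lie below the smallest unstable one. If the
#' largest stable tau exceeds some unstable tau (non-monotone sweep), the
#' largest stable tau below the first instability is returned. `NA` if no
#' tau is stable.
#'
#' @param tau numeric vector of homeostatic time constants (s).
#' @param stable logical vector (or a list of `stability_result`s).
#' @return `tau_crit` in seconds, or `NA`.
#' @export
critical_tau <- function(tau, stable) {
  if (length(tau) < 2) stop("critical_tau: need at least two grid points")
  if (is.list(stable)) stable <- vapply(stable, `[[`, logical(1), "stable")
  stopifnot(length(tau) == length(stable))
  o <- order(tau)
  tau <- tau[o]; stable <- stable[o]
  if (!any(stable)) return(NA_real_)
  max_stable <- max(tau[stable])
  if (!any(!stable)) return(max_stable)
  min_unstable <- min(tau[!stable])
  if (max_stable < min_unstable) return(max_stable)
  below <- stable & tau < min_unstable
  if (!any(below)) return(NA_real_)
  max(tau[below])
}

#' Baseline dendritic weight change
#'
#' The amount of dendritic plasticity in a run: the accumulated absolute
#' value of every applied dendritic weight update (and, alternatively,
#' the net signed total). The reference protocol is a 200 s simulation
#' with a homeostatic time constant of 5 s; runs at other settings are
#' accepted with a warning so that scaled-down protocols can reuse the
#' function.
#'
#' @param run a `dendgate_run`.
#' @param signed return the net signed total instead of the accumulated
#'   absolute change.
#' @return Total dendritic weight change (nS).
#' @export
baseline_dendritic_weight_change <- function(run, signed = FALSE) {
  stopifnot(inherits(run, "dendgate_run"))
  if (!isTRUE(all.equal(run$tau_homeo, 5)) || run$sim$duration != 200)
    warning("reference protocol is 200 s at tau = 5 s; got ",
            run$sim$duration, " s at tau = ", run$tau_homeo, " s",
            call. = FALSE)
  if (signed) run$cum_net_dend else run$cum_abs_dend
}

#' Per-neuron spike statistics
#'
#' Firing rate, interspike intervals and the coefficient of variation
#' (CV) of the ISIs per neuron. Neurons with fewer than 3 spikes have no
#' CV (fewer than 2 ISIs do not define a variability).
#'
#' @param spikes data.frame with `time` (ms) and `neuron`, or a
#'   `dendgate_run` (uses its main-phase E spikes).
#' @param duration recording duration (s); taken from the run if given.
#' @param n_neurons number of neurons (for silent-neuron rates).
#' @return A list with `rates` (Hz per neuron), `cv` (per neuron, `NA`
#'   where undefined), and `isi` (pooled ISIs, ms).
#' @export
spike_statistics <- function(spikes, duration = NULL, n_neurons = NULL) {
  if (inherits(spikes, "dendgate_run")) {
    duration <- spikes$t_end
    n_neurons <- spikes$net$N_E
    spikes <- spikes$spikes_E
  }
  stopifnot(!is.null(duration), !is.null(n_neurons))
  counts <- tabulate(spikes$neuron, nbins = n_neurons)
  rates <- counts / duration
  cv <- rep(NA_real_, n_neurons)
  isi_all <- vector("list", n_neurons)
  sp <- split(spikes$time, factor(spikes$neuron, levels = seq_len(n_neurons)))
  for (i in seq_len(n_neurons)) {
    ts <- sort(sp[[i]])
    if (length(ts) >= 2) {
      isi <- diff(ts)
      isi_all[[i]] <- isi
      if (length(ts) >= 3)
        cv[i] <- stats::sd(isi) / mean(isi)
    }
  }
  list(rates = rates, cv = cv, isi = unlist(isi_all, use.names = FALSE))
}

#' Seed-wise condition comparison
#'
#' Classical equal-variance two-sample two-sided t-test on per-seed
#' metrics (critical time constants, weight changes) of two conditions.
#'
#' @param a,b numeric vectors of per-seed values.
#' @return A list with `t`, `p`, `df`, and the two sample means.
#' @export
compare_conditions <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("compare_conditions: need >= 2 finite values per condition")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("compare_conditions: zero variance in both samples")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Population rate trace from a spike record
#'
#' @param spikes data.frame with `time` (ms).
#' @param n_neurons population size.
#' @param duration duration (s).
#' @param bin_s bin width (s).
#' @return data.frame with `t_bin` (bin centres, s) and `rate_hz`.
#' @export
population_rate <- function(spikes, n_neurons, duration, bin_s = 1) {
  n_bins <- as.integer(floor(duration / bin_s + 1e-9))
  b <- floor(spikes$time / (bin_s * 1000)) + 1
  cnt <- tabulate(b[b >= 1 & b <= n_bins], nbins = n_bins)
  data.frame(t_bin = (seq_len(n_bins) - 0.5) * bin_s,
             rate_hz = cnt / (n_neurons * bin_s))
}
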