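---
title: "Gated dendritic plasticity in a balanced spiking network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated dendritic plasticity in a balanced spiking network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendgate)
```

## The scientific problem

Hebbian plasticity in recurrent networks is self-amplifying: potentiated
synapses raise firing rates, which potentiate synapses further. Homeostatic
processes that monitor activity and strengthen long-term depression (LTD)
can hold the network at a target rate, but only if they react quickly
enough. The speed a homeostat needs — summarised by the largest filter time
constant $\tau$ at which the network still remains stable, the *critical
homeostatic time constant* $\tau_{crit}$ — is the currency in which this
package measures the plasticity–stability trade-off.

The model asks how *gates* on plasticity (neuromodulatory control of the
learning rate, excitability, spiking threshold, or inhibition) change
$\tau_{crit}$, and specifically whether gating plasticity in the *dendrites*
of two-compartment pyramidal cells costs less stability than gating it
perisomatically.

## The network

`network_params()` describes a balanced recurrent network of $N_E = 1000$
excitatory two-compartment pyramidal cells and $N_I = 250$ inhibitory
leaky integrate-and-fire cells. All neurons receive excitatory input from a
shared pool of 1000 Poisson processes at 2 Hz, fanned out with connection
probability 0.1 (onto the perisomatic compartment of E cells). Recurrent
projections are independent Bernoulli draws at probability 0.1, except
E→E perisomatic synapses at 0.09; autapses are excluded. Synapses are
conductance-based: a presynaptic spike increments the target conductance by
the synaptic weight, and conductances decay exponentially.

The pyramidal soma integrates leak, excitation (reversal 0 mV), inhibition
(reversal −80 mV), and the dendro-somatic coupling
$\lambda\,(g_s\,\sigma(V_d) + \omega^s)$, where
$\sigma(V_d) = 1/(1+e^{-(V_d-E_d)/D_d})$ is a sigmoidal dendritic calcium
nonlinearity ($E_d = -38$ mV, $D_d = 6$ mV) and $\omega^s$ a
spike-triggered adaptation current. The dendrite integrates its own leak,
synaptic input, the local nonlinearity $g_d\,\sigma(V_d)$, a rectangular
back-propagating action potential (bAP) current (2600 pA for 2 ms, 0.5 ms
after each somatic spike), and subthreshold adaptation
$\omega^d \to a_\omega^d (V_d - E_l)$. Somatic spikes occur at −50 mV,
reset to −70 mV, and are followed by an 8.3 ms refractory period during
which the membrane is clamped at the reset value. The factor
$\lambda = 0.54$ rescales coupling and adaptation to the 200 pF soma used
here from the 370 pF soma of the original layer-5 fit.

## Plasticity

Perisomatic E→E synapses follow a minimal triplet STDP rule
(`plasticity_delta_perisomatic()`): at each postsynaptic spike the weight
grows by $\eta\,w_0\,A^+ z^+_j z^{slow}_i$, at each presynaptic spike it
shrinks by $\eta\,w_0\,A^-_i z^-_i$. The traces $z^+, z^-, z^{slow}$ decay
with 16.8, 33.7 and 114 ms and jump by 1 at their driving events; trace
values are read *before* the triggering spike's own increment (the
$t-\varepsilon$ convention).

Dendritic E→E synapses follow the same triplet rule with the bAP as the
postsynaptic event (a bAP is detected when $V_d > -50$ mV, a somatic spike
occurred within 3 ms, and no bAP occurred within 5.8 ms). In addition, a
presynaptic spike arriving while the dendrite is depolarised above
$\theta_{Ca} = -40$ mV potentiates by the fixed amount $A^{Ca}$
(calcium-spike-dependent potentiation), and every presynaptic spike
depresses by the constant $\alpha$ (transmitter-induced depression). All
weights are clipped to $[0, 10]$ nS. Updates scale with the *initial*
weight $w_0$, not the running weight.

Homeostasis acts through the depression amplitude
(`homeostatic_amplitude()`):
$$A^-_i = \frac{A^+\,\tau^+\,\tau^{slow}}{\tau^-\,\kappa}\,\bar s_i^2,$$
where $\bar s_i$ low-pass filters neuron $i$'s spikes with time constant
$\tau$ (`tau_homeo`, in seconds — the central parameter of the study) and
$\kappa$ is the target rate. For independent Poisson pre- and postsynaptic
activity at rate $\kappa$ the expected potentiation
$A^+\tau^+\tau^{slow}\kappa^3$ and depression $A^-(\kappa)\tau^-\kappa^2$
cancel exactly, making $\kappa$ the fixed point of the drift; this identity
is verified by simulation in the test suite.

### Gates

`gating_config()` / `apply_gates()` express the four gates per neuron and
per compartment: `gamma` multiplies the total excitatory conductance term
of a compartment, `inhibition` scales inhibitory synaptic increments onto a
compartment, `threshold` shifts the somatic spiking threshold additively,
and `eta` scales the learning rate of a compartment's synapses. The
identity configuration leaves the simulation bit-identical to an ungated
run. With a closed learning-rate gate (`eta = 0`) the affected synapses are
frozen exactly; for dendritic synapses this means the whole per-event
update — including the constant $\alpha$ — is gated, a deliberate reading
that makes "gate closed" synonymous with "no plasticity" (with the printed
per-event composition, $\alpha$ would leak through a closed gate; at the
gate values actually studied, where the learning-rate factor is 1 or 2, the
two readings differ by at most $10^{-4}$ nS per presynaptic spike).

## Simulation protocol

`run_simulation()` integrates everything with forward Euler at
$dt = 0.1$ ms (synaptic conductances, plasticity traces and the rate filter
use their exact per-step exponential decay factors, so event-driven
closed forms are matched to machine precision at grid points). Within a
step: conductance decay, spike delivery (recurrent spikes arrive one step
after emission), voltage/adaptation integration, threshold detection and
reset, bAP detection, trace decay, plasticity updates on pre-increment
traces, trace increments.

Each run starts with a warm-up of $3\tau$ seconds (floor 15 s) with
plasticity off; $\kappa$ is set to the population mean rate over the
warm-up's last 2 s (one global value). The warm-up serves two purposes:
the network settles into its asynchronous-irregular state, and the filter
$\bar s$ converges to each neuron's own rate — switching plasticity on with
an unconverged $\bar s$ systematically understates LTD for a period of
order $\tau$ and can destabilise runs that are otherwise stable, which is
why shortcuts on the warm-up are not taken even when $\tau$ is large.

All randomness (wiring, initial voltages, Poisson input) flows from one
master seed through three independent child streams, so conditions that
differ only in gates share identical wiring and input spike trains.

## Stability analysis

`explosion_factor()` computes $EF = r_{max}/r_{baseline}$ from the 1 s
binned population rate, with the baseline averaged over the first 50 s of
the main phase (runs shorter than 50 s use their first quarter and are
flagged). A run is stable iff $EF \le 1.5$. `critical_tau()` returns the
largest stable $\tau$ on a grid, required to lie below the smallest
unstable one. `baseline_dendritic_weight_change()` accumulates the
absolute value of every applied dendritic update (a 200 s run at
$\tau = 5$ s is the reference protocol; the net signed total is also
available, since "total weight change" admits both readings — the absolute
sum is used because it measures the *amount* of plasticity rather than its
direction). Seed-wise condition comparisons use the classical
equal-variance two-sample t-test (`compare_conditions()`).

Runs can be aborted early once a completed rate bin exceeds three times
the baseline (`stop_on_explosion`); this only fires beyond the
instability threshold, so classification is unaffected while exploded
runs become much cheaper.

## Design choices on under-determined points

Several details are not fixed by the published description; the package
resolves them as follows and exposes each choice as a parameter:

- **Synaptic decay constants.** The two printed values (16 ms, 7 ms)
  carry compartment superscripts but the conductance equations name
  per-type constants $\tau_E, \tau_I$. The default maps them to
  *compartments* (16 ms for all somatic and inhibitory-cell synapses,
  7 ms for all dendritic ones), consistent with the original
  two-compartment cell the model builds on. The per-type reading is
  available (`sim_config(syn_tau_mapping = "type")`) but destabilises the
  plasticity-off network at reduced scale — warm-ups jump to a
  refractory-limited ~117 Hz attractor for most seeds — so it is not the
  default: a stable asynchronous-irregular baseline is a prerequisite of
  the whole analysis.
- **Reset and refractory behaviour.** Reset potential (−70 mV,
  `v_reset`) and the clamped refractory voltage are unstated in the
  source; the conventional choices are used.
- **Inhibitory membrane.** The inhibitory cell's equation reuses the
  somatic symbols, but a 10 ms inhibitory membrane time constant is
  printed; with the printed 10 nS leak this fixes $C_I = 100$ pF.
- **Ca-potentiation voltage.** The dendritic voltage is evaluated at the
  presynaptic spike's time step.
- **Population rate bin.** 1 s bins for both baseline averaging and
  $r_{max}$; exposed in `sim_config(rate_bin = )`.
- **Gated subpopulation.** The first $\lceil N_E/4\rceil$ indices; under
  exchangeable random wiring the identity of the quarter is immaterial.

## The reduced-scale fixture and what it does (not) show

`make_fixture(scale)` shrinks both populations by `scale` and multiplies
recurrent weights by `1/scale`, preserving the mean recurrent input
$p\,N\,w$ (external drive is left untouched; the weight cap is also left
untouched, since it is a property of the plasticity rule, not the wiring).
This preserves the balanced operating point in the mean but *not* the
fluctuation and correlation structure: fewer, stronger synapses make the
small network noisier and more correlated. Desk-scale results are
therefore read as *relative* comparisons (between gates, compartments,
subpopulations) rather than as quantitative predictions for the full-size
network.

A consequence worth stating plainly: in this reconstruction the full-size
network settles at a quieter operating point (population rate well below
the homeostatic few-Hz regime that makes triplet potentiation, which grows
with the cube of the rate, dangerous). Its plastic runs are therefore
stable for both fast and slow homeostats, with explosion factors close to
1.05 — the published stable-run value — while a published *unstable* slow-
homeostat example is not reproduced by the printed parameter set as
implemented here. The quarter-scale fixture runs hotter (2–5 Hz) and shows
the asynchronous-irregular statistics expected of the balanced state. The
tests and the acceptance script report both operating points honestly
rather than tuning parameters to force either outcome.

## Problem sizes used by the tests and scripts

Unit tests run networks of 20–40 E cells for seconds. The acceptance
checks use the quarter-scale fixture (250 E + 62 I) with 100 s plastic
phases and 5 seeds for the stability dichotomy, the full-size network for
the 10 s asynchronous-irregular baseline and one stable-run explosion
factor, and a reduced campaign (quarter scale, 60 s runs, 3 seeds, compact
$\tau$ grids) for the directional comparisons. The analysis scripts under
`analysis/` use the same sizes and write their tables under `results/`.

## Known limitations

- The operating-point discrepancy described above: absolute
  $\tau_{crit}$ values are not comparable to the published ones; only
  within-package comparisons are meaningful. A corollary is that
  pure learning-rate gates, which change plasticity without changing
  activity, do not destabilise this reconstruction on any affordable
  $\tau$ grid, so their $\tau_{crit}$ comparisons tie at the grid
  maximum; gates that raise activity (higher excitability, lower
  inhibition) do destabilise it and support informative comparisons.
- One synapse per ordered pair and compartment; no synaptic delays beyond
  the one-step delivery delay and the 0.5 ms bAP delay.
- No NMDA conductances, inhibitory plasticity, synaptic scaling, or
  structured connectivity; stimulation protocols are out of scope.
- The homeostat modulates LTD amplitude only; alternative homeostatic
  mechanisms are not implemented.
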