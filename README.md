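# spinesim

Stochastic simulation of plasticity induction at a single CA3–CA1
hippocampal synapse.

Whether a stimulation protocol leaves a synapse potentiated (LTP), depressed
(LTD) or unchanged depends not only on spike timing and rate but also on the
experimental conditions — animal age, bath temperature, extracellular Ca²⁺
and Mg²⁺, and the spine's distance from the soma. `spinesim` is for
computational and experimental neuroscientists who want to simulate
plasticity-induction experiments under explicit experimental conditions and
ask how those conditions reshape the induction rules.

## The model

The synapse is simulated as a piecewise-deterministic Markov process
coupling five stages:

* **Presynaptic release** — a stochastic two-pool vesicle system (docked
  pool D ≤ 25, reserve pool R ≤ 30) with a phenomenological presynaptic
  calcium resource `Ca_pre`. Each spike releases a vesicle with probability
  `p_rel = Ca_pre² / (Ca_pre² + h([Ca²⁺]ₒ)²)` (≈ 67% for the first spike at
  2.5 mM Ca²⁺), and cleft glutamate amplitudes are gamma-distributed around
  1 mM. GABA is co-released onto the dendrite by the same events.
* **Electrical compartments** — spine, dendrite and soma. The soma
  generates action potentials (Na⁺/K⁺ gates); back-propagating APs (BaPs)
  reach the spine attenuated by distance and by use-dependent resources
  (λ, λ_age), reproducing activity- and age-dependent BaP failure.
* **Stochastic channels** — Markov chains for 120 AMPArs (16 states, three
  sub-conductances), 15 NMDArs split between GluN2A/GluN2B by an
  age-dependent ratio, 34 GABA(A)rs (chloride reversal shifts with age),
  and 3 each of T/R/L-type voltage-gated calcium channels; a deterministic
  SK channel provides calcium-activated negative feedback.
* **Spine calcium** — Goldman–Hodgkin–Katz influx through NMDArs (with
  voltage-dependent Mg²⁺ block and Ca²⁺-dependent conductance) and VGCCs, a
  generic endogenous buffer, diffusion through the spine neck, and an
  optional fluorescent dye mode.
* **Enzymes and readout** — a deterministic coarse-grained
  CaM → CaMKII / CaN network (17 species, conserved totals 30/70/20 µM)
  driven by spine calcium. The joint (CaN, CaMKII) activity orbit is
  classified geometrically: polygonal LTP and LTD regions in the activity
  plane drive leaky activation variables and a stochastic 100-process
  plasticity chain whose LTP − LTD count is the weight change in percent.

Everything upstream of the enzymes is stochastic (channel flicker, release
failures, vesicle depletion); any source can be switched to its mean-field
limit for stochastic-vs-deterministic comparisons.

## Worked example

Simulate a classic burst-pairing LTP protocol (presynaptic spike followed
10 ms later by a postsynaptic doublet, 100 pairings at 5 Hz) in adult
tissue at physiological temperature:

```r
library(spinesim)

cond  <- experimental_conditions(age = 52, temperature = 35, ca_o = 2.5, mg_o = 1.3)
proto <- build_protocol("1Pre2Post10, 100 at 5 Hz")
sim   <- simulate_synapse(proto, cond, n_samples = 10, seed = 42)
glance(sim)
#> # A tibble: 1 × 7
#>   n_samples mean_weight median_weight   q25   q75 sd_weight mean_peak_ca
#>       <int>       <dbl>         <dbl> <dbl> <dbl>     <dbl>        <dbl>
#> 1        10        11.9          11.5  9.25  14.2      3.73         36.6
```

`mean_weight` is the mean plasticity outcome across samples (+11.9%
potentiation here; each of the 100 chain processes is 1% of synaptic
weight), and `mean_peak_ca` the mean peak spine calcium in µM over the run.
`tidy(sim)` returns per-sample outcomes, `sim$trajectory` the sampled state
(voltages, calcium, open channel counts, enzyme activities, readout state),
and `autoplot(sim)`, `plot_orbit(sim)`, `plot_dwell_map(dwell_map(sim$trajectory))`
show the traces, the (CaN, CaMKII) orbit against the plasticity regions,
and the dwell-time map.

Model-level quantities are directly measurable, e.g. the GluN2A NMDAr
deactivation constant at 35 °C and the initial release probability:

```r
measure_channel_decay_ms("glun2a")
#> [1] 46.3716
measure_initial_release_probability(2.5)
#> [1] 66.58018
```

Protocol variants for in-vivo-like firing are built with `apply_jitter()`,
`apply_sparsity()` and `poisson_protocol()`; condition/protocol bundles for
classic experiments are in `experiment_preset()`; `sweep_protocols()` runs
grids. A thin command-line front end lives at
`inst/scripts/spinesim.R` (`run`, `readout`, `fit-decay` subcommands), and
`readout_classify()` applies the geometric readout to externally generated
(time, CaN, CaMKII) trajectories.

## Scope

The package models plasticity *induction* (enzyme dynamics and their
geometric classification), not expression or maintenance; the spine is a
single well-mixed compartment; and the plasticity-region polygons are fixed
constants of the readout, not refit. See the methods vignette
(`vignettes/plasticity-model.Rmd`) for the model's assumptions, numerical
scheme, calibration choices and known limitations.
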