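---
title: "A stochastic spine model of plasticity induction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic spine model of plasticity induction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `spinesim`, the choices that
were genuinely open during implementation, the numerical scheme, and what the
shipped tests do and do not establish.

## Model overview and assumptions

The simulated object is a single CA3–CA1 glutamatergic synapse: a spherical
spine head (0.03 µm³) on a passive dendrite attached to a spiking soma. The
model is a piecewise-deterministic Markov process: continuous variables
(compartment voltages, somatic gates, BaP-attenuation resources, spine
calcium, buffer and dye, the 17-species enzyme network, the readout
activations) evolve by ODEs, while discrete populations (vesicle pools,
AMPAr/NMDAr/GABAr/VGCC channel states, the 100-process plasticity chain) jump
stochastically with rates that depend on the continuous state.

Key structural assumptions, inherited from the model family this package
implements:

* one well-mixed spine compartment; no spatial calcium microdomains;
* one generic endogenous buffer (calmodulin is modelled explicitly, all other
  buffers are aggregated);
* enzymes are deterministic, inheriting noise only through calcium;
* plasticity *induction* only: the chain state is an abstract weight, with no
  AMPAr-trafficking mechanism;
* extracellular Ca²⁺/Mg²⁺ fixed within a run (bath conditions);
* the strongly attenuating BaP phenotype (the weakly attenuating neuron class
  is out of scope).

## Units

Time s, voltage mV, concentration µM (extracellular Ca/Mg in mM where fitted
expressions use mM), conductance nS, current pA, capacitance pF. All rates
printed in ms⁻¹ in the source literature (somatic gates, VGCC gates) are
converted to s⁻¹ at load time; `pA/pF` integrates as mV/ms and is scaled by
10³ once, in the engine. The BaP-attenuation step constants are per (pA·ms)
and are likewise converted once (see below).

## Experimental conditions and their scalar hooks

`experimental_conditions()` carries the knobs; `synapse_params()` resolves
them into scalars:

| knob | default | enters through |
|---|---|---|
| age | P56 | NMDAr GluN2A:GluN2B split (15 receptors, logistic ratio, ±1 receptor sampling noise); chloride reversal (−92.6 mV adult asymptote); BaP age resource step |
| temperature | 35 °C | per-mechanism forward/backward rate factors (below) |
| [Ca²⁺]ₒ | 2.5 mM | release threshold h; NMDAr conductance (33.9–92.3 pS logistic); GHK driving force |
| [Mg²⁺]ₒ | 1.3 mM | NMDAr Mg block `1/(1 + Mg/3.57 e^(−0.062 V))` |
| d_soma | 200 µm | distance factor `0.1 + 1.4/(1+e^(0.02(d−230.3)))` on the dendro-somatic conductance |

Rounding in the subunit split is half-away-from-zero (base R's banker
rounding would flip counts at exact halves). Conditions outside the fitted
temperature range [15, 45] °C warn rather than error.

## Temperature factors: how the printed curves are applied

The fitted logistic factor pairs (ρ_f, ρ_b) per mechanism are exposed
verbatim by `temperature_factors()`. How they multiply the chains required
interpretation, because several printed expressions are internally
inconsistent (one has its midpoint at −37.6 °C and turns negative below
11 °C; another is printed with a double minus sign; the SK pair makes the
channel's steady-state activation 0.6%). The package resolves them by
requiring each chain to reproduce the model's own stated behaviours:

* **AMPAr**: ρ_f scales glutamate binding; ρ_b scales unbinding *and channel
  closing*; desensitisation and opening are temperature-insensitive. This is
  the only assignment that reproduces the stated deactivation pair
  (≈0.95 ms at 25 °C, ≈0.6 ms at 35 °C) at both temperatures.
* **NMDAr, CaMKII, CaN**: the printed factors are applied normalised to
  their value at 35 °C. The subtype chains then deactivate in ≈46 ms
  (GluN2A) and ≈237 ms (GluN2B) at physiological temperature — the published
  subtype kinetics — and the enzyme decay constants match their fitted
  physiological-temperature values. The printed temperature *dependence*
  (curve shape) is preserved.
* **GABA(A)r**: the single printed factor is read as a closing-*time*
  multiplier (closing rates are divided by it). This yields ≈10 ms
  deactivation at 35 °C and slower decay at room temperature, the
  physiological direction. The two closing rates are printed under the same
  name; they are assigned as rc1 = 9800 s⁻¹ (O1), rc2 = 400 s⁻¹ (O2), the
  source-model ordering in which the doubly liganded open state is
  long-lived.
* **SK**: activation is first-order relaxation to `min(1, r(Ca)·ρ_f)` with
  time constant τ_SK/ρ_b: ρ_f acts as an activation gain (the reported
  left-shift of SK half-activation with temperature), ρ_b on the kinetics.
* **VGCC**: applied as printed (α rates ×ρ_f, β rates ×ρ_b, all subtypes).

Deactivation constants are fitted from the open-probability peak after a
standard 1 ms, 1 mM transmitter pulse (`channel_decay_tau()`), the
convention that reproduces the stated AMPAr pair.

## Calibrated constants

Three quantities are free parameters of the model family, fixed once here
and never revisited:

* **BaP injection**: amplitude 1000 pA for 2 ms. Calibrated so a lone
  injection at rest elicits a somatic AP overshooting 0 mV and a spine
  depolarisation of ~60–70 mV; with the printed attenuation steps
  (δ_decay = 1.727×10⁻⁵, δ_aux = 2.304×10⁻⁵ per pA·ms) the dendritic BaP
  amplitude then attenuates to ≈85% by the 30th pulse of a 5 Hz train, as
  the model family reports. The per-(pA·ms) reading of the step constants is
  itself a design decision: read per (pA·s) they produce no attenuation at
  all.
* **GHK flux scale** (`ghk_scale = 0.3`): the calcium permeability is the
  model's declared free parameter; the scale is set so a single successful
  vesicle release yields a ~3 µM spine calcium peak under default adult
  conditions (50-sample mean).
* **VGCC conductance scale**: the printed per-channel conductances are
  exponent-garbled ("12·10³ nS"); they are read as 12/17/27 pS — the
  physiological single-channel range — with a common scale
  (`vgcc_scale = 0.1`) set so a solitary BaP yields a spine calcium
  transient of order 1 µM. SK conductance is likewise read as 10 pS.

## Presynaptic model

Two pools with the printed occupancy-dependent rates (refill
`(D₀−D)·R/τ_D`, mixing `(R₀−R)·D/τ_R`, replenishment `(R₀−R)/τ_ref`), exact
Gillespie sampling between spikes. The release probability uses the
Hill-with-threshold form; the resource `Ca_pre` jumps by `Ca_jump` per spike
and both relax deterministically (τ_pre = 20 ms, τ_rec = 20 s,
δ_Ca = 4×10⁻⁴). Glutamate amplitude variability follows the printed
Γ(1/0.52, 0.52) (mean 1, CV ≈ 0.72); a `glu_cv_mode` switch provides a
CV = 0.52 variant and a fixed-amplitude mode used for uncaging-style
protocols, where release is forced and GABA co-release suppressed. GABA
otherwise shares the release events and amplitudes (synchronised co-release
from the same decision). The whole presynaptic stage, including the
EPSP-evoked-AP test (25 Bernoulli draws against the release probability of
the EPSP accumulator, evoke on >80% successes, +15 ms latency), is computed
ahead of the postsynaptic simulation and depends only on the protocol,
conditions and its own random draws.

## Numerical scheme

The engine (C++) advances the coupled system on an adaptive fixed-step grid:

* 10 µs inside a 15 ms window after each postsynaptic spike (AP upstroke),
* 50 µs elsewhere during stimulation (up to 1 s after the last event),
* 0.5 ms during relaxation.

Within each step, transition rates are frozen and the discrete populations
are advanced by exact Gillespie sampling inside the step (continuous jump
times, state-dependent propensities updated jump to jump). For rates that
are truly constant this sampler is exact, which is what the dwell-time and
chain oracle tests verify against analytic laws. Time-averaged open-state
occupancies over the step — not endpoint counts — drive the conductances and
calcium fluxes, so sub-step channel flickers (e.g. tonic T-type openings at
rest) contribute their correct time integral even on the coarse relaxation
grid.

Voltages use exponential-Euler updates (the spine's 2.8 fF capacitance makes
its equation stiff with a microsecond relaxation time; exponential Euler is
exact for the frozen-conductance linear system). Somatic gates and SK use
Rush–Larsen updates; the attenuation resources and readout activations have
exact frozen-coefficient updates. Calcium, buffer, dye and the enzyme
network integrate with RK4 on substeps of ≤50 µs (the buffer association
rate, ≈1.5×10⁴ s⁻¹, sets the stiffness limit). The x/(1−e^(−x/k)) gate
forms switch to a series branch for |x| < 10⁻⁴k. Negative calcium from
integration error is clipped at zero and counted (`neg_ca_events`, asserted
zero in tests). Halving all step sizes changes a reference protocol's mean
weight by well under one percentage point (tested).

Each sample starts from a two-phase warm-up: a mean-field relaxation (all
channels deterministic; by default 150 s, enough for the ~50 s CaN unbinding
time) followed by a short stochastic settling, after which the readout state
is reset. Samples are independent, with per-sample seeds derived from the
run seed; a run is bit-reproducible from (protocol, conditions, seed).

## The geometric readout

Active CaN is the CaM4-bound CaN species; active CaMKII is the sum of all
CaM-bound and autonomous kinase states. The LTP region is the printed
rectangle CaN ∈ [6.35, 10], CaMKII ∈ [1.4, 29.5] µM. The LTD polygon's
printed vertex list is unordered; vertices are stored in angular order about
the centroid, which yields a simple polygon containing the probe point
(2, 12) and abutting the LTP region's left edge. Boundary points count as
inside (dwell near edges is common); the shared LTP/LTD edge at CaN = 6.35
is the only locus where both indicators can be 1, a measure-zero set that
random-probe tests avoid. Region membership is evaluated on the integration
grid; between grid points the indicator is held, bounding the activation
error by (grid step × a_X).

The plasticity chain is LTD ⇌ NC ⇌ LTP with the two printed rates: every
toward-LTP transition at P_rate(act_P) and every toward-LTD transition at
D_rate(act_D) (sigmoids bounded by 1/13 and 1/18 s⁻¹). Direct LTP⇌LTD
transitions are not included — the printed description ("only two transition
rates") does not require them. Activations reset between samples.

## Problem sizes in the shipped tests and acceptance script

The acceptance script uses the sizes its reference quantities were defined
with: analytic evaluation for the release probability; one deterministic
30-pairing run for the BaP attenuation; matrix-exponential occupancy
propagation for the four deactivation constants; 20 stochastic samples
(6 s stimulation + 450 s relaxation) for the enzyme decay triplet; 20
samples (5 s + 300 s) per temperature for the uncaging CaN decay; and 50
single-release samples for the calcium peak. The default test suite runs the
same computations (sharing batches across assertions) in a few minutes on
one core.

## Known limitations

* **Enzyme-activation magnitudes vs the region geometry.** The calcium
  calibration (3 µM per release) together with the printed enzyme kinetics
  drives CaN and CaMKII harder than the fixed plasticity-region polygons
  presume: long low-frequency trains saturate CaN near the LTP region
  rather than the LTD region, so the package does not quantitatively
  reproduce the published frequency–response maps (LTD at 3 Hz vs LTP at
  50 Hz) or the per-protocol outcome classifications. The readout machinery
  itself is exact (oracle-tested); the mismatch is in the drive amplitude
  feeding it. Users studying outcome maps should treat absolute weight
  changes as qualitative.
* **CaM decay timescale.** The model's calcium-bound CaM relaxes with a
  ~2 ms N-lobe component and a seconds-scale tail; the intermediate ~500 ms
  timescale reported for the model family is not separately realised under
  any fit window, and the corresponding check is expected to fail.
* **CaN decay at 35 °C.** The model family states both ~120 s (pairing-train
  context) and 54.4 s (uncaging context) for CaN decay at 35 °C; these are
  mutually inconsistent under a single unbinding rate. The package's
  convention reproduces the uncaging pair's physiological-temperature value
  and leaves the ~120 s figure unmet (≈55 s measured).
* Dye mode implements the documented surrogates (dye species, +10 °C, BaP
  amplitude reduction ×0.8) and is qualitative.
* The trajectory serialisation is CSV/JSON via the CLI script; no HDF5.
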