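---
title: "Temporal sequence discrimination in a compartmental Purkinje cell model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal sequence discrimination in a compartmental Purkinje cell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Cerebellar Purkinje cells receive on the order of 10^5 parallel-fiber
synapses across an elaborate dendritic tree. If brief inputs arrive at a set
of dendritic sites *sequentially* — sweeping from the dendritic tips toward
the soma ("IN") or from the soma outward ("OUT") — can the cell's output
(somatic spiking) distinguish the two orders, even when the two stimuli are
identical in every respect except order? `pcseq` implements a biophysical
multi-compartment Purkinje cell model and the full experimental pipeline for
that question: directional pulse-train stimulation, spike-based response
classification, perturbation of the calcium-channel kinetics that carry the
temporal memory, and a climbing-fiber-gated depression rule that can retrain
the preferred direction.

## The model

### Cable equation on a labeled tree

The membrane potential of compartment $j$ obeys the spatially discretized
cable equation

$$ c_m \frac{\partial v_j}{\partial t} \;=\;
   \frac{a}{2R}\,\frac{v_{j+1} - 2v_j + v_{j-1}}{\Delta x^2}
   \;-\; \sum_k I_{k}(v_j) \;+\; I_{\text{ext},j}(t), $$

generalized to a branched tree: the second difference becomes a sum over
tree neighbours with per-pair axial conductances computed from the two
half-compartment axial resistances ($R$ the axial resistivity, $a$ the
cable radius). Terminals are sealed (zero flux). Compartments carry one of
four type labels — soma, main, smooth, spiny dendrite — and the label
selects the ion-channel inventory:

| type   | channels |
|--------|----------|
| soma   | Leak, NaF, NaP, CaT, Kh1, Kh2, Kdr, KM, KA |
| main   | Leak, CaP, CaT, Kdr, KM, KA, KC, K2 |
| smooth | Leak, CaP, CaT, KM, KC, K2 |
| spiny  | Leak, CaP, CaT, KM, KC, K2 |

### Channel kinetics as data

Each channel contributes $I_k = \bar g_k\, m^q h^r (v - E_k)$ with gates
obeying $\tau_x(v)\,\dot x = x_\infty(v) - x$. Five channels (NaF, NaP,
CaP, CaT, KA) define $x_\infty = \alpha/(\alpha+\beta)$ and
$\tau_x = 1/(\alpha+\beta)$ from rate functions $\alpha(v), \beta(v)$; the
rest define $x_\infty$ and $\tau_x$ directly. All rate functions are *data*:
a small library of named functional forms (exponential, sigmoid, linoid,
bell, constant, calcium-Hill-times-sigmoid) parameterized by coefficients in
a JSON file (`inst/extdata/channels_purkinje.json`). This keeps the kinetics
auditable and swappable without touching code. The alpha-beta rate
coefficients were transcribed from the published tables of the classic
compartmental Purkinje model this model descends from, as far as they are
recoverable; the direct-kinetics channels use sigmoid/bell forms matching
that model's voltage ranges and time-constant magnitudes; and the
conductance densities were then adjusted — once — so that the packaged
reduced morphology is quiescent at rest and sits near its spike threshold in
the stimulus range of interest. All of these are configuration, not
constants.

Two choices deserve explicit mention:

* **Calcium dependence of KC/K2.** The Hill term
  $[\mathrm{Ca}]^n/([\mathrm{Ca}]^n + K_d^n)$ multiplies the voltage
  sigmoid of the activation steady state (rather than entering the rate
  functions' arguments). This separable form is recorded in the parameter
  file itself.
* **Calcium reversal.** Calcium currents use a fixed Nernst-style
  $E_{\mathrm{Ca}} = 135$ mV rather than a GHK flux equation; this is a
  documented fidelity knob, configurable per channel.

Submembrane calcium follows a first-order shell model,
$d[\mathrm{Ca}]/dt = -\phi\, i_{\mathrm{Ca}} - ([\mathrm{Ca}] -
[\mathrm{Ca}]_\text{rest})/\tau_{\mathrm{Ca}}$, with $\phi$ derived from the
shell depth (0.2 µm) and the Faraday constant; $\tau_{\mathrm{Ca}} = 50$ ms.

### Why CaT matters

The discrimination mechanism rests on the low-threshold (T-type) calcium
channel: its activation boosts the depolarization delivered by each pulse,
and its inactivation gate $h$ — time constant about 50 ms in the operating
range, the same order as the inter-pulse intervals — carries a memory of
recent activity along the stimulated corridor. The order in which a
sequence recruits that corridor (distal-to-proximal or the reverse)
therefore changes how much boost reaches the soma. The perturbation
operation `scale_tau()` multiplies the CaT (or CaP) inactivation time
constant by a factor $f$; the experiments scan $f$ from 0.1 to 3.0, and the
test suite verifies that shrinking the CaT memory ($f = 0.1$) does not
increase — and in the scanned band eliminates — direction selectivity.

## Stimulation

A pulse train stimulates $n$ compartments on a straight dendritic path, one
1-ms current pulse each, at a fixed interval. `IN` fires distal to
proximal, `OUT` proximal to distal; both use identical compartments, times
and weights, so total injected charge is identical by construction and any
response difference is genuinely about order. Two pulse shapes are
provided: the ideal square pulse of amplitude $w$, and a ramped variant
$w(1 - e^{-(t - t_j)/\tau_I})$ with $\tau_I = 50$ ms. Note that over a 1-ms
pulse the ramped form delivers only about 2% of $w$; both modes are exposed
because the choice materially changes the effective stimulus scale.

Sweep grids enumerate (pulse count, interval, weight) triplets in
deterministic order. The full-scale study grids are 19 pulse counts
(2–20) × 20 intervals (10–200 ms) × 20 weights, i.e. 7,600 triplets, and
2,800 for the 7-count main-dendrite cube. The weight list is slightly
ambiguous in its source (1–10 nA in 0.5-nA steps names 19 values, yet 20
are reported, and quoted weights such as 7.920 and 6.633 nA sit on a
×0.99-like grid); the default here is 20 evenly spaced values from 0.5 to
10 nA, with the grid fully configuration-driven.

Duration bookkeeping: the nominal duration is $n \times$ interval (so 6
pulses at 10 ms book as 60 ms and 20 at 200 ms as 4,000 ms), while the
physical last-pulse offset is $(n-1)\times$ interval + 1 ms; both are
stored on every `pulse_train`.

One mapping had to be fixed by fiat: sources differ on whether IN means
proximal-to-distal or the reverse. This package defines **IN =
distal-to-proximal** (toward the soma), and the mapping is visible in
`schedule()`'s output rather than buried.

## Classification

The response to a triplet is the pair (soma spiked under IN, soma spiked
under OUT), classified as BOTH / IN_ONLY / OUT_ONLY / NEITHER. A spike is
an upward crossing of 0 mV with 2-ms separation — the source work defines
"spiking" only implicitly, so the detector is explicit configuration — and
"spiked" means at least one spike between the first pulse onset and the
last pulse offset plus a 500-ms grace window. The *discriminated ratio* of
a sweep is (IN_ONLY + OUT_ONLY)/total; cube summaries average per-cube
ratios unweighted because cube sizes differ.

## Plasticity

Parallel-fiber weights are plastic under a trace-based pairing rule. Each
stimulated compartment carries a presynaptic trace
$x_j \leftarrow e^{-\Delta t/\tau_\text{pre}} x_j + S_j$; the
climbing-fiber (CF) event drives a postsynaptic trace $y$ likewise. Per
update,

$$ \Delta w_j = -A_1\, y\, S_j + A_2\, x_j\, S + A_3, $$

with $A_1 = 0.9$, $A_2 = 0$ (depression only), $A_3 = 0.001$, and weights
clamped to $[0, 12.87]$ nA. Three semantic choices:

* **The update clock.** Applied literally at every solver step, the
  constant $A_3$ would accumulate at a rate proportional to $1/\Delta t$.
  Updates therefore run on a dedicated plasticity tick (default 1 ms)
  decoupled from the solver step, making $A_3$'s cumulative effect
  step-size independent while preserving its meaning (slow AMPA-receptor
  reinsertion).
* **Trace time constants.** $\tau_\text{pre}$ and $\tau_\text{post}$ are
  not given by the source; the defaults are 100 ms each, the order of the
  stimulus intervals, and they are ordinary visible parameters.
* **Presentations per trial.** In a single presentation with the CF
  delivered 2 ms after the last pulse, $y = 0$ at every pulse tick, so the
  depression term is structurally inert and only $A_3$ acts — the package
  surfaces this rather than hiding it. With two or more presentations in
  the 5,000-ms trial, the CF trace of one presentation overlaps the next
  presentation's pulses and depression engages. Both modes are supported;
  every result names the mode used (the learning tests and the acceptance
  script use `presentations = 2`).

The CF itself is modeled as a trace event only (a "simulated CF stimulus");
an optional somatic current injection can be attached but is off by
default. Because traces and weights depend only on event times, the weight
trajectory is computed exactly on the tick grid, and the membrane
simulation uses the weight in force at each pulse's onset.

The reversal experiment follows the four-step procedure: sweep with
learning off; pair each responsive sequence with a delayed CF under
learning; re-test both directions with the learned per-compartment weights
(learning off); and report sequences whose exclusive direction flipped
(IN_ONLY → OUT_ONLY or the reverse). Learned weights replace the uniform
sweep weight per compartment at re-test.

## The synthetic reduced morphology

`generate_reduced()` builds the packaged test cell: a soma, a chain of main
dendrite, then smooth and spiny layers grown breadth-first with a branching
cap, 43 compartments by default. It emulates the *type layering* and
tapering of the real cell (soma 10 µm radius; main 3 µm, smooth 1.25 µm,
spiny 0.7 µm; compartment lengths 20–40 µm, chosen so the explicit
stability bound comfortably exceeds the default step and the passive length
constant spans many compartments). Generation is bit-reproducible for a
fixed seed and never touches R's global RNG.

What it does **not** emulate: the real cell's 1,600 compartments and their
reconstructed geometry, the ~150,000 spines (no spine area correction), and
the sheer electrical load of the full tree. Consequences worth stating
plainly: the reduced cell's spike threshold sits at lower pulse weights
(the discrimination band is near 2–2.5 nA rather than 6–8 nA), and its
response classes change in coarser steps. Passing the packaged tests
demonstrates the *mechanism* — order-selective spiking that requires CaT
inactivation memory — not the full-scale parameter maps, which require the
original 1,600-compartment morphology and are explicitly out of desk-scale
scope. The `.p` reader exists so that the full morphology, where available,
drops straight in.

## Numerics

* **Schemes.** Default is an explicit scheme: forward Euler for the
  voltage, exact exponential integrators for gates and calcium (the gate
  update is exact under frozen voltage, so gate stiffness never limits the
  step). The implicit reference scheme is backward Euler with the ionic
  conductances linearized at the freshly updated gates and the tree system
  solved by Hines elimination; it serves as the numerical oracle in the
  tests, which require soma-trace agreement within 1 mV on an active
  fixture.
* **Steps.** Default $\Delta t$ = 5 µs explicit, 10–50 µs implicit. The
  explicit scheme *checks its stability bound at setup*
  ($\Delta t < C_j/g_{\text{tot},j}$ per compartment, a factor-2 safety
  under the forward-Euler limit) and refuses to run rather than silently
  blow up; non-finite voltages abort with a time stamp.
* **Tables.** Gate steady states and time constants are tabulated on a
  0.05-mV grid over [−100, 60] mV and linearly interpolated, with
  $e^{-\Delta t/\tau}$ pre-tabulated per run; the calcium Hill factor is
  computed analytically.
* **Units.** One fixed contract everywhere: mV, ms, µm, µF/cm², mS/cm²,
  Ω·cm, nA, µM; conversions are centralized in the simulation builder.
* **Determinism.** The solver contains no randomness; identical
  configuration and protocol give bit-identical traces, and sweep rows are
  written in grid order.

### Problem sizes used by the packaged tests and script

The test suite and `scripts/acceptance.R` run entirely on built-in
fixtures: the 26-compartment passive cable for the analytic profile check,
an 8-compartment chain for charge conservation, a 10-compartment active
fixture for the cross-solver oracle, and the 43-compartment reduced cell
with a 5-pulse path, weights {2, 2.5} nA × intervals {20, 40, 60, 100} ms
for the discrimination, τ-scaling and learning experiments (settle time
1,000 ms; 5,000-ms learning trials with 2 presentations). These sizes were
chosen as the smallest on which the mechanism is cleanly expressed. The
full-scale cubes (7,600 triplets × 21 start sites) are supported through
the same `run_sweep()` interface as a long-running mode.

## Known limitations

* The exact rate functions of the original model's supplementary tables are
  not all recoverable; the packaged direct-kinetics coefficients are
  reconstructions at the level of voltage ranges and time-constant
  magnitudes, and the parameter file is the single place to refine them.
* No spontaneous simple spiking: like its ancestor, the model is silent at
  rest, which is what makes spike/no-spike classification usable.
  Pause-based coding for spontaneously active models is out of scope.
* No GHK calcium flux, no stochastic gating, no temperature corrections,
  no conductance-based synapses (inputs are current pulses by design).
* The CF is an instruction event, not a biophysical synapse.
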