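---
title: "Modeling PV and SST interneuron function in auditory cortex: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PV and SST interneuron function in auditory cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acxsim)
```

## The circuit and the two model tiers

`acxsim` simulates an idealized auditory-cortex microcircuit of one
excitatory population (Exc) and two inhibitory interneuron populations —
parvalbumin-positive (PV, fast, perisomatic) and somatostatin-positive
(SST, delayed, dendrite-targeting) — at two levels of description.

**Rate tier.** A dimensionless Wilson-Cowan system. Each iso-frequency
unit obeys

$$\tau_u \dot u = -u + f(w_{ee}u - w_{ep}p - w_{es}s + q\,g(t)\,i(t) - u_{th})$$

with analogous PV and SST rows (the optogenetic drives $I_{Opt,PV}$,
$I_{Opt,SST}$ enter the PV and SST gain arguments; SST receives no
thalamic drive). $f$ is threshold-linear with gain $r = 3$, clipped at 1,
so all activities are normalized rates in $[0,1]$. Tones arrive as
instantaneous jumps of the input trace $i(t)$ with exponential decay
($\tau_q = 10$ ms), gated by a depressing thalamic resource $g(t)$
(recovery 1500 ms, depletion 20 ms). Within-unit weights are
$W_1 = \{\{1.1,2,1\},\{1,2,2\},\{6,0,0\}\}$ (rows postsynaptic Exc, PV,
SST): SST receives no inhibition, which makes its tone-evoked response
indirect (through Exc) and therefore delayed relative to PV — the
temporal asymmetry that drives most of the circuit's differential
effects.

Three units with lateral Exc-sourced connections
($w^{*}_{ee} = 0.667$, $w^{*}_{pe} = 1.25$, $w^{*}_{se} = 0.125$) and a
thalamic spread fraction $\alpha = 0.65$ form a gross tonotopy (left,
center, right abstract frequency channels). Two short-term plasticity
terms shape the tonotopic dynamics: the PV$\to$Exc weight depresses as
$w_{ep} - a(1-D_i(t))$ with $a = 0.5$, and the lateral SST$\to$Exc
inhibition is gated by a facilitation variable $F_i(t)$ with strength
$b$ (default 1). By default both reuse the thalamic resource
($F_i = 1-g_i$, $D_i = g_i$), the simplification the model family is
built on; the full differential equations are available via
`three_unit_params(use_proxy = FALSE)`.

**Spiking tier.** A conductance-based network of 1600 Exc, 200 PV and
200 SST adaptive exponential integrate-and-fire neurons per unit. Exc
neurons are two-compartment ball-and-stick models: PV synapses and the
thalamic current target the soma, SST synapses target the dendrite,
whose coupling current into the soma is scaled by $(1 + bF(t))$ with a
slow tone-driven facilitation $F$ ($b = 3$). PV$\to$Exc currents carry a
depression factor $a\,D(t)$ ($a = 1.7$). Synaptic conductances jump by
$g_{max}/n_X$ per presynaptic spike ($n_X$ the presynaptic population
size) and decay with 1 ms time constants except Exc$\to$PV (25 ms) and
Exc$\to$SST (15 ms). Thalamic input follows a fast-rising, doubly
depressing profile driven by the tone square wave, delivered to Exc and
PV only, with an 0.85-scaled copy to adjacent units. Connection
probabilities: 0.1 for Exc$\to$Exc, 0.6 for the other within-unit
classes, 0.1 for lateral (Exc-sourced only).

## Baseline-inhibition regimes

The circuit operates in two baseline states. Under *weak* inhibition the
Exc row uses $w_{ep} = 2$, $w_{es} = 1$ and the SST threshold is 1;
under *strong* inhibition the inhibitory weights rise to 3 and the SST
threshold drops to 0 (spiking tier: PV/SST$\to$Exc maxima 38/19 nS weak
vs 40/20 nS strong). A slow facilitation variable
$\dot{\bar F} = -\bar F^2/\tau_{F1} + \bar I/\tau_{F2}$
($\tau_{F1} = 1500$, $\tau_{F2} = 100$ ms), driven by the sum of all
tone input traces, classifies a paradigm by its 30 s asymptote against
the threshold $\bar F_{th} = 0.22$ (`baseline_facilitation()`,
`select_regime()`; a sigmoidal soft switch is available via
`select_regime(mode = "smooth")`).

Two deliberate design choices here:

* With our input-trace convention all four paradigm presets integrate to
  asymptotes above 0.22, but the oddball paradigm (0.62) and
  forward-suppression stream (0.73) saturate strictly above tuning-curve
  adaptation (0.47) and the single-tone paradigm (0.39). The package
  therefore treats the *separation* as the mechanistic content (and
  tests it), while the presets pin each paradigm's regime directly —
  equivalent to replacing the soft switch by its resolved value before
  the run, which is also how the model family is used in practice.
* The forward-suppression preset runs in the **strong** regime. Under
  weak inhibition the paradigm's signature bidirectional effect
  inverts: SST suppression *lowers* the normalized same-frequency probe
  response (5.6% vs control 6.6%) instead of raising it, while under
  strong inhibition the full pattern holds (PV suppression 3.1%,
  control 6.3%, SST suppression 12.3%). The weak regime remains
  selectable through `simulate_rate(regime = "weak")`.

## Paradigms and optogenetic schedules

`make_oddball()` builds the stimulus-specific adaptation (SSA) stream:
100 ms tones every 400 ms to the two units flanking the recorded center,
standard/deviant with probability 0.9/0.1, no leading or consecutive
deviants, two counterbalanced blocks with identical timing and swapped
roles (500 tones per block by default; block length is not dictated by
the paradigm tables, so it is a package choice).
`make_forward_suppression()` builds 500 ms masker-probe trials (50 ms
tones, 20 ms gap, probe fixed at the center) including a masker-absent
reference trial that defines 100% when probe responses are normalized;
the driver runs each masker condition as an independent trial from rest,
because in a continuous session the probe-unit depression accumulating
across trials contaminates later maskers (an ordering artifact, not a
circuit effect). `make_tuning_adaptation()` presents 8 tones per unit
with a 2400 ms inter-trial interval; `make_single_tone()` gives the 1 s
single-tone trials of the PV-activation paradigm.

Optogenetic drives are additive currents into PV or SST
(`make_opto()`): tone-locked for the oddball and forward-suppression
paradigms, sustained for tuning-curve adaptation and PV activation.
Suppression windows open 100 ms before tone onset and close 100 ms
after offset. Activation windows are concurrent with the tone: the
100 ms-early timing is documented for suppression only, and an early
SST-activation window tonically pre-activates SST (its drive exceeds
threshold at rest), collapsing the standard responses — the activation
CSI values below are only reproduced with concurrent windows.

## Metrics

* `csi()` — the common-contrast SSA index
  $(d_{f1}+d_{f2}-s_{f1}-s_{f2})/(d_{f1}+d_{f2}+s_{f1}+s_{f2})$.
  Deviant responses are all deviant tones; standard responses are
  standards at least two positions after a deviant. Responses are tone-
  window **peaks**: with window means, every default-parameter response
  (deviants included) sits below the 0.1 validity floor that masks
  unmeasurable CSI values, so the mean measure would blank the entire
  default parameter map. The mask flags (but still reports) CSI when a
  standard response is below 0.1 or the Exc response saturates (mean
  standard above 0.99 of the rate ceiling).
* `onset_aligned_correlation()` — Pearson correlation against the
  thalamic trace, optionally after onset alignment (first sample above
  10% of peak) or cross-correlation-peak alignment; the two are
  equivalent for clean onsets and the latter is the default.
* `ei_balance()` — least-squares slope through the origin of pooled
  excitatory vs inhibitory current samples during suprathreshold
  activity. Rate tier: recurrent weight currents ($w_{ee}u$ vs
  $w_{ep}^{eff}p + w_{es}s$) wherever $u > 0$; the dimensionless
  feedforward drive is not a circuit current and is excluded. Spiking
  tier: total excitatory transmembrane input (recurrent AMPA plus the
  thalamo-cortical synaptic current, which *is* a physical current) vs
  the PV-somatic plus SST-dendritic currents, sampled over the tone
  window.
* `tuning_light_ratio()` — light-on/light-off response pairs per
  frequency distance and tone index for the unit-slope comparison.

## Numerical choices

The rate tier integrates with fixed-step classical Runge-Kutta at
$dt = 0.1$ ms; the exogenous tone traces are advanced analytically
(exact exponential decay) so onsets land on the grid, and optogenetic
windows are piecewise-constant on the grid. Halving $dt$ changes traces
by less than $10^{-6}$, and the compiled path is cross-checked against
an independent explicit-Euler oracle at $dt = 0.001$ ms in the test
suite. The all-zero state is an exact fixed point without input, and the
saturating gain keeps activities in $[0,1]$ by construction. Initial
conditions: activities 0, $g = D = 1$, $F = \bar F = 0$, no burn-in.

The spiking tier uses Euler-Maruyama at $dt = 0.05$ ms with exact
exponential conductance decay between spikes, a 2 ms refractory period
and a spike cutoff at $V_T + 5\Delta_T$. Membrane noise is an additive
voltage increment $\sigma\sqrt{2\,dt/\tau_m}\,\mathcal N(0,1)$ per step
(soma only), giving a free-membrane standard deviation of
$\sigma = 20$ mV. The network realization is sampled with R's RNG under
`set.seed`; the membrane noise uses a dedicated xoshiro-style generator
seeded from the same integer, so a (seed, configuration) pair is
bit-reproducible.

Constants the AdEx literature provides but the model family leaves
open, all exposed in `spiking_params()`: adaptation coupling
$a_w = 4$ nS with $\tau_w = 150$ ms, spike-triggered increment
$b_w = 0.08$ nA, refractory 2 ms. The increment deserves a note: it
sets a slow negative feedback whose equilibrium current
($\approx b_w \cdot \text{rate} \cdot \tau_w \approx 0.25$ nA on Exc)
partially absorbs *sustained* perturbations, so chronic optogenetic
suppression produces weaker steady-state disinhibition in the spiking
tier than in the rate tier. A smaller increment (0.02 nA) lets those
sustained effects express more clearly but drags the spiking
excitatory/inhibitory balance slope well below its reference value of
2.5, so the canonical 0.08 nA is retained and the muted
sustained-suppression effects are listed as a limitation.

The maximal-conductance matrix is
$\{\{20,40,20\},\{240,40,12\},\{120,0,0\}\}$ nS. The strong Exc$\to$PV
coupling (240 nS at $\tau = 25$ ms) puts PV neurons under a
multi-nA recurrent drive, so they fire at high spontaneous rates and the
stated sub-nA optogenetic currents modulate rather than gate them; an
alternative reading proportional to the rate-model weights
(Exc$\to$PV 20 nS) lets $-1$ nA silence PV completely but degrades the
oddball-paradigm effects, so the default keeps the stronger coupling.
Alternate parsings are reachable through `synapse_params(Gmax = ...)`.

## What the synthetic protocols do and do not emulate

All inputs are generated internally: there is no external data. The
tone protocols reproduce the paradigm timing tables (durations,
inter-stimulus and inter-trial intervals, deviant probabilities); the
abstract units stand for well-separated frequency channels, so there is
no frequency axis in Hz, no partial spectral overlap, and no
across-trial variability in tone level. Thalamic input is a stereotyped
depressing drive; the models contain no subthreshold modulation or
population-spike mechanism. Passing tests therefore demonstrate the
circuit-level mechanisms — PV/SST compensation, depression-driven
adaptation, facilitation-gated lateral inhibition — under idealized
drive, not quantitative agreement with recordings (the reference
comparisons for those mechanisms are qualitative, sign-level claims,
which is what the directional regression suite asserts).

## Problem sizes

Default experiment sizes: 500-tone oddball blocks (rate tier), 30-trial
feedforward-connectivity sessions, eight-strength balance scans. The
spiking-tier summary statistics use the full 6000-neuron network with
5 seeds (correlations) and 3 seeds (balance). The spiking directional
suite defaults to a quarter-scale network (400/50/50 per unit) with
30-tone oddball blocks; its test-suite incarnation runs 10 seeds on a
1/8-scale network (200/25/25) with 36-tone blocks so that the full
matrix fits in an ordinary test session. Per-synapse increments scale
with $1/n_X$, so the mean-field operating point is unchanged across
scales while population-rate noise grows as the inverse square root of
the population size; the unit tests use further reduced networks for
structural properties.

## Known limitations

* The printed regime threshold 0.22 does not separate the paradigms
  under our input convention (the separation itself does); regime
  assignment is therefore preset-driven.
* The forward-suppression activation predictions reproduce for SST
  (stronger suppression) but invert for PV activation at its default
  amplitude.
* Spiking-tier optogenetic effects are weaker than their rate-tier
  counterparts at the stated amplitudes: the PV population is
  recurrently dominated (240 nS Exc$\to$PV coupling at 25 ms decay), so
  sub-nA optogenetic currents modulate rather than gate it, and the
  20 mV membrane noise keeps interneurons at high spontaneous rates.
  Consequently several spiking sign claims hold only in a majority of
  seeds rather than uniformly (the directional suite reports
  pass fractions around 0.6–0.7 rather than the 0.9 the rate tier
  would suggest), the PV-activated feedforward correlation gain is
  small, and the two spiking feedforward correlations land near 0.92
  for both conditions instead of separating.
* No fitting to experimental recordings is attempted anywhere.
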