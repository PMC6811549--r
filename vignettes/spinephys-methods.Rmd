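---
title: "Models and methods behind spinephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the neuron
model, the measurement definitions, the synthetic-cohort generator, the
statistical layer, and the numerical and design choices that were
genuinely open. Nothing here states an empirical result that the test
suite or the acceptance script does not itself compute.

## The neuron model

The simulator is a conductance-based point neuron (optionally with one
lumped dendritic compartment) built around the hyperpolarization-
activated cation current I_h, because I_h dominates the phenomena the
package measures: voltage sag, post-hyperpolarization rebound, membrane
resonance, and the slow voltage-clamp relaxation used to build
activation curves.

Units are fixed package-wide: mV, pA, nS, pF, ms (so `C dV/dt`,
`g (V - E)` and injected currents are all in pA without conversion
factors), and sweeps are stored at 20 kHz with times in seconds.

Somatic voltage obeys

$$C_m \frac{dV}{dt} = -g_L (V - E_L) - g_h\, m\,(V - E_h)
  - I_{syn} + I_{inj},$$

with first-order HCN gating

$$\frac{dm}{dt} = \frac{m_\infty(V) - m}{\tau(V)}, \qquad
  m_\infty(V) = \frac{1}{1 + e^{(V - V_{1/2})/k}},$$

and a gating time constant that is a logistic function of voltage
between `hcn_tau_min` (hyperpolarized, fast) and `hcn_tau_max`
(depolarized, slow). The defaults (`neuron_params()`) describe an
immature layer-4 stellate cell: C_m 70 pF, g_leak 3.7 nS (leak-only
input resistance 270 MOhm), E_leak −65 mV, g_hcn 0.7 nS, V1/2 −86 mV,
k 8 mV, E_h −30 mV. Capacitance and leak sit in the range reported for
P10–14 cortical neurons; the HCN parameters were chosen once so that
the −125 pA step protocol produces a sag of roughly 10% of the peak
deflection in the wild-type configuration, the regime the measurements
target. The NMDA magnesium block uses the standard constants
$B(V) = 1/(1 + [\mathrm{Mg}]\cdot e^{-0.062 V}/3.57)$ with 1 mM Mg.

Two temperature regimes are used deliberately. The current-clamp
protocols run with fast gating (tau 40–250 ms), appropriate near
physiological temperature and required for the sag to express within a
500-ms step. The dedicated I_h voltage-clamp protocol is a
room-temperature experiment, so `room_temp_kinetics()` slows the
gating (tau 300–700 ms). This is not cosmetic: the I_h measurement
defines the "instantaneous" current inside a 10–60 ms window after the
step, which presumes that negligible activation develops inside that
window; with the fast kinetics several percent of the relaxation would
leak into it and bias the fitted midpoint by a few millivolts, whereas
the 5-s steps still reach steady state (more than seven time
constants) with the slow kinetics.

### Integration

Gating uses exponential Euler (exact for the locally linear gating
equation); voltage a forward update at a 0.025-ms internal step,
decimated to the 20-kHz output rate. Synaptic conductances are
differences of exponentials maintained as two analytically decaying
state variables per receptor, so synaptic updates are exact and
per-event amplitude weights are supported. Integration aborts with a
diagnostic if |V| exceeds 200 mV. The membrane time constants in play
(2.9 ms for the dendritic compartment and upward) are two orders of
magnitude above the step size, and the passive step response matches
the closed-form RC solution to within 0.5% (tested).

Action potentials are stylized: when the somatic voltage crosses a
threshold (default −49 mV), the spike time is recorded as a marker and
a stereotyped waveform (0.3-ms rise to +35 mV, sub-ms fall to the
reset) is pasted into the trace, followed by a 3-ms refractory hold.
This gives AP detection something realistic to find (dV/dt above
20 V/s, a zero-crossing, a measurable amplitude) while keeping the
simulator free of sodium/potassium channel models, which nothing in
the analysis requires. The spike threshold was set so that, together
with the ensemble synaptic weights below, the near-simultaneous
protocol needs on the order of eight to nine wild-type spines to reach
threshold.

### The two-compartment option and sublinear summation

Current-based inputs onto a single compartment superpose exactly, so a
point neuron cannot produce the sublinear multi-spine summation the
analysis must detect; linearity-slope recovery on that configuration
is instead the module's superposition oracle (slope 1.00 within 2%,
tested). Sublinearity requires a shared dendritic driving force: the
two-compartment model places all synapses on a small dendritic
compartment (C 8 pF, leak 0.8 nS) coupled to the soma by 2 nS. Several
co-active conductance synapses depolarize the dendrite toward the
synaptic reversal, each successive input faces a smaller driving
force, and the observed compound EPSP falls below the linear sum of
the singles. NMDA conductance counteracts this (depolarization
relieves magnesium block), which is exactly the mechanism by which the
knockout preset — more NMDA weight — shows less sublinear summation
than wild type.

### The linearized resonant membrane

Membrane resonance produced by HCN is subtle at the conductance the
presets use, so resonance recovery is validated on a constructed
linearized membrane: an R–C membrane in parallel with a
phenomenological inductive branch (series resistance r, inductance L),
whose impedance

$$Z(\omega) = \left(g_L + i\omega C + \frac{1}{r + i\omega L}\right)^{-1}$$

is closed-form. `resonant_membrane(f_peak)` solves L from this
expression by root finding, so the target peak location is analytic
and independent of the time-domain simulator that is then asked to
recover it. The construction defaults (C 500 pF, R 250 MOhm,
r 0.05 GOhm) were chosen to give a clearly expressed peak (Q around
2–3): a 20-s chirp estimates |Z| with percent-level systematic error
from spectral leakage, and with a nearly flat peak (Q near 1) the
argmax of such an estimate is not meaningful to 0.1 Hz.

## Measurement definitions

**Sag.** Per hyperpolarizing step, deflections are measured from the
pre-step baseline; the peak is the most negative voltage in the first
200 ms, the steady state the mean of the final 100 ms, and
`sag % = 100 (peak − steady)/peak`. The 200-ms/100-ms windows are not
dictated by the measurement itself; they were fixed once from the time
course the model produces (peak well inside 200 ms at these membrane
time constants) and live in function arguments. The rebound is the
maximal depolarization above baseline within 200 ms of release, and
the rebound slope is the least-squares slope of rebound against
steady-state deflection across steps.

**Impedance.** `|Z(f)|` is the ratio of Fourier amplitude spectra of
voltage and current over the chirp segment, restricted to 0.2–20 Hz
and smoothed with a Gaussian kernel in log10 frequency (sigma 0.05
decades); the resonant frequency is the quadratically interpolated
argmax. The Q factor is defined as the peak impedance over the
impedance at the low band edge — the literature does not agree on a
single "Q-factor" formula, so this package states its own and keeps it
configurable through the band arguments; by construction Q >= 1. A
guard rejects stimuli whose spectral power does not extend into the
upper half of the analysed band, since the estimator is meaningless
for non-swept stimuli.

**I_h extraction.** The instantaneous current is estimated by a
linear extrapolation of the 10–60 ms window back to the step onset
(removing what little relaxation develops inside the window), the
steady state is the mean of the final 500 ms, and I_h is their
absolute difference, reported as a positive magnitude. Steps whose
final two 250-ms bins differ by more than 5% of the developed
amplitude are flagged unsettled but kept.

**Activation fit.** The amplitude-versus-voltage curve is fitted with
the variable-slope sigmoid by Levenberg–Marquardt least squares with a
multi-start over midpoints (−70, −85, −100 mV). By default the
amplitudes are first divided by the driving force (V − E_h), i.e. the
fit is performed on chord conductance. This matters: the raw current
curve is the product of a Boltzmann and a driving force that triples
over the analysed range, and fitting it directly places the apparent
midpoint several millivolts hyperpolarized of the gating midpoint.
The conductance fit recovers set midpoints within 1 mV on noiseless
simulations (tested); `response = "current"` remains available to
reproduce the plot-the-currents convention, with its midpoint
understood as a property of the current curve, not the gate.

**Uncaging windows.** AMPA uEPSC: 0.5-ms average around the extremum
within 10 ms post-photolysis, relative to a 5-ms baseline; NMDA:
window mean over 20–50 ms at +40 mV (after the AMPA component has
decayed); uEPSP: peak over 20 ms. Repetitions (at least three) are
averaged before measurement. Silent spines are called with a common
noise floor of 3x the baseline SD — a threshold borrowed from the
mEPSC amplitude criterion, since no separate silent-spine threshold is
standard; a spine below floor at −70 mV but above it at +40 mV is
silent, below floor at both is unresponsive and excluded from ratio
statistics.

**Template detection.** The Clements–Bekkers-style sliding fit: at
every template position, scale and offset are solved in closed form
from running sums (the cross-correlation computed by FFT), the
detection criterion is scale over residual SD, and local criterion
maxima above threshold (default 3) become candidates. Candidates must
then exceed 3x the SD of the 5 ms preceding baseline, and a
refractory period (7.5 ms at −70 mV, 25 ms at +40 mV) is enforced
keeping the *higher-criterion* event of any close pair — resolving by
quality rather than by order maximizes recall on overlapping events.
The criterion threshold is a free parameter of the method (the
algorithm is standard but no canonical threshold exists); it is
reported in the event-table metadata.

## The synthetic-cohort generator

`generate_cohort()` is the package's stand-in for a study whose raw
recordings are not publicly deposited. Its genotype presets *are* the
simulated study conditions; their group means are set to the printed
group values of the study being emulated (uEPSC amplitude 6.9 vs
9.8 pA; silent fraction 0.064 vs 0.176; activation midpoint −86 vs
−92 mV; MIS incidence 0.072 vs 0.205; mEPSC rates and amplitudes;
morphology means), and the dispersions are realistic choices fixed
once: cell-level parameters log-normal with 10–15% CV, midpoints
normal with 1.5 mV SD, spine amplitudes log-normal with 40% CV.

Choices worth flagging:

- **Truncated amplitude distribution.** Responsive-spine amplitudes
  are drawn from a log-normal left-truncated at 4.5 pA, with the
  log-mean solved so the truncated mean equals the preset mean. The
  truncation encodes a measurement fact: a spine whose AMPA response
  cannot be resolved above the noise floor is, by definition, not in
  the responsive class; without it, the classifier would relabel the
  lower tail as silent and both the silent fraction and the amplitude
  mean would drift from their presets.
- **Silent spines carry full NMDA strength.** A clear +40 mV current
  is what makes a silent spine classifiable at all, so silent spines
  draw their NMDA conductance from the strength distribution of a
  typical spine rather than from their own (zeroed) AMPA amplitude.
- **Ensemble protocol weights.** The near-simultaneous protocol uses
  a different optical configuration from sequential single-spine
  uncaging, and its responses are correspondingly larger; the
  generator applies a fixed conductance gain (28x) and a reduced
  effective NMDA weight (0.3 WT / 0.5 KO of AMPA) to the ensemble
  synapses. These two constants, together with the spike threshold,
  set the spines-to-AP operating point and the sublinearity level.
- **Thalamocortical trains.** The train synapse uses a slow NMDA
  decay (150 ms), appropriate for GluN2B-rich synapses at this age;
  the slow component is what makes 10-Hz trains summate more
  effectively than 5-Hz trains. Trial-to-trial amplitude variability
  is log-normal with 25% CV.
- **Nesting.** Litters contain animals of both genotypes
  (littermates), one slice per cell, so the hierarchical statistics
  see the intended random-effect structure.

What the generator does *not* emulate: electrode series-resistance
artefacts and bridge imbalance, temperature drift, space-clamp error
along real dendrites, channel noise, seal degradation over time, or
spike-waveform diversity. Passing tests on generator output therefore
demonstrate estimator correctness against known ground truth under
idealized recording physics — not robustness to every pathology of
real recordings. The QC gate (`reject_cell()`) operates on metadata
precisely because those pathologies arrive as measured quantities, not
as simulated traces.

## The statistical layer

Family selection fits normal, log-normal and gamma by maximum
likelihood (all two-parameter families, so likelihood ranks them
directly, AIC breaking ties); non-positive data restrict the choice to
normal, with a note. The hierarchical comparison fits mixed models
with lme4 — Gaussian LMMs (on log values for the log-normal family),
Gamma or binomial GLMMs with log/logit links — with random intercepts
for litter, animal and slice, and tests genotype by a likelihood-ratio
test against the model with genotype dropped. Random terms with fewer
than two levels, or as many levels as observations (slice, when there
is one cell per slice), are dropped up front; a singular fit is
simplified by dropping slice, then litter, never animal, and the
realised structure is recorded in the result's metadata. Type-I error
of this procedure is checked by a 200-run null simulation at 10
animals per genotype and must land in [0.025, 0.075] at nominal 0.05.

Two-sided Fisher tests use the point-probability convention (the
p-value sums all tables no more likely than the observed one), which
the tests verify against an independent hypergeometric enumeration.
The D'Agostino–Pearson omnibus statistic (D'Agostino's skewness z,
Anscombe–Glynn kurtosis z, K2 = z1² + z2²) is implemented in the
package because no installed dependency provides it, and is verified
against an external reference implementation on frozen data. The
curve-comparison F-test uses the standard nested sum-of-squares form
with shared-versus-separate parameter sets for linear, origin-linear
and sigmoid models.

## Problem sizes and determinism

All validation runs on sizes chosen to exercise the estimators while
keeping the full suite to a few minutes: cohorts of 3 animals × 2–3
cells per genotype, 200 spines for classification calibration, 60-s
detection sweeps with around 100 events, 200 null simulations for the
type-I check, and tens of random tables for the Fisher enumeration
comparison. Every stochastic element takes an explicit seed, and
cohorts, pipelines and the acceptance script are bit-reproducible
functions of (configuration, seed).

## On-disk format

The canonical store is a plain-text CSV directory (`write_cohort()` /
`read_cohort()`): per-cell metadata, a sweep index carrying dt, clamp
mode and holding level, marker tables, one two-column trace file per
sweep, and a JSON provenance sidecar with seed and preset. All floats
are written with 17 significant digits, which makes the round trip
bit-exact for doubles — the property the IO tests assert. This format
was chosen over a binary sweep store because it needs no binary
dependencies, diffs cleanly, and makes bit-exactness trivial to
guarantee; NWB/HDF5 import is a recognised dialect name but not
provided by this build.

## Known limitations

- The point-neuron model cannot reproduce location-dependent dendritic
  effects (distance-dependent filtering, local spikes); the
  two-compartment model captures shared-driving-force sublinearity
  only.
- The stylized spike mechanism makes AP amplitude and half-width
  essentially constant, so those AP parameters are only meaningful as
  detection checks, not as biological read-outs.
- Resonance produced mechanistically by the HCN presets is weak
  (f_res near the low band edge); quantitative resonance validation
  uses the constructed linearized membrane instead.
- The apparent midpoint of a raw-current sigmoid fit differs from the
  gating midpoint by a driving-force-dependent shift; comparisons
  between conditions are unaffected (both shift together), but
  absolute midpoints should be read from the conductance fit.
- mEPSC detection recall is quoted for template-shaped events at 5x
  noise SD; slow, heavily overlapping event trains (the +40 mV NMDA
  regime at high rates) are detected with lower recall, which affects
  absolute frequencies more than between-genotype ratios.
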