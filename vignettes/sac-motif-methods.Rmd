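---
title: "Modelling noise-resilient retinal inhibition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling noise-resilient retinal inhibition: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacmotif)
```

## The circuit and the question

On-Off direction-selective ganglion cells (DSGCs) of the mouse retina fire
preferentially for one direction of motion because starburst amacrine cells
(SACs) on their null side deliver directionally tuned GABAergic inhibition.
SACs themselves receive GABAergic input from neighbouring SACs and from
wide-field amacrine cells, forming serially connected SAC–SAC–DSGC and
WAC–SAC–DSGC motifs — canonically "disinhibitory" wiring. When a bright bar
moves over a randomly flickering checkerboard, removing the GABAergic input
to SACs (a *Gabra2* conditional knockout) does not enhance DSGC inhibition,
as disinhibition would predict, but weakens it, and direction selectivity
degrades. The mechanistic account this package implements: lateral
SAC–SAC inhibition gives the SAC a receptive-field surround; a bar crossing
that surround transiently silences the flicker-evoked depolarisations of the
SAC just before its motion-evoked response; without that silent window the
flicker keeps driving GABA release, and the short-term-depressing SAC→DSGC
synapse enters the motion response with a depleted vesicle pool.

The package provides every computational stage of that argument as a tested
module: morphology, passive cable model, stimulus, bipolar drive, depressing
synapse, protocol statistics, synthetic recordings, and the orchestrated
in-silico experiments.

## Passive SAC model and the soma-to-tip attenuation

The SAC membrane is purely passive (sodium and potassium channels blocked /
absent) with the experimentally constrained parameters carried by
`passive_params()`: resting potential −70 mV, axial resistivity
R~i~ = 40 Ω·cm, specific membrane resistance 9.2×10³ Ω·cm² on proximal
dendrites and 20×10³ Ω·cm² on the distal varicosity zone, and
C~m~ = 0.9 µF/cm². `discretize()` splits each segment of the morphology into
cylinders no longer than `dx_max` (default 2 µm), couples neighbours with
the axial conductance of two half-cylinders in series
(g = πa²/(R~i~ℓ) per half), treats the soma as one isopotential sphere, and
seals the terminals. Time-domain simulation (`simulate_cable()`) uses
backward Euler — implicit and unconditionally stable at the default
dt = 0.1 ms — with a sparse Cholesky factorisation that is re-used while the
synaptic conductances are unchanged (the bipolar drive is piecewise
constant, so refactorisations happen only at stimulus events). A voltage
clamp is an access conductance 1/R~s~ to the command potential; the default
R~s~ floor of 0.01 MΩ tracks the command to solver tolerance while keeping
the system matrix symmetric. Correctness is pinned to closed forms in the
test suite: a sealed-end uniform cylinder must match
V(x)/ΔV = cosh((L−x)/λ)/cosh(L/λ) with λ = √(R~m~a/2R~i~) to better than 1%,
a lumped compartment must charge with τ = R~m~C~m~ to better than 1%, and
the clamp current must balance membrane plus capacitive current to
round-off.

### The synthetic morphology

The digitized SAC used in the original simulations is not published, so
`generate_sac_morphology()` builds a stand-in and is explicit about being
synthetic. The defaults were chosen once, on anatomical grounds, and then
frozen: 6 primary dendrites, binary branching of order 5, a planar arbor of
110 µm radial extent, a 8-µm soma, cable diameters tapering 0.10 → 0.08 µm,
and 1.5-µm varicosity beads every 2 µm along the distal third of the arbor
plus one bead at every dendritic tip. Starburst dendrites are among the
thinnest neurites in the retina (on the order of 0.1 µm between
varicosities in electron microscopy) and their distal zone is densely
beaded; those two features — high axial resistance and a large distal
membrane load — are precisely what electrotonically isolates the release
sites from the soma. Thicker, smooth-dendrite geometries of the same
silhouette attenuate almost nothing (>95% of the somatic step survives to
the tips) and cannot reproduce the measured isolation. With the defaults,
`steady_state_attenuation()` reports a mean terminal depolarisation of
about 25–26% of the somatic clamp step:

```{r attenuation}
m <- generate_sac_morphology(seed = 1)
model <- discretize(m, passive_params(), dx_max = 2)
att <- steady_state_attenuation(model, clamp_dv = 10)
round(att$percent, 1)
round(1 / att$mean_ratio)   # the command scale factor this implies
```

The ratio is independent of the clamp size (the passive system is linear),
nearly identical across generator seeds (the jitter is small), and grid
convergence changes it by less than 1% per halving of `dx_max`. Its
reciprocal, rounded, is the ×4 command scaling used in the paired-recording
protocol; scale factors 3 and 5 bracket it in the robustness checks.

## Stimulus and bipolar drive

`stimulus_spec()` describes a positive-contrast bar (110 µm along motion,
385 µm across, 6.3×10⁴ R\*/rod/s) sweeping at 440 µm/s by default over a
660-µm arena, on either a uniform 1800 R\*/rod/s background or a
checkerboard whose checks switch independently each 1/15 s frame with
probability `p_on` (default 0.5 — the distribution is binomial and the
parameter is not otherwise constrained, so the maximally variable value is
used). Space is continuous; the model samples the field analytically rather
than rasterising frames. The model-facing checker uses 12.5-µm checks so a
single check is commensurate with one bipolar receptive field; the
display-facing default is 55 µm.

Bipolar cells (`place_bipolars()`) contact the tree in a semi-random
pattern, about 10 per primary dendrite within 100 µm of the soma, each with
a square receptive field of one model check (12.5 µm side, an explicit
design choice — the field extent is not otherwise specified), a release
threshold at −45 mV, a step to 7 mV above threshold while the bar or an
"on" check covers the field, and a tonic off state 7 mV below threshold
(symmetric by choice, keeping tonic drive e^(−7/6) ≈ 0.31 of the threshold
rate). Release maps to conductance through the exponential nonlinearity
exp((V−V~thr~)/6 mV) and a saturating map g = g~max~·drive/(1+drive) with
per-synapse ceilings drawn uniformly from 20–50 pS; a linear, non-saturating
map is available as a switch. The integration test of the whole chain
checks the salient emergent property: a centrifugally moving bar over the
noisy background depolarises soma and distal tip to comparable peaks
(ratio within a factor of 2), even though a somatic voltage step reaches
the tips at only ~25% — distributed dendritic input and somatic clamp
attenuate very differently in a passive tree.

## The depressing SAC→DSGC synapse

`simulate_release()` implements a single-pool resource-depletion model: the
dendritic-equivalent command V(t) engages release at rate
r(t) = \[exp((V−θ)/g) − 1\]₊ · U · R(t), the available resource obeys
dR/dt = (1−R)/τ~rec~ − r(t), and the DSGC IPSC is the release flux
convolved with a unit-peak bi-exponential kernel (rise 1 ms, decay 20 ms)
times a scale factor. The resource equation is linear within a sample, so
each step uses its exact solution; the integrator is therefore accurate for
the piecewise-constant drives the protocols produce. A single depleting
pool (no facilitation) is deliberate: the paired-pulse data show only
depression.

`U` is defined as the fraction of available resource released by one
standard activation. `calibrate_pulse_amplitude()` makes that definition
operational: for a rectangular pulse of width w it returns the amplitude at
which the depletion 1 − e^(−hw) equals exactly U. With that standard pulse,
the simulated paired-pulse ratio must equal the analytic depletion-recovery
expression 1 − U·e^(−Δt/τ~rec~); the tests hold this to 2% across
Δt ∈ {0.2, 0.4, 1.6} s (the experimental intervals), with monotone recovery
and PPR → 1 at ten recovery time constants. The default calibration
U = 0.5, τ~rec~ = 0.7 s puts the PPR markedly below 1 at 200 ms and near 1
at 1600 ms, the qualitative shape of the measured recovery; the measured
values are reported only graphically, so the defaults are declared
calibrations, not extracted numbers.

Two synapse-level defaults deviate from a literal reuse of bipolar
parameters. The release threshold is −55 mV rather than −45 mV: the
calcium channels coupling SAC dendritic depolarisation to GABA release
activate at relatively hyperpolarised potentials, and flicker-evoked DSGC
IPSCs are prominent in recordings during the baseline period — a −45 mV
threshold would leave typical ×4-scaled flicker events sub-threshold and
silent, contradicting that observation. The e-fold gain stays at 6 mV, the
only release gain stated for the circuit.

`fit_depression()` recovers (U, τ~rec~) from PPR observations by nonlinear
least squares on 1 − U·e^(−Δt/τ) with a log-linear starting estimate.
Noiseless synthetic curves are recovered to 1e−6. Under 5% multiplicative
observation noise with 8 intervals, the recovered distribution over 100
seeded replicates is unbiased with median errors well inside ±20% for both
parameters; individual replicates can err more on τ~rec~, whose Fisher
information at that noise level bounds the per-replicate precision to
roughly ±13% (1 SD) — the recovery criterion is therefore asserted on the
distribution (mean and median within ±20%), not on every replicate.

## Synthetic SAC recordings

`generate_sac_vm()` emulates the phenomenology of somatic SAC recordings
that the analysis pipeline assumes, not their absolute statistics: a flat
baseline at −70 mV with 0.3 mV measurement noise; under the noisy
background, frame-locked depolarising flicker events (one Bernoulli(0.5)
draw per 66.7-ms frame, half-sine shaped, 40 ms long) with lognormal
amplitudes of mean 6 mV and SD 3 mV — in the recordings the flicker
responses are comparable in size to the motion response, which is exactly
why they can depress the synapse, and amplitudes much below that regime
would render the ×4-scaled events invisible to the exponential release
nonlinearity; a surround-suppression window of duration
`surround_extent/speed` in which the genotype multiplies event amplitudes
by (1 − residual suppression) and hyperpolarises the membrane by up to
3 mV; and a genotype-independent motion-evoked alpha-function
depolarisation peaking at 12 mV. The residual suppression fractions are
0.9 (control), 0 (*Gabra2* cKO, all GABAergic input removed) and 0.15
(Vgat cKO, wide-field input only) — the wide-field share is set to 15% so
that the Vgat knockout phenocopies the *Gabra2* knockout, as observed. The
surround extent default of 200 µm is anchored only by the ~150 ms
protective window measured at 1320 µm/s (200/1320 ≈ 0.15 s) and is a
declared calibration. Control and knockout populations differ *only* in
the surround window, by construction — the generator enforces the central
identifiability assumption of the analysis.

What the generator does not emulate: correlations between neighbouring
frames, spatial structure of the flicker response, adaptation of the
flicker amplitude over the sweep, and the cell-to-cell covariance of
resting potential and response gain (population jitter is independent with
10% CV). Tests passing on these traces therefore certify the analysis
pipeline and the mechanistic ordering, not quantitative agreement with any
recorded data set.

## The paired-waveform protocol and the speed series

`run_paired_protocol()` mirrors the dual-recording experiment.
`construct_control_waveform()` replaces the surround-window segment of a
knockout-style trace with the mean control-group pattern
(`mean_control_pattern()` averages seeded control traces), leaving every
sample outside the window bit-identical and cross-fading 5 ms at the seams;
`scale_waveform()` amplifies both waveforms about the baseline mean (the
scaling anchor is not otherwise specified; the baseline mean makes the
scaling act on deviations from the operating point). Both scaled waveforms
drive the depressing synapse, and IPSC peaks are quantified in window 1
(baseline) and window 3 (motion). Because the waveforms are identical
through windows 1 and the preceding samples, the window-1 ratio is exactly
1 — the internal control — while persistent flicker in window 2 depletes
the pool and pushes the window-3 ratio below 1 for any scale factor in
3–5. `run_speed_series()` repeats this at 110, 440 and 1320 µm/s. Because
the 1320 µm/s window holds only ~2 checker frames, a randomly drawn trace
may contain no surround event at all; the experimental protocol used
representative waveforms matching the average number and amplitude of noise
events in the window, and `representative_cko_trace()` implements exactly
that selection (first seeded candidate whose surround event count equals
its expectation, with at least one event).

## The direction-selectivity experiment

No quantitative DSGC input–output function is available, so the spiking
readout (`dsgc_readout_params()`) is deliberately minimal and its use
ordinal: spike count per direction is Poisson with rate
gain·max(E − w(θ)·Q, 0), where Q is the motion-window IPSC charge of the
simulated null-side SAC pathway, w(θ) = (1−cosθ)/2 peaks in the null
direction, and E is a direction-independent excitatory drive (DSGC
excitation is unchanged in the knockouts), fixed at 1.3× a control-group
reference charge computed identically for every genotype at a given seed.
`run_dsi_experiment()` reports DSI = (pref−null)/(pref+null) on the 0°/180°
pair. At the default calibration the control group keeps its DSI under
noise while the *Gabra2* knockout loses selectivity through elevated
null-direction spiking; in the noise-free background the genotypes are
statistically indistinguishable. Only these orderings — not the DSI
magnitudes — are asserted.

## Numerical choices and problem sizes

Defaults were chosen so the full test suite and the reproduction script run
comfortably on a single core: morphology discretised at dx_max = 2 µm
(≈4000 compartments; one sparse solve for the attenuation), cable time
steps 0.1–0.2 ms, synthetic traces sampled at 1 ms, synapse protocols at
0.2 ms, 10–25 control traces per mean pattern, and 25–50 trials per DSI
condition. All randomness flows through explicit integer seeds; every
generated object records its seed and parameters, and identical
configuration plus seed reproduces results bit-for-bit. Degenerate inputs
fail loudly: zero-terminal models, overlapping pulses, empty analysis
windows, undefined DSI (zero total count), non-positive control metrics and
malformed SWC rows all raise errors rather than guessing.

## Known limitations

The SAC model is passive: no voltage-gated calcium channels, no
SAC–SAC network simulation (lateral inhibition enters only through the
generated membrane-potential phenomenology), no Off-pathway, and no
cholinergic SAC→DSGC excitation. The DSGC is a one-line readout, not a
biophysical model. The synthetic morphology reproduces scale, branching
style and electrotonic behaviour of a starburst cell but not the exact
branch statistics of any digitized reconstruction; the attenuation figure
should be read as "a SAC-like arbor with realistic calibres under the
stated membrane parameters", with a per-terminal spread (reported
alongside the mean) of a few percentage points.
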