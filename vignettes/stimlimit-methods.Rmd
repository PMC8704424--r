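---
title: "Charge-limited microelectrode stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-limited microelectrode stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimlimit)
```

## The problem

High-acuity subretinal prostheses need stimulating electrodes packed at a
pitch of a few tens of micrometres, which forces disk diameters down to the
10–30 μm range. At that scale the safe charge per pulse — bounded by the
electrode material's charge injection capacity (CIC) — shrinks with the
geometric area, and the question becomes whether retinal ganglion cells
(RGCs) can still be recruited, at what charge threshold, and over what
dynamic range of evoked spiking, all *within* the electrochemical safety
limits. `stimlimit` implements that analysis as a tested pipeline with
three measurement stages and a synthetic-data generator that emulates the
recordings the analysis expects, so every stage is testable end to end
without instrument data.

## Electrochemical limits

**Charge storage capacity (CSC).** Slow cyclic voltammetry (200 mV/s,
−0.6 to +0.8 V vs Ag/AgCl, the water window of iridium oxide) yields a
current trace whose time integral per sweep direction, normalised by
geometric area, is the anodic/cathodic CSC. `compute_csc()` integrates by
trapezoids over samples inside the water window. Two numerical choices
matter:

* *Sweep-direction attribution.* The anodic/cathodic split is taken from
  the potential trajectory (dV > 0 vs dV < 0), not from the sampled current
  sign: the current magnitude is continuous across the sweep vertices while
  its sampled sign flips there, so direction-based attribution keeps the
  quadrature error at O(Δt²) instead of O(Δt) per vertex.
* *Cycle averaging.* With ≥2 complete cycles the first (conditioning)
  cycle is discarded and the rest averaged; a sub-cycle scan is integrated
  as a single segment with a warning.

**Charge injection capacity (CIC).** A biphasic, anodic-first,
charge-balanced current pulse polarizes the electrode; the transient
potential decomposes into an instantaneous ohmic access-voltage step
V_a across the electrolyte and the electrode polarization E_m = ΔV − V_a.
`measure_polarization()` reads the polarizations 10 μs after the end of
each phase (E_ma anodic, E_mc cathodic), referenced to the mean potential
over the 1 ms before pulse onset — the reference is not standardised in the
field, and a pre-pulse baseline makes polarizations comparable across
electrodes by removing DC offsets. V_a is measured as the potential step
across the single sample interval straddling each current edge, with the
capacitive drift removed by extrapolating the pre-edge slope; the steps are
averaged over all four edges. The pulse model includes a 100 μs interphase
gap so the post-phase read happens at zero current; sampling must be at
least as fine as the 10 μs delay (the generator default is 100 kHz).

`compute_cic()` takes a family of transients at strictly increasing
per-phase charge, finds the largest pulse whose polarizations stay inside
the water window, and refines the limit by linear interpolation in charge
of the binding polarization between the last passing and first failing
pulse — the same interpolation convention the threshold estimator uses.
The limit divided by geometric area is the CIC density; for the reference
synthetic electrode (series RC with 4.125 mF/cm² specific capacitance) the
anodic limit binds at 0.8 V × 4.125 mF/cm² = 3.3 mC/cm² exactly, so the
interpolation is exact and serves as a closed-form oracle.

At 3.3 mC/cm² the per-phase charge budgets are 2.59, 10.37 and 23.33 nC
for 10, 20 and 30 μm disks (exact π d²/4 arithmetic; conventional
2-significant-figure reporting rounds these to 2.6, 10 and 23). The budget
scales exactly as d² (1 : 4 : 9).

## Volume-conductor field model

The quasi-static potential in a homogeneous ohmic medium obeys
∇·(σ∇V) = 0 with E = −∇V. The default configuration is a disk injecting a
fixed (uniform) current density into a medium of σ = 0.2 S/m, with a
grounded return far away; an equipotential-disk variant is available for
sensitivity analysis, as is a half-space mode (disk on an insulating
substrate, fields doubled) alongside the sphere/full-space mode.

**Closed forms.** For the uniform-current-density disk of radius *a* in
full space the on-axis solution is

$$V(z) = \frac{I}{2\pi\sigma a^2}\left(\sqrt{z^2+a^2}-z\right),\qquad
E_z(z) = \frac{I}{2\pi\sigma a^2}\left(1-\frac{z}{\sqrt{z^2+a^2}}\right),$$

which reduces to the point monopole I/(4πσz) in the far field. Off-axis
values integrate the surface source with a complete-elliptic-integral
kernel; the equipotential disk uses the oblate-spheroidal solution. These
closed forms are the oracle for the numerical solver and also power the
fast accessors (`activation_depth()`, `required_current()`).

**Finite-volume solver.** `solve_field()` discretises the axisymmetric
(r, z) problem with conservative finite-volume fluxes on a graded tensor
grid: uniform spacing a/16 out to two disk radii, then geometric growth
(ratio 1.2) to the domain edge — the disk-edge singularity demands local
refinement while the far field tolerates coarse cells. The disk applies a
Neumann flux J = I/(πa²); the rest of the z = 0 plane is zero-flux; the far
boundary is Dirichlet: V = 0 on the grounded shell in sphere mode, or the
asymptotic monopole value at the domain edge in half/full-space mode (an
open-boundary condition; a hard zero at finite range would bias the near
field by O(z/R), which the 1–2% oracle-equivalence requirement does not
admit). Full-space solutions exploit the disk's mirror symmetry by solving
one half with I/2. The sparse system is solved directly; the relative
residual must be below 1e−8. On axis the solution matches the closed form
within 1.6% at the default grid and 0.4% at one refinement (node-wise,
z ∈ [2, 50] μm for a 10 μm disk), and matches the monopole within 1%
beyond ten radii; solutions are linear in I to machine precision.

**Activation depth.** With the conventional 1000 V/m minimum field for
stimulation, `activation_depth()` inverts the on-axis field (closed form
for the uniform-J disk, bisection otherwise; 0.01 μm tolerance). At each
diameter's CIC-limited 1 ms current the depth increases strictly with
diameter. At σ = 0.2 S/m the full-space depths are 31.8 / 63.6 / 95.5 μm
for 10 / 20 / 30 μm disks; reported experimental modelling of this
configuration quotes substantially shallower depths (∼20/35/55 μm) that
are not reproducible from σ = 0.2 S/m under either disk boundary condition
or geometry mode — they are consistent with σ ≈ 0.5 S/m, which yields
19.8 / 39.7 / 59.5 μm. The package therefore treats the depth *ordering*
and the oracle equivalences as the reproducible facts and leaves σ as an
explicit configuration knob rather than guessing which value was actually
used. Depth is measured on-axis from the electrode plane; an iso-surface
reading would differ off-axis.

## Evoked-response statistics

Trials carry spike times relative to stimulus onset with a ≥2 s baseline.

* `count_evoked()`: spikes in the 0–500 ms evoked window minus the
  baseline rate × window length. Negative values (suppression) are kept.
* `build_psth()`: trial-averaged rate in 10 ms bins over −50 to +500 ms;
  by construction Σ rate·Δt over post-stimulus bins equals the mean
  post-stimulus count (an exact conservation law, property-tested).
* `response_curve()`: per charge level, the response probability
  (fraction of trials with ≥1 spike in the evoked window after blanking
  the stimulus span + 0.5 ms) and the spontaneous-corrected mean count.
  The probability is a raw per-trial boolean — a boolean cannot be
  rate-corrected — while the correction applies to counts; the two
  definitions are deliberately kept distinct.
* `estimate_threshold()`: the charge at which the response probability
  first reaches 0.5, by linear interpolation between the first bracketing
  pair of levels ("lowest crossing" — deterministic and conservative for
  non-monotone curves). A lowest level already at ≥0.5 returns
  left-censored; never reaching 0.5 within the CIC returns no-threshold.
* `estimate_half_max()`: same lowest-crossing rule on the count curve at
  half its within-CIC maximum.
* `dynamic_range()`: DR = 10·log₁₀(max within-CIC count / count at the
  threshold charge), with the threshold count interpolated on the count
  curve (a nearest-level mode is available). The power-style 10·log₁₀
  convention is used because spike counts are magnitude-like; multiply by
  2 for the 20·log₁₀ amplitude convention. DR is exactly 0 dB when the
  maximum equals the threshold count and is invariant to scaling all
  counts.
* `analyze_cell()` additionally applies a responsiveness screen before
  accepting a threshold: at least one within-CIC level's response count
  must exceed what the cell's own baseline rate predicts for the window
  (one-sided binomial test, α = 0.05, Bonferroni over levels). Without
  the screen, spontaneously active cells reach a 50% any-spike rate by
  chance at some level in roughly 9% of simulated non-responsive cells,
  which would inflate the responsive fraction; the screen reduces that to
  below 2% while retaining >99% of true responders.
* `population_summary()`: per diameter and protocol, the mean, median,
  quartiles and 9–91% range of thresholds and dynamic ranges, the
  responsive fraction, and charge-density thresholds (threshold /
  geometric area).

Short/long latency fractions (`latency_split()`) use a 100 ms cut by
default, with the sub-10 ms cut available descriptively; no direct-versus-
network attribution is made. `detect_spikes()` (band-pass 100–4000 Hz,
5×MAD threshold, 1 ms refractory merge, artifact blanking) is provided for
raw traces; the study-style tables enter at spike-time level.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised: anodic-first biphasic pulses of 1 or 5 ms per phase, single
pulses and 20-pulse 500 Hz trains, 5 repeats per level at 10 s intervals,
8 log-spaced charge levels from CIC/20 up to the CIC limit, and a 2 s
spontaneous baseline per trial.

**Electrochemistry.** CV traces are the capacitive response
i = ±ν·A·c(V) of a direction-specific pseudocapacitance profile (baseline
plus Gaussian redox peaks); the preset solves peak heights in closed form
so the designed window integrals are 12 (anodic) and 17 (cathodic)
mC/cm². Transients are the series-RC response with exact step charge.
Designed ground truths (`designed_csc()`, `designed_cic()`) are computed
by adaptive quadrature / closed form, independent of the analyzers.

**RGC populations.** Each cell draws a charge-threshold midpoint Q₀ from a
log-normal distribution (medians 0.83 / 1.8 / 3.6 nC for 10 / 20 / 30 μm
single pulses; train midpoints scaled by 0.46/0.83, 1.6/1.8 and 2.4/3.6),
is responsive with probability 0.47 / 1.0 / 1.0, and fires spontaneously
as a homogeneous Poisson process. Per trial, spiking occurs with logistic
probability in charge (scale 0.12·Q₀); a responding trial emits at least
one spike plus Poisson around a saturating-linear mean count
m(Q) = min(g·(Q − Q_b), m_sat), with the count onset Q_b = (1 − δ)·Q₀
sitting a fraction δ below the midpoint. Taking the count onset *at* the
midpoint would force the threshold count — and hence every dynamic
range — to zero, so the onset is a separate parameter. Latencies mix a
short Gamma component (mean 10 ms, shape 2, weight 0.6) with a long
uniform 100–400 ms component, echoing the bimodal latency structure of
subretinal stimulation.

**Dynamic-range calibration.** The designed population dynamic ranges are
8.0 / 10.4 / 12.8 dB (single) and 9.0 / 10.5 / 11.7 dB (trains), i.e. the
30 μm DR is 1.6× (single) and 1.3× (trains) the 10 μm value on the dB
scale. The per-diameter count parameters (δ, count at CIC, train slope
gain and saturation) were solved in closed form from those designed
values using the estimator's expectation
E[count at threshold] ≈ ½·(m(Q₀) + e^(−m(Q₀))) — the ½ from the logistic
probability at threshold, the exponential from the at-least-one-spike
floor — before any simulation was run. Train count curves saturate below
the CIC (trains evoke more spikes but the response flattens at the top of
the charge range), which is what allows trains to combine higher counts
with a *smaller* 30-vs-10 μm DR ratio.

**Chosen-once defaults.** Spontaneous rates are Gamma(shape 2, mean
0.2 Hz): the raw any-spike response boolean over a 0.5 s window only
carries information when the spontaneous hit probability is well below
0.5, so the generator emulates low-background recordings; real
degenerated-retina recordings can show much higher (often rhythmic)
background firing, and the raw boolean would then need the count-based
threshold mode instead. Midpoint dispersion is sdlog 0.35 (a broad,
strictly positive spread matching the wide reported quartile ranges);
cell distances are drawn uniform 0–25 μm (half the array pitch) and do
not modulate responses — coupling distance to the field model is an
extension hook, not part of this version.

## What the tests do and do not show

Fixed-seed simulations at n = 60 cells/diameter recover the designed
threshold medians within 15% (the estimator is sampling-limited with 5
repeats per level: the median of 60 log-normal draws alone has ≈6%
standard error, and interpolation on the 8-level ladder adds a few
percent), the designed DR ratios within 10% (across-seed standard
deviation ≈0.1 on a ratio of 1.6), and the designed responsive fraction
within the binomial CI at n = 100. Passing these says the estimators are
calibrated and unbiased *under the generative model*; real recordings add
artifact residue, bursting and oscillatory background, electrode drift
and cell-type structure that the generator deliberately omits, so the
tests validate the analysis machinery, not the biology.

Known inconsistencies in the reference values themselves are documented
rather than reconciled: the rounded per-electrode charges (2.5/10/25 nC)
imply slightly different densities (3.18–3.54 mC/cm²) than the single
3.3 mC/cm² figure; thresholds quoted as a percentage of CIC (38/23/18%)
do not match the quoted nC thresholds and charge budgets under any single
convention (0.83/2.5 = 33%); and the printed activation depths require a
conductivity about 2.5× the stated one (see above). No acceptance surface
in this package depends on reconciling them.

## Problem sizes and runtime

The shipped analyses use 60 cells per diameter and protocol (360 cells,
8 levels × 5 repeats each), a 100-cell arm for the responsive fraction,
CV scans of ~840 samples, 14-pulse transient families at 100 kHz, and
field grids of ~5.9k (default) to ~23k (refined) nodes — sizes at which
the full pipeline, test suite and acceptance script each run in well
under a minute on one core, while leaving every estimator in its
calibrated regime.
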