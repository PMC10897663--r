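---
title: "Methods: simulating and analyzing ex vivo aortic PWV acquisitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing ex vivo aortic PWV acquisitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archpwv)
```

## The problem

Aortic pulse wave velocity (PWV) is the standard surrogate for aortic
stiffness: the pressure/flow pulse launched by ventricular ejection travels
faster along a stiffer wall. In bench experiments on explanted thoracic
aortas mounted on a mock circulatory loop, PWV is measured as

$$\mathrm{PWV} = \frac{L}{\mathrm{TT}},$$

where $L$ is the centerline length of the specimen between the proximal and
distal connectors and $\mathrm{TT}$ is the transit time of the pulse between
the proximal and distal flow meters. Such experiments compare arch-mounting
configurations (a mildly angulated Type I arch versus a strongly angulated
Type III arch) and the stiffening induced by deploying a thoracic
stent-graft (TEVAR) into the same specimen.

Per-specimen raw data from bench studies of this kind are rarely deposited;
published tables carry only means and SDs. `archpwv` therefore pairs the
estimation pipeline with a synthetic bench-rig generator that produces
acquisitions with known ground truth, so every stage of the chain —
cycle segmentation, ensemble averaging, cross-correlation delay estimation,
pixel-scale calibration, arc-length measurement, the pressure–length
regression, and the paired statistics — can be validated end to end, and
cohort-level summaries with the published tables' structure can be
regenerated from scratch.

## The forward model

### Pump and afterload

A half-sine ejection waveform represents the pulsatile pump: flow is
$Q(t) = Q_{\max}\sin(\pi t/T_e)$ during the ejection window $T_e$
(default 35% of the cycle) and zero in diastole, scaled so the time average
equals the set cardiac output. The half-sine is the simplest shape with a
well-defined foot and a single systolic peak; valve dynamics are not
modeled.

The afterload is a three-element Windkessel: a characteristic impedance
$Z_c$ (default 5% of the peripheral resistance) in series with a
resistance–compliance pair. Because the forcing is periodic, the zone-3
pressure is computed exactly in the frequency domain: each flow harmonic at
angular frequency $\omega$ is multiplied by the impedance
$R/(1 + i\omega R C)$, and $Z_c Q(t)$ is added. There is no transient:
every acquisition is at periodic steady state.

### Auto-tuning

The bench protocol sets resistance, compliance, heart rate (75 bpm) and
cardiac output (4.5–5.5 L/min) until the zone-3 pressures reach physiologic
windows: DBP 75–85, SBP 115–125, PP 40–50, MAP 90–100 mmHg.
`tune_windkessel()` mirrors this: bisection on $R$ drives the measured MAP
(defined throughout as DBP + PP/3) to its target, then bisection on $C$
drives PP to its target; two sweeps of up to 40 iterations each suffice
because the two knobs are nearly separable ($R$ sets the mean level, $C$
the pulsatility). The MAP set-point is the window center (95 mmHg). The PP
set-point defaults to 41 mmHg, slightly below the window center, a choice
made from window arithmetic: since SBP $=$ MAP $+ \tfrac{2}{3}$PP, a PP of
45 at MAP 95 would park SBP exactly on the 125 mmHg window edge, where any
measurement noise pushes it out; PP 41 leaves about 2 mmHg of headroom on
both SBP and DBP. A tuned baseline that still misses any window raises an
error naming the offending window.

### Wall mechanics and arch effects

Each specimen carries wall parameters linked to its wave speed by the
Moens–Korteweg relation

$$c = \sqrt{\frac{E\,h}{2\rho\,r}},$$

with Young modulus $E$, wall thickness $h$ (2 mm), lumen radius $r$ at the
proximal landing zone (point 2) and fluid density $\rho$ = 1000 kg/m³ —
water is the circulatory fluid of the rig; the density is an explicit
argument for other fluids. The cohort generator draws a target baseline
wave speed per specimen and back-solves $E$, so the simulated PWV
distribution is controlled directly while remaining mechanically grounded.

How arch angulation raises pressure and PWV is a hypothesis, not an
established mechanism — an increased systemic vascular resistance is the
leading candidate. The simulator therefore encodes the Type III effect as
two explicit parameters rather than asserting physics:

* `arch_resistance_factor` (default 1.085) multiplies the tuned peripheral
  resistance when the specimen is mounted in the Type III guide, raising
  the mean pressure while leaving pulse pressure nearly unchanged (the
  compliance still shunts the harmonics);
* `arch_stiffening_exponent` (default 1) makes the effective wave speed
  pressure-dependent, $c = c_0\,(\mathrm{MAP}/\mathrm{MAP_{ref}})^\beta$
  with $\mathrm{MAP_{ref}} = 95$ mmHg, reflecting the nonlinear stiffening
  of the wall as distension increases.

With these defaults a Type III mount raises MAP by ≈8 mmHg and PWV by
≈8–9% relative to Type I, the directionality and magnitude the bench
comparisons report. A log-normal per-specimen response factor
(`arch_effect_sd`, default 0.10) spreads individual Type III responses by
about ±10%; the study orchestrator draws this factor once per specimen so
both of its Type III acquisitions (native and stented) share it — the
response to angulation is a property of the specimen, not of the
acquisition. The Type III centerline runs ≈0.7 cm longer
(`arch_length_delta_cm`), per the published mean lengths.

### Stent-graft

A deployed stent-graft stiffens its 112 mm covered segment. Locally the
wave travels at $\kappa c$ ($\kappa$ = `stent_speed_factor`, default 1.28),
so the true transit time becomes

$$\mathrm{TT} = \frac{L - L_s}{c} + \frac{L_s}{\kappa c}.$$

The default $\kappa$ was derived by inverting this expression for a ≈7%
PWV rise over a 36.2 cm Type I specimen, the reported magnitude of
TEVAR-induced stiffening in that configuration. As $\kappa \to \infty$ the
covered segment contributes nothing and TT tends to $(L - L_s)/c$, a limit
the tests exercise.

### Measurement noise and seeds

Additive Gaussian noise with SD expressed as a fraction of each waveform's
peak-to-peak amplitude (default 1%) emulates sensor noise; placement jitter
on planar points is Gaussian in pixels (default 1 px at 40 px/cm).
Everything is seeded: one master seed per study, with per-sample and
per-acquisition sub-streams derived deterministically
(`substream_seed()`), so any acquisition can be regenerated in isolation.

## The estimation pipeline

1. **Segmentation** (`segment_cycles()`): the record is cut into complete
   cardiac cycles synchronized with the pump rate; at least 25 consecutive
   cycles are required, as in the acquisition protocol.
2. **Ensemble averaging** (`ensemble_average()`): pointwise mean across
   cycles, suppressing noise by $\sqrt{n_\text{cycles}}$.
3. **Cross-correlation** (`estimate_transit_time()`): the delay is the lag
   maximizing the normalized circular cross-correlation of the
   mean-subtracted averaged cycles. Operating on the periodic single cycle
   is equivalent to tiling it once, so no edge samples are lost. The search
   is restricted to $(0, T_c/2]$ — the physical delay is positive and well
   under half a cycle for these lengths and speeds — with ties resolved to
   the smallest lag, and the integer peak is refined by three-point
   parabolic interpolation. Refinement matters: at 1 kHz and TT ≈ 100 ms,
   integer lags alone quantize PWV at the 1% level, too coarse for the
   0.01 m/s reporting precision. Identical inputs return TT = 0 with a
   degeneracy flag (useful in tests) rather than an error; a peak
   correlation below 0.5 raises an unreliable-estimate error. Waveforms are
   mean-subtracted but not detrended further, because the simulator
   produces stationary cycles; field data with drift would need detrending
   upstream.
4. **Centerline length** (`calibrate_scale()`, `arc_length()`,
   `fit_length_pressure()`): pixels convert to centimeters through the
   2.5 cm reference line on the arch guide; length is the polyline
   (chord-sum) arc length of at least 15 manually placed points. Polyline
   rather than spline: manual points are the only specified input, the
   polyline is reproducible, and its error against a smooth curve is
   bounded and testable (a semicircle sampled at 101 points is short by
   under 0.05%). Point order is taken as given (proximal to distal).
   Lengths at the three continuous-flow pressures (80/100/120 mmHg) feed an
   ordinary least-squares pressure–length line, and the length entering PWV
   is the line evaluated at the MAP realized during the pulsatile
   acquisition.
5. **PWV** (`compute_pwv()`): length over transit time, reported to
   0.01 m/s; pressures are reported to 1 mmHg and percent changes to 0.1%,
   matching the field's printed precision.

## Statistical layer

`paired_compare()` implements the normality-routed paired testing scheme:
Shapiro–Wilk on the paired differences (routing α = 0.05, two-sided tests
throughout, no multiplicity correction — matching the analysis convention
of such studies) selects a paired t test or a Wilcoxon signed-rank test
(zeros dropped; exact null for up to 25 non-zero differences, normal
approximation with continuity correction beyond). An explicit `test`
argument can force either branch — with very small n and tied differences
Shapiro–Wilk rejects essentially always, and an analyst may reasonably
prefer the t branch. Identical vectors are degenerate (p = 1); constant
non-zero differences are an error.

`icc_a1()` is the McGraw–Wong two-way, single-rater, absolute-agreement
intraclass correlation: mean squares for rows (specimens), columns
(raters) and error come from the two-way ANOVA decomposition, and

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
 {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the F-distribution confidence interval using Satterthwaite degrees of
freedom. The implementation is checked against an independent `aov()`-based
oracle to 10⁻¹⁰ and, by Monte-Carlo, against nominal CI coverage. When
$MS_E = 0$ (perfect within-cell fit) the interval collapses to the point
estimate.

`sample_size_paired_t()` iterates the exact noncentral-t power of the
two-sided paired t test and returns the smallest n reaching the requested
power. The effect size is a parameter rather than a constant because power
analyses in this literature inherit d from prior studies without printing
it; at α = .05 and power .95 a d near 1.3 yields n = 10.

## The in-silico study

`run_study()` reproduces the bench protocol's pairing: each specimen is
acquired in Type I and Type III configurations, and specimens whose point-2
diameter lies in the device's eligibility range (inclusive, 21.7–23.6 mm
for a 26 mm device at 10–20% oversizing) are re-acquired with the
stent-graft in both configurations. The afterload is tuned once per
specimen at its Type I baseline — as the experimenters tuned once and then
re-mounted — and only configuration deltas differ between acquisitions: the
arch factor, the stent, and a small cardiac-output re-mount jitter (SD
0.1 L/min) that emulates resetting the pump to the same output. Per-sample
failures (tuning or pipeline) are recorded and excluded listwise per
contrast, since paired analyses use complete pairs.

Oversizing uses the aortic-diameter denominator,
$d_\text{graft}/d_\text{aorta} - 1$: it is the only convention consistent
with both published anchors (26/22.8 − 1 = 14%; 26/1.2 = 21.7 and
26/1.1 = 23.6 mm). Percent changes are reported as both estimands — the
mean of per-specimen ratios and the ratio of means — because published
percent-increase figures with SDs are per-specimen means, which differ from
ratios of the printed group means.

## What the generator does and does not emulate

Emulated: pulsatile pressurization into physiologic windows, tapered
geometry and its population spread, pressure-dependent centerline length,
arch-configuration effects on pressure and wave speed with per-specimen
heterogeneity, stent stiffening over a fixed covered length, ≥25-cycle
acquisitions, sensor noise and manual point-placement jitter.

Not emulated: wave reflections and secondary waveform morphology (the
distal waveform is a damped, delayed copy of the proximal one), valve
dynamics, viscoelastic creep of the explanted wall over the experiment,
operator-dependent systematic bias in point placement (only zero-mean
jitter), specimen damage or leakage, and any structural change of the wall
between configurations. Passing tests therefore demonstrate that the
estimation chain recovers known ground truth under realistic noise — not
that the forward model captures every feature of bench waveforms.

## Numerical choices and degenerate inputs

* Windkessel solution via FFT of one sampled cycle: exact periodic steady
  state, no integration error or transient.
* Delays are imposed in closed form (the flow waveform is analytic), so
  fractional-sample ground truth is exact.
* Bisection bounds: $R \in [10^7, 10^9]$ Pa·s/m³, $C \in [10^{-10},
  10^{-6}]$ m³/Pa — generous brackets around the physiologic operating
  point (≈1.5·10⁸ and ≈1.2·10⁻⁸ at 5 L/min).
* Parabolic refinement is clamped to ±0.5 samples; a flat correlation
  (zero curvature) falls back to the integer lag.
* Zero-length polyline segments (duplicate clicked points) are allowed and
  contribute nothing; coincident scale-segment endpoints are an error.
* Degenerate statistical inputs: constant rating matrices (ICC undefined,
  0/0) and constant non-zero paired differences raise errors; identical
  paired vectors return p = 1 with a degeneracy flag.

## Problem sizes used by the test suite

The packaged suite validates the estimator-quality properties at these
sizes, chosen to give stable Monte-Carlo estimates on a single CPU: 200
random fractional delays for the transit-time oracle comparison (noise-free
and at 20 dB SNR), 10⁴ null replicates for the type-I error of the routed
paired comparison, 200 replicates per wave speed on the 2.5–5.5 m/s grid
for PWV parameter recovery (|bias| < 1%, SD < 3%), 100 tuned runs for
pressure-window attainment, and 20 replicate cohorts of n = 24 for the
qualitative Table-2 structure (Type III > Type I mean PWV in every
replicate, median arch-contrast p < .001, non-significant flow contrast).

## Known limitations

* The arch effect is a calibrated description, not a mechanism; the
  resistance factor and stiffening exponent cannot be identified separately
  from PWV data alone.
* The ventricular compliance of the physical pump is not reported in this
  literature; it is absorbed into the Windkessel compliance and the distal
  damping factor.
* Simulated percent-change spreads for the TEVAR contrasts (≈3% SD) are
  narrower than published ones (≈5–9%), because the stent factor is
  deterministic; only the arch response carries per-specimen heterogeneity.
* The eligibility fraction of simulated cohorts (≈48% for the 26 mm device)
  sits below the 62.5% a single bench cohort reported; the difference is a
  property of the published population parameters themselves (a
  Normal(22.8, 1.6) diameter puts ≈45% of mass in 21.7–23.6 mm), not of the
  filter.
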