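---
title: "Simulating nodule size measurement in dose-reduced chest tomosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nodule size measurement in dose-reduced chest tomosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomonodule)
```

## The question and the simulation chain

Chest tomosynthesis reconstructs coronal section images from about sixty
low-dose projection radiographs acquired over a &plusmn;15&deg; vertical
tube sweep. It has been proposed for the follow-up of pulmonary nodules,
where what matters is whether the longest nodule diameter can be measured
accurately and reproducibly — and whether it still can be when the
examination dose is cut to a half or a third.

`tomonodule` implements the computational chain needed to study that
question without patients: a population of ellipsoid nodules with exactly
known dimensions, analytic insertion of those nodules into raw projection
radiographs, a noise-injection simulation of dose reduction whose output
matches genuinely low-dose acquisitions in both magnitude and spectrum,
limited-angle filtered back-projection, a stochastic observer model that
emulates repeated manual diameter readings, and the accuracy/precision
statistics of those readings. Every stage is seeded and reproducible; the
`analysis/` scripts run the chain end to end at desk scale.

## Nodule model

Nodules are homogeneous ellipsoids with two equal minor axes. Size is
parameterised by the volume-equivalent sphere diameter $d$ and the
major/minor axis-length ratio $r \ge 1$:

$$a_\text{major} = d\,r^{2/3}, \qquad a_\text{minor} = d\,r^{-1/3},$$

so that $a_\text{major} a_\text{minor}^2 = d^3$ exactly (volume
preservation). The study population uses $d \in \{4, 8, 12\}$ mm and
$r \in [1.1, 1.5]$; at those bounds the major-axis ranges are
4.3–5.2, 8.5–10.5 and 12.8–15.7 mm. The ratio is described as uniformly
distributed; we realise it as a *deterministic uniform spacing* across the
27 nodules of a group, which reproduces the printed min/max exactly and
keeps the population identical under a fixed seed. The major axis lies in
the coronal plane (no out-of-plane tilt), rotated by an angle drawn
uniformly on $[0°, 180°)$ once per position and shared by the three size
groups at that position, so nodules at the same position correspond in
shape and orientation across groups.

The per-nodule motion-blur SD is drawn from a normal with mean 0.20 mm
truncated to [0.13, 0.32] mm — the published summary gives only that mean
and range, not the per-nodule values. The attenuation coefficient is
0.16 cm^-1^ (typical solid nodule at this beam quality); lung background
is 0.03 cm^-1^ and is subtracted at insertion, since the nodule displaces
lung tissue. The 27 anatomical positions are not published; a
deterministic grid spanning a plausible lung volume stands in, and
positions are ordinary configuration inputs.

## Acquisition and insertion

The geometry puts the detector at $z = 0$ with the focal spot sweeping
vertically at $z = \text{sid}$ (1800 mm default); angles span
$[-15°, +15°]$ inclusive, uniformly. The vendor's detector dimensions are
not published; defaults of 0.2 mm pitch and a 2022&times;2022 grid are
used, and every test and script chooses a reduced grid explicitly. Raw
pixel values are linear in detected exposure (pre-logarithm), which is
what makes insertion multiplicative.

The tube load per projection is
$\max(0.25, \mathrm{R10}(\text{scout mAs} \times 10 / 60))$ mAs, where
R10 rounds *down* to the Renard preferred-number series (…, 0.25, 0.32,
0.40, …). The clinical description is ambiguous about whether
quantisation precedes or follows the division by 60; both orders are
implemented behind `per_projection_tube_load(order=)`, with
divide-then-round as the default (the floor clamp makes the two coincide
at typical scout loads).

Insertion ray-traces every detector pixel in a window around the
projected nodule: the chord length through the (rotated, translated)
ellipsoid comes from the closed-form quadratic, evaluated after
re-centring the ray at its closest approach so the discriminant keeps
full precision even for source distances of 10^7^ mm (the parallel-beam
limit used in tests). The pixel factor is
$\exp(-(\mu_n - \mu_\text{lung})\,\ell/10)$, the increment
$\Delta P = P(A-1)$ is blurred with the detector MTF, scaled by
$1/(1+\mathrm{SPR})$ for scatter contrast loss, and added back. Three
stand-ins replace proprietary or irreproducible components, all
configurable:

* **MTF** — an isotropic Gaussian, $\mathrm{MTF}(f) = e^{-2\pi^2\sigma_d^2 f^2}$
  with $\sigma_d = 0.25$ mm; a tabulated curve can be supplied instead.
* **Scatter** — a scalar scatter-to-primary ratio per projection
  (default 0.4) instead of Monte-Carlo scatter maps.
* **Motion** — one random displacement per projection: direction uniform
  on the 3-D sphere (the stated "uniform over all directions" does not
  distinguish 2-D from 3-D; 3-D was chosen), magnitude
  $|N(0, \mathrm{SD}_\text{motion}^2)|$. Over many draws the mean
  displacement vanishes and the RMS magnitude equals
  $\mathrm{SD}_\text{motion}$, which the tests check by simulation.

## Dose reduction by noise injection

Simulating a dose fraction $s$ scales each raw projection by $s$ and adds
a synthetic noise image. At chest-tomosynthesis projection doses the
detective quantum efficiency falls as dose falls — electronic noise is
dose independent while quantum noise shrinks — so the added noise cannot
be simple white noise scaled by $\sqrt{s - s^2}$. The calibration
therefore consists of flat-field sets at several dose levels, from which
we take (a) the monotone pixel-value/variance relationship (piecewise
linear in the per-level means; exact for a quantum-plus-electronic
detector, whose variance is affine in the mean) and (b) the 2-D noise
power spectrum per level.

The noise image is white Gaussian noise shaped in the Fourier domain by
$\sqrt{\max(0,\, W_\text{low} - s^2 W_\text{high})}$ — the NPS of the
flat fields matched (by mean pixel value) to the scaled and the original
radiograph — then rescaled per pixel so its local variance equals
$v(sP) - s^2 v(P)$ from the variance curve. The exact internal ordering
of these corrections in the original method is not published; this
two-stage contract (spectral shape from the NPS difference, magnitude
from the variance curve) fixes the observable behaviour, and the
forward-simulation oracle in the tests confirms it: reducing a full-dose
flat-field stack to 50% or 32% reproduces the variance (within 5%) and
the radially averaged NPS (within 10% below 0.8&times;Nyquist) of flat
fields simulated directly at those doses. Negative spectral differences
(estimation noise at low frequency) are clamped to zero, with an error if
they cover more than half the spectrum — that indicates a calibration
inconsistent with the requested fraction.

The synthetic detector is stationary across projection angles, so one
calibration set serves every angle and the per-angle matching required
for real detectors becomes trivial; a per-angle calibration list is
accepted for data where that does not hold.

## Reconstruction

Sections are reconstructed by filtered shift-and-add: for a plane at
depth $z$, material at that depth appears in projection $i$ displaced
vertically by $-\text{sid}\tan\theta_i \cdot z/(\text{sid}-z)$ and
magnified by $M = \text{sid}/(\text{sid}-z)$; each projection is
resampled onto the object-plane grid (separable Catmull–Rom cubic
interpolation, reflected edges), filtered along the tube-motion axis with
a Hann-apodised ramp, and averaged. The vendor algorithm is proprietary;
this is the standard limited-angle stand-in, and its two testable
properties are the ones the study relies on:

* **Depth localisation.** A point-like object is sharpest (sum of squared
  vertical gradients in a window) in the section nearest its depth; the
  tests require &ge;95% agreement over 100 random depths at 5-mm section
  spacing.
* **Diameter preservation.** The ramp filter turns the projected ellipse
  profile into a flat-topped one: along the filtered axis the filtered
  profile of $\sqrt{c^2 - y^2}$ is constant inside $|y| < c$, so the
  width at half contrast of the in-focus nodule equals the true axis
  length rather than the $\sqrt{3}/2$-foreshortened FWHM of the raw
  chord profile. Measured perpendicular to the filter axis (where the
  per-column filtered values are constant inside the support for the
  same reason), a noiseless 12-mm-class in-plane ellipsoid is recovered
  within one 0.2-mm pixel; along the filter axis the Hann apodisation
  erodes the edge slightly more. `measure_diameter_fwhc()` takes the
  baseline from the profile's outer quarters and interpolates the
  half-contrast crossings linearly.

Section depths are chosen so one section coincides with each nodule's
centre depth, and `extract_case_window()` reproduces the presentation
format: 10 consecutive sections with the in-focus one at position 5, the
nodule centred in a circular ROI of equal radius for all nodules, the
window shifted inwards (never truncated) at stack edges.

## Synthetic data: what it emulates, and what it does not

The detector model produces
$\text{gain} \times \text{blur}(\text{Poisson quanta}) + N(0, \sigma_e^2)$:
mean linear in dose, variance affine with intercept $\sigma_e^2$, DQE
monotonically increasing with dose — the qualitative behaviour that makes
naive dose scaling wrong. Defaults (gain 0.2 raw/quantum, 5000 quanta per
pixel at full dose, $\sigma_e = 4$ raw units, blur $\sigma$ 0.18 mm) give
an electronic-noise share that grows from roughly a sixth of the variance
budget at full dose toward half below a third of it, which produces a
clearly dose-dependent DQE without letting electronic noise dominate the
full-dose image.

Lung-like backgrounds are a single 3-D power-law Gaussian texture
(spectral exponent 3 by default) projected per focal spot with a
depth-proportional vertical shear, entering multiplicatively in the
expected quanta. This gives the low-frequency anatomical modulation and
consistent parallax across the sweep, but **not** rib shadows, vessels,
or the heart/diaphragm high-density regions — the study deliberately
restricted itself to nodules in high-dose lung areas, and so does the
generator.

The observer model produces, for measurable cases,

$$y = a_\text{major} + \text{bias}(\text{group}, \text{dose}) + b_\text{obs}
  + u_\text{nodule} + \varepsilon_\text{round},$$

with $b_\text{obs} \sim N(0, \sigma_\text{obs}^2)$ per observer,
$u \sim N(0, \sigma_\text{nodule}^2)$ per observer-nodule pair and
$\varepsilon \sim N(0, \sigma_\text{intra}^2)$ per round. Non-measurable
status follows a logistic model in $d$ and dose fraction, driven by one
latent visibility per observer-nodule pair: marginally Bernoulli at each
dose, identical across rounds, and nested across doses (a nodule
invisible at one dose stays invisible at every lower dose), which yields
the characteristic pattern — many small nodules unmeasurable,
more so at lower dose; large nodules always measurable. The default
parameters (bias −0.4/−0.25/−0.15 mm by size group, an extra −0.2 mm
below 40% dose for a subset of observers, $\sigma_\text{intra}$ 0.2,
$\sigma_\text{obs}$ 0.1, $\sigma_\text{nodule}$ 0.3 mm) sit inside the
ranges human thoracic radiologists show on this task; they are
illustrative modelling choices, not fits to any reader's data, and
nothing in the package treats them as reproduction targets. Passing
tests therefore demonstrate the machinery — estimator calibration,
parameter recovery, orderings — not agreement with any particular
radiologist.

## Measurement statistics

Accuracy is the mean signed error (round-1 measurements minus truth) per
observer, size group and dose, with a t-based 95% CI. Precision has
three estimators:

* **Intraobserver** — per nodule, the SD of the two rounds divided by
  $c_4(2)$, averaged over nodules; $c_4(n) = \sqrt{2/(n-1)}\,
  \Gamma(n/2)/\Gamma((n-1)/2)$ unbiases the sample SD at these tiny
  sample sizes ($c_4(2) \approx 0.798$, $c_4(4) \approx 0.921$; verified
  against Monte-Carlo $E[s]/\sigma$).
* **Interobserver** — per nodule, the SD across the observers' round-1
  measurements divided by $c_4(m)$; averaged over nodules. The source
  description does not name the round; round 1 matches the accuracy
  convention and was adopted.
* **Internodule** — the SD over nodules of the round-1 signed errors,
  uncorrected (27 nodules is not a small sample; the correction is
  described only for the intra/inter SDs). Its CI is the chi-square
  interval for a normal SD, since this estimator is itself an SD rather
  than a mean of per-nodule SDs.

Nodules with a non-measurable entry are dropped from the affected
estimator only. The dose effect is tested with a one-way
repeated-measures ANOVA on $|y - \text{truth}|$ (round 1), nodules as
subjects, fitted with `stats::aov` and an error stratum; only nodules
measured at all dose levels enter, giving the df identity
$(k-1,\,(k-1)(n-1))$ — $(2, 16)/(2, 52)/(2, 46)$ at $n = 9/27/24$. No
sphericity correction is applied (none was used in the original
analysis). Significant omnibus tests are followed by paired t-tests with
p-values multiplied by the number of pairs and capped at 1. Under the
null the procedure's type-I error is 0.05 &plusmn; 0.01 at 2000
simulated replicates.

Kendall's tau-b relates dose level to internodule variability. With only
three dose levels the asymptotic p-value is meaningless, so for
$n \le 5$ it is computed exactly by enumerating all permutations of the
values; at $n = 3$, $|\tau| = 1$ gives $p = 1/3$, which is why a
reported $p < 0.001$ at three points cannot be reproduced and is not a
target.

## Numerical choices and problem sizes

Seeds propagate from one master seed through a small string hash, so
each stage (orientations, motion shifts, noise images, observer draws)
has an independent, reproducible substream, and any derived seed stays
below $2^{31}$. NPS estimation uses 128&times;128 half-overlapping ROIs
with second-order polynomial detrending, normalised so the spectral
integral equals variance times pixel area (Parseval, checked directly).
Noise-image normalisation divides by the analytic $\sqrt{\text{mean
spectral power}}$ rather than the sample SD, keeping the per-pixel
variance targeting unbiased. Cubic interpolation uses Catmull–Rom
weights with reflected edges; ramp filtering is circular along columns
(uniform backgrounds make wraparound negligible).

The tests and scripts run the image chain on reduced grids — detectors
of a few hundred pixels, 9–15 projections, 256–512&times;512 flat
fields — chosen so the whole suite completes in a couple of minutes
while every estimate stays far above its sampling noise; the physics
contains no scale-dependent shortcuts, and the full 2022&times;2022,
60-projection geometry runs through the same code path, only slower.

## Limitations

Smooth homogeneous ellipsoids avoid the shape ambiguity of real nodules
by construction; variability on irregular, spiculated lesions will be
larger. The reconstruction and MTF are parametric stand-ins for
proprietary vendor components, so absolute image texture is not
vendor-matched even though the tested geometric and spectral properties
are. The observer model has no psychophysics — it does not read the
reconstructed pixels, and dose enters only through its parameters — so
conclusions about human readers require the original reader-study data,
not this package. Dose increase ($s > 1$), detector lag/ghosting, beam
hardening and anti-scatter grids are out of scope.
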