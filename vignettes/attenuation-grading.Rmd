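---
title: "Grading brain-tumor infiltration from OCT attenuation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading brain-tumor infiltration from OCT attenuation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octatten)
```

## The problem

During glioma resection the surgeon must distinguish healthy brain tissue
from tissue at various grades of tumor infiltration. Optical coherence
tomography (OCT) can help: myelinated white matter scatters strongly, and as
tumor cells displace and degrade myelin, both the attenuation coefficient
$\mu$ and the backscattered intensity $I_0$ of the OCT signal drop. Gray
matter, having little myelin, resembles infiltrated white matter — which is
also where the approach finds its limits.

`octatten` implements the full quantitative chain for this measurement on
B-scan images from two system configurations: a swept-source system
(`"ss"`: 1310 nm, NA 0.021, 22/16 µm lateral/axial resolution) and a
spectral-domain system (`"sd"`: 930 nm, NA 0.051, 5.2/4.9 µm). Because no
public dataset accompanies this class of study, the package ships a
synthetic-cohort generator built on the same forward model, so every stage
can be validated end to end.

## Signal model

A single-scattering model describes an A-scan:

$$A^2(z) = r(z)\, h(z)\, I_0\, e^{-2\mu z},$$

with two instrument factors:

* **Spectrometer roll-off** $r(\xi) = \mathrm{sinc}^2(\xi)\,
  \exp(-\xi^2\omega^2 / 2\ln 2)$, where $\xi$ is depth normalized to the
  maximum imaging depth and $\omega$ is the ratio of the per-pixel
  wavelength spacing to the spectrometer's spectral resolution. Only the
  spectral-domain profile applies it; a swept source has no spectrometer and
  `apply_rolloff` is `FALSE` for `"ss"`.
* **Confocal collection** $h(z) = \left[1 + \left((z - z_f)/(n
  z_r)\right)^2\right]^{-1}$: a Lorentzian around the beam focus $z_f$ with
  Rayleigh length $z_r$.

Both are calibrated from mirror sweeps (`fit_rolloff()`, `fit_confocal()`):
one sweep moves the mirror by adjusting only the reference arm (samples $r$
alone), the other moves it physically with reference and focus fixed
(samples $r \cdot h$; the confocal fit divides $r$ out first). The fits are
bounded nonlinear least squares (Levenberg–Marquardt) in linear intensity
with analytic starting values ($\omega$ from a two-point log-ratio, $z_f$
from the argmax, $z_r$ from the half-maximum width) and a small multi-start
grid; a free amplitude makes recovery invariant to the sweep's intensity
scale.

Two geometric effects are handled explicitly:

* **Refraction focus shift.** Where the beam enters tissue ($n_1 = 1 \to
  n_2 = 1.36$) at surface depth $z_s$, Snell's law gives
  $\alpha = \arcsin(\mathrm{NA}/n_1)$, $\beta = \arcsin(n_1\sin\alpha/n_2)$
  and the shifted focus $z_f' = (\tan\alpha/\tan\beta)(z_f - z_s) + z_s$.
  A focus above the surface is left unshifted with a warning; the geometry
  does not apply there.
* **Depth rescaling.** Axial pixels sample optical path; geometric depth is
  the cumulative $\Delta s / n(i)$ with $n = 1$ in air and $1.36$ in tissue.
  We divide by $n$ (geometric = optical/$n$) so that fitted $\mu$ is per
  geometric millimeter and comparable across media; a
  `depth_scaling = "multiply"` switch preserves the alternative reading.

## The estimator

Patches of ~300 × 200 µm² (50 × 50 px on `"ss"`, 100 × 50 px axial ×
lateral on `"sd"`) are tiled laterally with 10 px overlap, starting 10 px
below the detected surface, and only where the label mask is homogeneous
(strictly: 100 % of pixels one label; a tolerance is configurable). Each
patch is averaged laterally to one A-scan, corrected by dividing out
$r$ and $h$ (the latter evaluated at the shifted focus on the geometric
axis), log-transformed and fitted by ordinary least squares over a 300 µm
window:

$$\ln A^2(z)' = \ln I_0 - 2\mu (z - z_s).$$

The window is counted in in-air pixels — 100 on the `"sd"` pitch (3 µm),
50 on `"ss"` (6 µm); the pitches themselves are fixed by those counts, the
only internally consistent choice with the stated window length. $I_0$ is
referenced to the tissue surface so that $\mu$ and $I_0$ decouple under
window translation. Pixels where a correction gain falls below $10^{-6}$ of
its maximum are flagged invalid rather than amplified; nonpositive
intensities are dropped from the regression, and a window with more than
20 % exclusions aborts that patch's fit (recorded per patch, not fatal to
the batch).

On noiseless synthetic input the corrected curve is a pure exponential and
the round trip recovers $(\mu, I_0)$ to better than $10^{-6}$ relative —
this forward–inverse exactness is the package's primary oracle and an
acceptance-tested property across both profiles, $\mu \in [0.5, 15]$
mm⁻¹, $\omega \in [0.5, 3]$ and $z_r \in [0.1, 0.5]$ mm.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` builds multi-patient cohorts: per-patient label
proportions jittered around a target mix (so cross-validation folds are
non-trivial), a mild log-normal patient-level effect on $(\mu, I_0)$
(default SD 0.05 in log units) making patches within a patient correlated,
and per-region parameters drawn log-normally around class medians. The
class medians default to the reference per-label values of
`reference_optical_properties()`, and the default spreads are half the
reference interquartile ranges, so a generated cohort reproduces
reference-like per-label distributions. Noise is fully developed speckle —
exponentially distributed intensity with the model value as mean — plus a
configurable additive background floor.

Deliberately absent: multiple scattering (which depresses apparent $\mu$ in
real tissue), lateral speckle correlation, motion and blood-flow artifacts,
heterogeneity within a labeled region, and the histology-registration
uncertainty that produces label noise in real datasets. Passing tests on
this cohort therefore demonstrate the correctness of the machinery —
corrections, estimator, statistics, cross-validation protocol — not
real-tissue classification performance. Published sensitivities and
specificities on patient data are not reproducible from synthetic input,
and the package makes no attempt to do so.

## Speckle and bias

Averaging the 50 columns of a patch before log-transforming leaves a small
positive offset in $\ln$-intensity ($\mathbb{E}[\ln \bar X] \approx \ln m -
1/2N$ for exponential $X$ with mean $m$), but because speckle is
multiplicative the offset is depth-independent and cancels in the slope:
$\mu$ stays unbiased while $I_0$ absorbs a ~1 % shift. The replicated-patch
test confirms $|\text{bias}| < 3\%$ in the mean $\hat\mu$ and strict
monotonicity across the white-matter grade medians (4.93, 3.91, 2.05, 1.22
mm⁻¹) with 200 seeded replicates.

## Comparing the two systems

`summarize_by_label()` reports per-label medians and 25th/75th percentiles.
`compare_systems()` implements the between-system statistic: for every
ordered pair of distinct labels $(x, y)$,

$$\rho_{xy} = \frac{m_A(x)/m_A(y)}{m_B(x)/m_B(y)},$$

collected over all pairs (the set is closed under reciprocals) and
summarized by median and quartiles. The ratio form makes the statistic
scale-free: a global recalibration of either system leaves every
$\rho_{xy}$ unchanged, so a median of 1 means the two systems order and
scale the tissue classes identically even though their absolute $\mu$
differ by a factor of ~2.5. "Relative difference" is implemented as this
ratio — verified by exhaustive enumeration before freezing — because it is
the only reading under which the reference medians reproduce the published
summary values. Quartiles use linear interpolation at $q(n{+}1)$
(`quantile(type = 6)`), the convention that best matches the published
brackets; it is configurable, and quartiles (unlike medians) are
convention-sensitive at $n = 20$ ratios.

## Classification protocol

Four tasks of increasing difficulty: (I) WM>60 % vs WM0 %; (II) adds
WM30–60 % to the tumor side; (III) adds WM0–30 %; (IV) adds GM0 % to the
healthy side. Two classifiers share one training protocol (Adam, learning
rate 0.001, categorical cross-entropy, batch 32):

* **FCNN** on the two optical features $(\mu, I_0)$: two fully connected
  hidden layers (widths 32, 32 — unstated in the protocol we follow, chosen
  as a small conventional default) and a softmax output. The protocol's
  "sigmoid" output with categorical cross-entropy is internally
  inconsistent for two classes; a 2-way softmax is the coherent choice.
* **CNN** on corrected image patches: four VGG-style blocks of (2, 2, 3, 3)
  3×3 same-padding relu convolutions with (64, 128, 256, 512) filters, 2×2
  max-pooling after each block, then dense 256 and 64. "Two or three layers
  per block" and "filters starting at 64 and increasing" are resolved by the
  VGG convention the architecture follows.

Training uses 30 epochs by default with a 10 % validation split and
best-validation-loss checkpointing, and horizontal flip plus ±10 %
horizontal shift (edge-replicated) augmentation for image inputs — all
seeded. Standardization is zero-mean only: per-image mean subtraction for
patches; for the 2-vector $(\mu, I_0)$ a literal per-input centering would
collapse the two features onto one axis ($x - \bar x = \pm(\mu - I_0)/2$),
so features are centered on training-fold means instead.

Evaluation is leave-one-patient-out: every sample of one patient is held
out per fold, rebalancing (random duplication, never deletion: first each
sample to the most prominent sample's patch count, then each class to the
most prominent class) and augmentation touch the training fold only, and
no patient contributes to both sides — asserted on provenance in every
fold. Folds whose training split lacks a class are skipped with a recorded
reason. Per-fold sensitivity and specificity (undefined denominators
reported as missing, not zero) are aggregated as mean ± SD.

The networks run on a compact feed-forward engine written in base R (dense,
3×3 same-padding convolution via im2col, 2×2 max-pooling, Adam,
cross-entropy), gradient-checked against numerical differentiation in the
test suite. It is sized for this package's desk-scale problems; the FCNN
trains a full LOPO study in seconds, while the full-size CNN is practical
for forward passes and small training runs.

## Numerical and design choices

* $\xi = \pi \cdot \text{depth}/\text{max depth}$ for the roll-off —
  the first sinc zero at the maximum imaging depth. The constant only
  rescales the fitted $\omega$ and divides out in the corrected signal.
* Mirror-sweep depth for $r$ uses the raw in-air axis (the instrument's
  coordinate); $h$ and the fit use the geometric axis.
* Maximum imaging depth defaults to 3.7 mm for both profiles (covers all
  sample imprint depths with headroom); configurable.
* Surface detection thresholds at background mean + 5 SD (estimated from
  the top rows), with a $10^{-3}\cdot\max$ fallback when the background is
  exactly constant; the crossing is found on a smoothed profile, refined on
  the raw profile so a noise-free flat surface is recovered exactly, then
  median-filtered across columns. Failure is declared when more than half
  the columns have no crossing.
* Degenerate inputs: $\mu = 0$ fits exactly (zero slope); $\omega = 0$
  reduces the roll-off to pure $\mathrm{sinc}^2$; a negative fitted $\mu$
  is reported but flagged `nonphysical`.
* One root seed spawns per-stage seeds deterministically in
  `run_pipeline()`, so partial re-runs reproduce; all generators require
  seeds and regenerate bit-identically.

## Problem sizes used in validation

The shipped tests validate on deliberately small configurations: A-scans of
120–450 pixels, B-scans up to 500 columns, cohorts of 2–8 patients with 2–3
samples each, 200 speckle replicates per grade for the bias study, 40–60
mirror positions per calibration sweep, and FCNN training of 12–30 epochs.
These sizes were chosen so the full validation chain — including the
stochastic studies — completes in well under a minute while keeping every
statistical tolerance meaningful; all of them scale up through ordinary
function arguments.

## Known limitations

* The single-scattering model omits multiple scattering; in strongly
  scattering tissue the true decay is sub-exponential and fitted $\mu$
  underestimates the scattering coefficient.
* The confocal correction degrades as NA grows (signal collapses away from
  focus faster than the Lorentzian can be estimated); the `"sd"` profile is
  the harder case.
* The 300 µm window assumes the tissue is homogeneous over the window; layered
  tissue within a window biases $\mu$ toward a weighted mixture.
* Synthetic-cohort results bound what the machinery can do, not what real
  tissue allows; gray matter vs infiltrated white matter (task IV) remains
  intrinsically hard because their optical parameters overlap.
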