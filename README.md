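# octatten

Attenuation-based grading of brain-tumor infiltration from optical
coherence tomography (OCT) B-scans.

During glioma surgery, the boundary between healthy brain and
tumor-infiltrated tissue is hard to see. OCT offers a quantitative handle:
healthy, myelin-rich white matter attenuates the OCT signal strongly, and
attenuation falls as tumor infiltration degrades the myelin. `octatten`
implements the full measurement chain that turns labeled B-scan images into
per-patch optical parameters and tumor/healthy classifications, for
neurosurgical-imaging researchers who want a tested, reproducible reference
implementation of this pipeline — and, because no public dataset exists for
this class of study, a seeded synthetic-cohort generator built on the same
forward model to validate every stage end to end.

## The model

An OCT A-scan is described by a single-scattering model

    A²(z) = r(z) · h(z) · I₀ · exp(−2 μ z)

where `r` is the spectrometer roll-off, `sinc²(ξ) · exp(−ξ²ω²/2 ln 2)`
(spectral-domain systems only), `h` the confocal collection efficiency
`1 / (1 + ((z − z_f)/(n z_r))²)`, `μ` the attenuation coefficient (per mm
of geometric depth) and `I₀` the backscattered intensity at the tissue
surface. `r` and `h` are calibrated from mirror sweeps; inside tissue, the
confocal focus is displaced by refraction per Snell's law
(`z_f' = (tan α / tan β)(z_f − z_s) + z_s`) and depth is rescaled by the
local refractive index (1 in air, 1.36 in brain tissue). After dividing out
`r` and `h`, the log-transformed signal is fitted by ordinary least squares
over a 300 µm window starting 10 px below the surface:

    ln A²(z)' = ln I₀ − 2 μ (z − z_s)

Per-label medians with quartiles, a scale-free between-system
relative-difference statistic, and a leave-one-patient-out classification
protocol (optical-feature and image-patch neural networks) complete the
pipeline. The methods vignette
(`vignettes/attenuation-grading.Rmd`) derives and motivates each piece.

## Worked example

Simulate a noiseless A-scan at the healthy-white-matter median attenuation
of the 1310 nm profile, correct it, and recover the generating parameters:

```r
library(octatten)

profile  <- load_profile("ss")                       # 1310 nm swept-source
confocal <- confocal_model(focus_mm = 0.9, rayleigh_mm = 0.25)
ascan    <- simulate_ascan(profile, mu = 4.93, i0 = 0.40,
                           surface_pixel = 11, confocal, n_pixels = 450)
fit <- fit_attenuation(correct_ascan(ascan, profile,
                                     as_calibration(confocal)), profile)
fit
#> Single-scattering attenuation fit (ss profile)
#>   mu  = 4.93 1/mm    I0 = 0.4 a.u.
#>   window: 50 px (300 um) from pixel 21; R^2 = 1.0000
```

The recovery is exact (relative error below 1e−6): the correction divides
out exactly the roll-off and confocal factors the forward model applied,
leaving a pure exponential whose log-slope is −2μ.

A small synthetic cohort, patch fits, and a leave-one-patient-out study of
the optical-feature classifier on task I (healthy vs >60 % infiltrated
white matter):

```r
cohort <- generate_cohort(n_patients = 4, samples_per_patient = 2,
                          class_mix = c("WM0%" = 0.5, "WM>60%" = 0.5),
                          profile, seed = 7)
fits <- batch_fit(cohort_patches(cohort, profile), profile,
                  as_calibration(cohort$confocal, cohort$rolloff))
summarize_by_label(fits, "mu")
#>    label parameter   median       q25      q75  n
#> 1   WM0%        mu 5.167506 4.9702600 5.702625 58
#> 2 WM>60%        mu 1.349546 0.8477263 1.760476 63

run_lopo_cv(assemble_task(fits[fits$ok, ], "I"), "fcnn",
            train_config(epochs = 15, seed = 5))
#> Leave-one-patient-out CV (fcnn, task I): 4 fold(s), 0 skipped
#>   sensitivity 1.00 +/- 0.00   specificity 1.00 +/- 0.00
```

The per-label medians land near the generating class medians (4.93 and
1.22 mm⁻¹, spread from the per-region and per-patient variation), and the
two extreme grades separate perfectly — on synthetic data whose class
distributions are this far apart, that is expected, and it validates the
protocol rather than predicting clinical performance.

The between-system statistic on the built-in reference medians shows that
the two systems, despite ~2.5× different absolute attenuation, order and
scale the tissue classes identically:

```r
ref <- reference_optical_properties()
mu_sd <- setNames(ref$mu[ref$system == "sd"], ref$label[ref$system == "sd"])
mu_ss <- setNames(ref$mu[ref$system == "ss"], ref$label[ref$system == "ss"])
compare_systems(mu_sd, mu_ss)
#> Between-system relative difference over 20 label pairs (5 labels)
#>   median 1.00 [0.76; 1.32]
```

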