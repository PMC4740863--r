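# hemoscan

Radar-based microwave head imaging for detecting intracranial hemorrhage
(ICH), built around a delay-and-sum (DAS) back-projection reconstruction
driven by a point-of-entry, depth-dependent effective head permittivity
model.

## The problem

Intracranial bleeding has a strong dielectric contrast against healthy brain
tissue, so a wideband antenna scanning the head monostatically (the same
antenna transmits and receives) records reflection coefficients
`S_n(f_m)` whose scattered component carries the bleed's signature. Imaging
the head interior from such data requires knowing how fast the wave travels
inside the head — but the head is heterogeneous (skin, fat, skull, CSF, gray
and white matter), so the classical assumption of one fixed average
permittivity misplaces or misses targets. This package implements the
alternative: a single effective permittivity that *varies with penetration
depth from the signal's point of entry*,

```
eps_eff(d) = eps_max * (1 - c1 * exp(-c2 * d / a))
```

where `d` is the depth from the entry point, `a` the distance from the entry
point to the head center, and `(eps_max, c1, c2)` are calibrated from
differential signal-arrival times (band-wide reference values 46.8, 0.75,
6.4). The full chain is:

1. **Frequency-to-time conversion** — inverse DFT of each position's
   284-sample sweep over 0.75–2.55 GHz (109% fractional bandwidth).
2. **Clutter removal** — adjacent average subtraction with Woody (first
   aligned) averaging: the dominant air–skin echo is nearly identical at
   neighboring positions and cancels.
3. **Gain normalization** — each scattered signal scaled to unit peak.
4. **Travel-time tables** — Fermat shortest-electrical-path times from every
   antenna to every 0.5 mm grid cell, with candidate entry points restricted
   to the antenna's line-of-sight boundary arc.
5. **DAS back-projection** — coherent summation of the scattered signals at
   the hypothesized round-trip delays; the absolute value is taken after
   summation and the image max-normalized.

Image quality is quantified by the signal-to-maximum-clutter ratio `gamma`
(> 1 means the global maximum is inside the true target region), the average
signal-to-clutter ratio `Q`, and the localization error `delta` (mm).

The package also provides a synthetic 2D layered head phantom with a
ray-based monostatic forward model (the test bed standing in for full-wave
scattering data), a noise-robustness study, Touchstone `.s1p` I/O, and
analytic radiation-safety calculators (incident power density and an
erfc-based skin temperature-rise model).

Audience: researchers in biomedical microwave imaging and students of
radar-based tissue imaging who need a complete, reproducible reference
implementation of the permittivity-model-driven DAS pipeline.

## Worked example

Calibrate the permittivity model to a head phantom, insert a 20 × 20 mm
bleed, scan, reconstruct, and score:

```r
library(hemoscan)

phantom  <- make_head_phantom()                      # ellipse 90 x 110 mm
model    <- fit_permittivity_model(phantom_permittivity_curves(phantom))
print(model)
#> <permittivity_model> variable, eps_max = 38.97, c1 = 0.328, c2 = 9.09

scan  <- make_parabolic_scan(105, 125, 32)           # ~15 mm standoff
bleed <- insert_target(phantom, c(45, 55))           # frontal quarter
data  <- simulate_reflection(bleed, scan, frequency_sweep(),
                             forward_config(seed = 1))

grid  <- imaging_grid(300, 300, 1)                   # 1 mm cells
image <- reconstruct_pipeline(data, bleed$boundary, grid, model)
image_metrics(image, target_region_rect(grid, c(45, 55), 20, 20))
#> <image_metrics> gamma = 2.209, Q = 4.517, delta = 0.71 mm,
#>                 argmax (44.5, 54.5) mm [correct localization]
```

`gamma = 2.209` says the brightest image cell lies inside the true bleed
region and is 2.2 times brighter than the strongest clutter elsewhere in the
head; `delta = 0.71 mm` is the distance from the true bleed center to that
cell. Running the same reconstruction with the legacy fixed model
`permittivity_model("fixed", eps_fixed = 1)` (free-space delays) misses the
target by over 100 mm, which is the point of the depth-dependent model.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/scripts/hemoscan`): `simulate`, `reconstruct`, `evaluate` and
`safety` subcommands over a YAML experiment configuration.

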