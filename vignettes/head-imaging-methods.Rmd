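---
title: "Methods: permittivity-model-driven delay-and-sum head imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permittivity-model-driven delay-and-sum head imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoscan)
```

# The imaging model

A monostatic wideband scan measures, at each of $N$ equiangular antenna
positions, the complex reflection coefficient $S_n(f_m)$ over $M = 284$
frequency samples covering 0.75–2.55 GHz. An inverse discrete Fourier
transform converts each sweep to a range profile; the package stores the
complex analytic signal

$$ s_n(t_k) = \frac{1}{M} \sum_m S_n(f_m)\, e^{+j 2 \pi f_m t_k}, $$

whose value at an echo's true round-trip delay equals the (real) echo
amplitude. This matters for the later coherent summation: channels align in
phase at a correct scattering hypothesis without any demodulation bookkeeping.

**Clutter removal.** The air–skin interface reflection dominates the raw
signal by one to two orders of magnitude. Because adjacent, equidistant
positions see nearly the same interface, subtracting the average of the two
ring neighbors cancels it. The Woody variant first shifts each neighbor by
the integer lag (bounded to 5% of the record) maximizing its
cross-correlation with the center signal, which helps when the skin echo
drifts between positions; sub-sample alignment is deliberately omitted for
determinism. Each scattered signal is then normalized to unit peak to
compensate the antenna's gain variation; all-zero channels are flagged
rather than rejected.

**Travel times.** The propagation path to a hypothetical scattering cell is
modeled as a free-space leg to a signal entry point on the skin plus one
straight interior leg. Following Fermat's principle, the one-way time is
minimized over candidate entry points, restricted to the boundary vertices
the antenna can actually see (the tangent-point arc):

$$ \tau = \tau_a + \min_{e \in \mathrm{LOS}}
   \left[ \frac{\lVert A - e \rVert}{c}
   + \frac{\lVert e - p \rVert \sqrt{\varepsilon_{\mathrm{eff}}
   (\lVert e - p \rVert;\, a(e))}}{c} \right]. $$

The minimization is exhaustive over the discrete line-of-sight vertex set
(the boundary resolution, default 360 vertices, controls the accuracy; a
continuous optimizer is avoided for determinism). Restricting to a subset
can only raise the minimum; for cells on the antenna's side the optimal
entry is visible and the restriction is exact, while for far-side cells it
correctly excludes unphysical occluded entries. The interior leg is a single
straight segment — no intra-head refraction — with the effective
permittivity evaluated at the segment length (endpoint evaluation, not a
path integral): the effective-permittivity function is *defined* as the
constant that reproduces the delay over a path of that length, so endpoint
evaluation is the consistent choice.

**The effective permittivity model.** The core quantity is a single
dielectric constant reproducing the true delay through the heterogeneous
head as a function of penetration depth $d$ from the point of entry:

$$ \varepsilon_{\mathrm{eff}}(d) = \varepsilon_{\max}
   \left( 1 - c_1 e^{-c_2 d / a} \right), $$

with $a$ the entry-point-to-head-center distance. The form encodes the
observed physics: a small value at the entry (thin high-permittivity skin
followed by low-permittivity fat and skull), a rise as the wave reaches CSF
and brain, and a plateau at $\varepsilon_{\max}$. It is monotone
nondecreasing, bounded by $\varepsilon_{\max}$, parameterized by exactly
$(\varepsilon_{\max}, c_1, c_2, a)$, and clamped at $d = 2a$ (no ray
penetrates beyond the far boundary). Band-wide reference constants are
$\varepsilon_{\max} = 46.8$, $c_1 = 0.75$, $c_2 = 6.4$; with them the model
starts at $\varepsilon_{\mathrm{eff}}(0) = 11.7$, consistent with a
skull-dominated entry. Among saturating two-shape-constant families
(rational, error-function, exponential), the exponential was chosen because
its two constants separate cleanly into dip depth ($c_1$) and saturation
rate ($c_2$), and because extraction and fitting then round-trip in closed
form.

**Calibration.** The model is calibrated per head, the way a propagation
study would do it: probes at increasing depths along inward rays record the
differential time of arrival $\Delta t(d)$, each converted to
$\varepsilon_{\mathrm{eff}} = (c\,\Delta t / d)^2$, giving one curve per
entry angle. Curves are averaged on the normalized-depth axis $u = d/a$
(depths differ between entry angles; normalizing makes the "unified" model
well defined) and fitted by unweighted nonlinear least squares
(`minpack.lm`), multistarted from three fixed initial guesses — seed-free
and deterministic. A degenerate (constant) curve falls back to a flat model
at its mean. `phantom_permittivity_curves()` runs exactly this study on the
synthetic phantom; all end-to-end experiments image with the resulting
head-calibrated model, while `permittivity_model()` defaults to the
reference constants.

**Reconstruction.** Delay-and-sum back-projection: each in-head cell's
intensity is the modulus of the coherent sum of the channels sampled
(linear interpolation; the 0.5 mm default grid is finer than the range
sampling) at twice the one-way Fermat time. The modulus is taken *after*
summation so that wrong hypotheses cancel; envelope detection would destroy
that. Delays beyond the record contribute zero. Images are max-normalized
with the raw maximum retained: un-normalized maxima carry diagnostic weight
(a real bleed produces coherent maxima an order of magnitude above the skin
residual of a healthy head).

# Image-quality metrics

With $\Omega_{\mathrm{head}}$ the head region and $\Omega_t$ the true target
region (an axis-aligned rectangle for synthetic targets),

* $\gamma$ — maximum intensity inside $\Omega_t$ over the maximum outside it
  (within the head). $\gamma > 1$ classifies the localization as correct.
  No guard band is excluded around the target; a guard band would only
  inflate $\gamma$.
* $Q$ — mean intensity inside $\Omega_t$ over the mean outside.
* $\delta$ — distance from the true target center to the argmax cell center.
  Sub-cell peak interpolation is omitted; on the 0.5 mm grid the
  discretization floor (half cell diagonal, 0.35 mm) is below the errors of
  interest. Ties break deterministically by lowest cell index (row, then
  column).

Both ratios are invariant to global intensity scaling, so they are identical
on raw and normalized images. A target region owning the sole nonzero cell
yields $\gamma = +\infty$ by convention.

# The synthetic phantom and forward model

The phantom is a 2D elliptical head section (default semi-axes 90 × 110 mm,
boundary sampled at 360 vertices): concentric shells of skin (2 mm), fat
(1 mm), skull (4 mm) and CSF (3 mm) — a 10 mm outer shell, matching the
skin-plus-skull "neutral region" where hemorrhage does not occur — around a
gray-matter shell (15 mm) and white-matter core, optionally with a
rectangular blood target (default 20 × 20 mm). Tissue permittivities
interpolate linearly between band-edge values; skin (50–44), CSF (69–66.2),
dura (44–41.9) and muscle (55–52.6) use published head-tissue ranges, the
rest are standard literature-style fixture values. Conductivities are
fixture constants chosen at the *low* end of reported ranges: a single-bounce
Born model has no multiple-scattering gain, so full literature conductivity
would extinguish deep-target echoes that the real system demonstrably
detects; the low-end values keep the synthetic study in the same
detectability regime.

Each antenna receives
$S_n(f) = \sum_e A_e\, P(f)\, e^{-j 4 \pi f \tau_e}$, with $P(f)$ the
excitation pulse spectrum and three echo classes:

* **skin echo** at the straight-ray air delay toward the head center, with
  Fresnel amplitude $(1 - \sqrt{\varepsilon_{\mathrm{skin}}})/(1 +
  \sqrt{\varepsilon_{\mathrm{skin}}})$ and a per-position skin-thickness
  jitter (seeded Gaussian, default sd 0.3 mm for healthy-head studies —
  sub-millimetre anatomical variation);
* **target echo** at the physical first-arrival: the minimum over
  line-of-sight entry points of the free-space leg plus a straight interior
  leg traced through the true layers (`fermat_layered_delay()`). This is the
  stationary-phase, geometrical-optics arrival; a straight
  antenna-to-target ray overestimates oblique-channel delays by up to a
  nanosecond and corresponds to no physical wavefront. Amplitude combines
  the blood-background Fresnel contrast, inverse-distance decay (exponent 1,
  cylindrical spreading in 2D), and round-trip tissue absorption accumulated
  along the path — the penetration loss that makes deep targets
  progressively harder to detect;
* optional seeded **clutter scatterers**.

All random draws happen up front regardless of which components are enabled,
so datasets superpose exactly (no-target + target-only = with-target) and are
bit-reproducible under a fixed seed.

The forward model deliberately differs from the imaging model — true layered
permittivities and exact refraction point versus the fitted
$\varepsilon_{\mathrm{eff}}(d)$ and its discrete entry search — so
model-mismatch experiments (fixed-$\varepsilon$ versus depth-dependent) are
meaningful. What the generator does *not* emulate: multiple scattering,
dispersion within an echo beyond the pulse envelope, antenna patterns and
polarization, 3D out-of-plane propagation, and measurement drift. Passing
tests therefore demonstrate the correctness and internal consistency of the
processing chain under controlled conditions, not clinical performance.

**Excitation pulse.** A Gaussian-modulated sinusoid at $f_c = 1.6$ GHz with
total width $\tau = 1.7$ ns. The width convention is $\tau = 7\sigma$
(envelope below 0.3% of peak outside $\tau$); with it the −10 dB spectral
extent covers the full operating band, which is the stated purpose of the
pulse, whereas a tighter $6\sigma$ convention leaves the upper band edge at
−12 dB (the carrier sits below the 1.65 GHz arithmetic band center).

**Scan profile.** `make_parabolic_scan(r1, r2, n)` places $n$ equiangular
positions whose radius interpolates parabolically within each quadrant from
$r_1$ on the x-axis to $r_2$ on the y-axis — the two radii of the profile —
approximating a constant standoff around an elliptical head; $r_1 = r_2$
degenerates to a circle. Defaults in the experiments ($r_1 = 105$,
$r_2 = 125$, $N = 32$, step 11.25°) keep a ~15 mm antenna–skin gap.

**Noise.** Complex white Gaussian noise scaled against the *total dataset*
signal power (one SNR per experiment, matching how a single acquisition is
characterized), seeded and restoring the caller's RNG state.

# Safety calculators

Incident power density is the spherical-spreading estimate
$S = P_{tx} G / (4 \pi r^2)$ with $G$ a linear gain factor: at the reference
operating point (1 mW, $G = 3.5$, 15 mm) this gives 1.24 W/m² = 0.124
mW/cm², an order of magnitude under the 1 mW/cm² exposure limit. (Reading
3.5 as dBi, i.e. $G = 2.24$, gives 0.79 W/m² and does not reproduce the
reference value; the helper `dbi_to_linear()` exists so both readings can be
computed explicitly.)

Skin heating uses the half-space solution for power absorbed with an
exponential depth profile over the skin depth $\delta$ and an insulated
surface:

$$ \Delta T(t) = \frac{S\, T_{tr}\, \delta}{k} \left[
   \tfrac{2}{\sqrt{\pi}} \sqrt{t/\tau_{th}} - 1 +
   e^{t/\tau_{th}} \operatorname{erfc}\!\left(\sqrt{t/\tau_{th}}\right)
   \right], $$

where $T_{tr} = 1 - |\Gamma|^2$ is the surface transmission from the skin's
complex permittivity, $\delta$ the power penetration depth from the same,
$k$ the thermal conductivity, and $\tau_{th} = \delta^2 I / k^2$ the thermal
time constant — the time for the thermal wave to diffuse one skin depth
($I = k \rho c$ is the thermal inertia). The solution is zero at $t = 0$,
rises linearly in the adiabatic regime
($\Delta T \approx S T_{tr} t\, k / (I \delta)$), and follows the
$\sqrt{t}$ surface-flux law $2 S T_{tr} \sqrt{t / (\pi I)}$ at long times;
both asymptotes are verified against series oracles in the tests. The scaled
form $e^{x^2}\mathrm{erfc}(x)$ is evaluated via `erfcx` (with an asymptotic
series beyond its overflow range). Higher frequencies raise the skin's
conductivity, shrink $\delta$, concentrate the absorbed power near the
surface and heat it faster — the model reproduces that ordering. Thermal
defaults ($k = 0.37$ W/m/K, $I = 1.39 \times 10^6$ W²s·m⁻⁴·K⁻²,
skin conductivity 0.9–1.8 S/m across the band) are standard skin-tissue
fixture values, all configurable. A frequency sweep spends only a fraction
of the scan at each frequency, so the effective rise is the
dwell-fraction-weighted superposition of per-frequency rises (the model is
linear in absorbed power); a 60-minute full-band sweep at 1 mW stays below
0.02 °C.

```{r thermal, fig.width = 6, fig.height = 4}
freqs <- seq(0.75e9, 2.55e9, length.out = 7)
curves <- band_sweep_temperature(freqs, rep(1 / 7, 7))
plot(curves$t_s / 60, curves$dT_C_effective * 1e3, type = "l",
     xlab = "time (min)", ylab = "effective skin temperature rise (mK)")
```

# Numerical choices and problem sizes

* Grid cells follow the half-open convention $[x, x + \mathrm{cell})$ with
  centers at half-cell offsets; the head mask uses the even-odd rule with
  boundary-touching centers counted inside.
* Zero-padding factor 4 in the time-domain conversion (smooth peak
  interpolation); window default none, Hann optional.
* Antenna delay $\tau_a$ defaults to 0 for synthetic data and is
  configurable for measured data.
* Travel-time tables are keyed by a content hash of geometry, boundary, grid
  and model, so repeated reconstructions over the same scene reuse one
  table.
* Degenerate inputs are flagged, not fatal: all-zero channels skip
  normalization, an all-zero image skips max-normalization and reports
  `normalized = FALSE`, out-of-support delays contribute zero to the sum.
* The test and acceptance experiments use a 1 mm grid for single-target
  localization and a 2 mm grid for the 24-position map, SNR and healthy-head
  ensembles, with $N = 32$ antennas and the full 284-sample sweep; these
  sizes resolve the 0.7–2 mm localization errors under study while keeping
  an ensemble of ~70 reconstructions comfortably on one CPU. The impulse
  consistency check runs on the 0.5 mm default grid over a reduced extent.

# Known limitations

The phantom is 2D and piecewise-elliptical; layer interfaces are offset
ellipses rather than true anatomy, and "white matter" stands for the whole
deep-brain composite. The imaging model ignores intra-head refraction
(single straight interior leg) and frequency dependence of
$\varepsilon_{\mathrm{eff}}$ (one band-wide model). The Born forward model
cannot produce shadowing, multiple reflections between skull and target, or
target-shape signatures — target extent enters only through the scoring
region, not the echo. Healthy-head statistics (skin-shell confinement)
emulate the qualitative behavior of volunteer scans, not their population
statistics.
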