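---
title: "Multi-LED wavelength-modulated SPR imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-LED wavelength-modulated SPR imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsprsim)
```

`wsprsim` simulates and analyzes a wavelength-modulated surface plasmon
resonance imaging (WSPRi) instrument built from five near-infrared LEDs
(730, 740, 756, 777, 805 nm) instead of a tunable filter. The package has
four layers: a Kretschmann-configuration reflectance forward model, an
adaptive second-order fitting (ASF) resonance-wavelength tracker, a
calibration/figure-of-merit layer, and a synthetic image-stack generator
that stands in for the instrument's camera.

## Optical forward model

The sensing stack is an ordered list of media — incidence prism, optional
chromium adhesion layer, gold film, analyte — each with its own
dispersion model (constant index, tabulated $(\lambda, n, k)$ with linear
interpolation and no extrapolation, or an analytic Drude–Lorentz form).
The p-polarized reflectance $R_p = |r_p|^2$ is computed by the standard
characteristic-matrix (Abelès) method. Conventions: time dependence
$e^{-i\omega t}$, so passive media have $\mathrm{Im}\,\varepsilon \ge 0$
and the decaying-wave branch is $\mathrm{Im}\,k_z \ge 0$; angles are
degrees at the user surface and radians internally; wavelengths are nm
everywhere. The test suite checks the matrix method against an
independently coded recursive Fresnel cascade to $10^{-10}$ absolute on
1000 randomized stacks, along with the passive energy bound, the
two-medium closed form, and total internal reflection.

Surface plasmons are excited where the in-plane wave vector
$k_x = (2\pi/\lambda)\, n_p \sin\theta$ matches the real part of the
surface-plasmon propagation constant
$k_{SP} = (2\pi/\lambda)\sqrt{\varepsilon_m \varepsilon_d /
(\varepsilon_m + \varepsilon_d)}$, with $\varepsilon_m$ the metal and
$\varepsilon_d$ the analyte permittivity. `resonance_residual()` exposes
$|\mathrm{Re}\,k_{SP} - k_x|$ as a diagnostic; the *resonance wavelength*
(RW) itself is defined operationally as the reflectance minimum, located
by `true_rw()` on a dense grid (default 0.01 nm) with three-point
parabolic refinement, ties broken toward the smaller wavelength, and a
boundary minimum treated as an error.

### Material models and the initialization angle

The two quantities the instrument description leaves open are the gold
optical constants and, consequently, where the dip sits at a given
geometry. The package ships a tabulated Johnson–Christy-style gold table
(`gold_table()`, the default), an analytic Rakić-style Drude–Lorentz
alternative (`gold_drude_lorentz()`), and a synthetic chromium table
(`chromium_table()`; a 2 nm adhesion layer shifts the dip by well under a
nanometre). Every simulation records which model produced it.

At a fixed prism index of 1.785 and 51.2°, tabulated gold places the
water dip near 784 nm — outside band 1. The instrument's own operating
procedure resolves this: the incidence angle is adjusted until the RW
sits inside band 1 before an experiment starts. `solve_init_angle()`
reproduces that procedure numerically, solving for the angle at which
the dense-grid dip of the water-loaded stack sits at 735 nm (the middle
of the band-1 selection range). For the default bare gold chip this
gives ≈ 51.80°, and the validation sweep (`simulate_sweep()`) uses it.
The bare prism/Au/analyte chip (`gold_chip_stack()`) is used for that
sweep because the simulation being replicated describes a gold-coated
chip; the full default stack keeps the chromium layer.

## The adaptive second-order fitting tracker

Within roughly ±17 nm of the dip the reflectance curve is close to
quadratic, so three samples suffice to reconstruct it locally. The ASF
loop is:

1. **Initialization** (`fullscan_init()`): all five LEDs are sampled and
   a degree-4 polynomial is interpolated exactly through the five points
   (fits are exact interpolations throughout — point counts equal
   parameter counts; all fits are performed in wavelength coordinates
   centered on the sample mean for conditioning). The quartic's interior
   minimum on 730–805 nm (derivative-cubic roots with positive second
   derivative; ties by lower fitted value, then smaller wavelength)
   seeds the tracker; with no interior minimum the lower-valued endpoint
   is used and flagged clamped.
2. **Three-point fit** (`quadratic_rw()`): the active band's LED triple
   is sampled and a parabola interpolated. If it opens upward with its
   vertex inside the triple's span, the vertex is the RW estimate.
   Otherwise the estimate is *clamped* to the span endpoint with lower
   fitted intensity and flagged; collinear samples clamp toward the
   lower measured intensity. Clamping is what makes band switching
   mechanical rather than heuristic.
3. **Band switching** (`asf_step()`): bands 1–3 use LEDs 1–3, 2–4, 3–5
   with fit ranges 730–756, 740–777, 756–805 nm. The default selection
   partition is `[730, 740)`, `[740, 777)`, `[777, 805]`: an estimate at
   or above a threshold activates the next triple, and an estimate
   clamped at a band's *lower* fit edge steps one band down (the mirror
   rule, needed for rinse phases that blue-shift the dip — a bare
   threshold lookup would hold band 3 at exactly 756 nm forever).
4. **Convergence** (`asf_converge()`): steps repeat until the band is
   stable, at most three fits. A dip sitting in band 3 reached from band
   1 therefore produces the stepwise estimates 756 (clamp), 777 (clamp),
   then the interior vertex — the canonical red-shift hand-off. If the
   final fit is clamped but an earlier fit in the cycle produced an
   unclamped vertex, the unclamped value is reported: clamps drive
   switching and are not the best available reading. A dip exactly at a
   boundary can propose a previously visited band; the loop stops there
   and stays in the band that produced the last fit, so a convergence
   cycle never exceeds two switches.

Two threshold conventions appear in descriptions of this class of
instrument: switching to the third triple at 756 nm, or at 777 nm with
740–777 nm all belonging to band 2. We measured both on the replication
configuration over a 1-nm grid of dip positions: the 777 convention cuts
the worst trigger-zone error from about 5 nm to about 0.3 nm for dips
just above 756 nm, is never worse elsewhere, and is the only convention
that produces the three-step 756 → 777 → 783 hand-off. It is therefore
the default; `band_configs(thresholds_nm = c(740, 756))` restores the
early-switch variant.

### What accuracy to expect

The three-point parabola vertex of a genuine Fresnel dip carries a
systematic bias that grows with the triple span relative to the dip
width and with the dip's asymmetry (the red flank recovers more slowly
than the blue flank rises). Under the replication configuration the test
suite asserts the measured envelope: within 4.5 nm of the dense-grid
truth for dips in 732–790 nm, and a clamped 805 nm reading for dips
within ~10 nm of the red window edge. The *sensitivity* — the slope of
RW against refractive index — is far better behaved than any single
reading, because the bias varies slowly along the sweep: the ASF slope
agrees with the dense-grid slope to a few percent. Sub-nanometre
per-point agreement would require a dip substantially more parabolic
over 26–49 nm spans than Fresnel theory with standard gold constants
produces; tolerances tighter than this envelope should be read with that
in mind.

## Acquisition model

`led_bank()` models the five channels; sampling is a delta function at
each center wavelength by default (the tracker mathematics uses centers
only), with an optional Gaussian line profile (`fwhm_nm`) averaged by
quadrature over ±5σ for realism studies. `cycle_time_ms()` implements
the timing budget: each wavelength costs the LED response time (2 ms)
plus the camera exposure (33 ms), so a three-wavelength tracking cycle
takes 105 ms and a five-wavelength full scan 175 ms. Noise enters at
sampling as additive zero-mean Gaussian intensity noise under an
explicit seed, so every stochastic test is reproducible.

## Calibration and figures of merit

`linear_calibration()` is an ordinary least-squares line through
(refractive index or concentration, RW shift), with $r^2$ the squared
Pearson correlation. From it:

* refractive-index resolution `rir()` $= \Delta\sigma_{SD}/S$, baseline
  noise RMS over sensitivity, in RIU (`baseline_rms()` computes the RMS
  about the window mean on a flat baseline segment — mean removal only);
* limit of detection `lod()` $= 3\delta_N/S$, with $\delta_N$ the blank
  channel's standard deviation;
* `net_shift()`, the post- minus pre-reaction window mean;
* `dynamic_range()`, the width of the analyte-index interval over which
  the noise-free tracker error stays within a tolerance while the dip
  remains inside the LED span; at a tolerance the tracker meets across
  the window, range × sensitivity ≈ usable wavelength span;
* `nacl_to_delta_ri()`, the linear NaCl conversion anchored at
  13% ↔ 0.0241 RIU (≈ 1.854 × 10⁻³ RIU per percent, consistent with
  refractometry tables to about two significant figures).

## Synthetic image stacks

`render_frames()` emulates the camera: for each frame time and LED,
pixels inside each flow-cell channel ROI take the stack reflectance at
that channel's instantaneous analyte index, background pixels a fixed
non-resonant level (0.85), plus per-pixel Gaussian reflectance noise,
clamped to [0, 1] and quantized to 16 bits with round-half-even.
Refractive-index time courses are staircases (`course_staircase()`, for
salt calibrations), 1:1 Langmuir binding (`course_langmuir()`, with
association $\Delta n(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})$,
$R_{eq} = R_{max}C/(C + K_D)$, and exponential dissociation, continuous
at the switch), or constants (blank channels). Frame stacks round-trip
as one multi-page 16-bit TIFF per LED plus a YAML sidecar, and
`extract_roi_series()` reduces them to per-ROI, per-LED mean-intensity
traces for `asf_track()`.

The default per-pixel noise (sd 2 × 10⁻³ reflectance units) was fixed
once so that tracking a default-geometry channel ROI (≈ 570 pixels
averaged) yields a baseline RMS in the 0.010–0.014 nm regime typical of
this instrument class; the acceptance suite asserts that regime. The
generator deliberately omits optical blur, fixed-pattern noise, prism
image distortion and mass-transport-limited kinetics, so passing tests
demonstrate correct signal processing on idealized frames, not
robustness to those real-world effects. A noisy staircase is judged
against the *noise-free run of the same pipeline*: over a full staircase
the optics' own nonlinearity (sensitivity grows toward the red) exceeds
the noise floor, so comparing against a global linear fit of the truth
would conflate model nonlinearity with noise.

## Problem sizes

The shipped tests and the acceptance script use: 0.01 nm dense grids for
truth searches (0.001 nm in oracle cross-checks), 1000 randomized stacks
for the reflectance oracle, a refractive-index sweep of 8 points
(1.333 to 1.347 in 0.002 steps, the span the 75 nm window holds at this
sensitivity), staircases of up to 8 levels × 10 frames on 48 × 32-pixel
two-channel frames, and a 96 × 64 six-channel demo scenario. These sizes
were chosen so a full run completes in minutes on one core while every
quantity is still computed from scratch.

## Known limitations

* Per-reading tracker accuracy is bias-limited as described above; the
  0.5 nm regime claimed for instruments of this class is reachable only
  with broader (more parabolic) dips than standard gold constants give.
* The NaCl→RIU conversion is linear by construction; real salt curves
  bend slightly at high concentration.
* `dynamic_range()` reports the widest contiguous in-tolerance interval,
  which depends on the chosen tolerance; with a sub-nanometre tolerance
  the biased trigger-zone readings fragment the interval.
* s-polarization, angular interrogation, phase modulation, rough or
  graded interfaces, and kinetic-constant estimation from real data are
  out of scope.
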