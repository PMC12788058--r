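# wsprsim

Simulation and signal processing for **multi-LED wavelength-modulated
surface plasmon resonance imaging (WSPRi)**.

SPR biosensors read out binding events as a shift of the resonance
wavelength (RW) — the minimum of the p-polarized reflectance of a
prism/gold/analyte stack in the Kretschmann configuration. Wavelength
interrogation usually needs a tunable filter; a cheaper, faster
alternative replaces it with five fixed near-infrared LEDs (730, 740,
756, 777, 805 nm) and reconstructs the RW from as few as three samples
per cycle with an **adaptive second-order fitting (ASF)** algorithm:

* a one-off five-point quartic full scan locates the dip coarsely;
* thereafter an adaptively chosen LED triple is sampled and a parabola
  interpolated exactly through the three points — its vertex is the RW;
* when the vertex leaves the active triple's span, the estimate clamps
  to the span edge and the tracker switches to the neighboring triple,
  so a dip anywhere in 730–805 nm is reached within three fits.

This package is for instrument builders and algorithm developers who
want the whole chain — Fresnel multilayer optics, LED-bank acquisition
with its 105 ms three-wavelength cycle budget, the ASF tracker,
calibration analytics (sensitivity in nm/RIU, refractive-index
resolution `RIR = RMS/S`, limit of detection `LOD = 3δ_N/S`, dynamic
range), and a synthetic six-channel flow-cell imaging generator — as
reproducible, testable code with no hardware attached.

## Worked example

Simulate the algorithm-validation experiment: a bare gold chip
(prism n = 1.785, 48 nm Au, tabulated gold constants), the incidence
angle solved so the water dip starts mid-band-1, then the analyte index
stepped by 0.002 RIU while both the dense-grid ("true") RW and the
ASF-tracked RW are recorded.

```r
library(wsprsim)

stack <- gold_chip_stack(analyte_n = 1.333)   # prism / 48 nm Au / water
angle <- solve_init_angle(stack)              # 51.8022 deg
sweep <- simulate_sweep(stack, angle_deg = angle)
sweep
#>      ri true_rw_nm asf_rw_nm band_id clamped
#> 1 1.333    735.000   735.110       1   FALSE
#> 2 1.335    743.302   743.730       1   FALSE
#> 3 1.337    751.961   753.737       2   FALSE
#> 4 1.339    761.189   761.732       2   FALSE
#> 5 1.341    770.897   773.922       2   FALSE
#> 6 1.343    781.067   782.350       3   FALSE
#> 7 1.345    791.737   793.011       3   FALSE
#> 8 1.347    802.952   805.000       3    TRUE

sens <- sweep_sensitivity(sweep)
#> true sensitivity: 4850.4 nm/RIU
#> ASF sensitivity:  4962.3 nm/RIU
#> relative error:   2.31%

cal <- linear_calibration(sweep$ri, sweep$asf_rw_nm)
rir(cal, 0.014)      # resolution at a 0.014 nm baseline RMS
#> 2.82e-06 RIU
cycle_time_ms(3)
#> 105 ms
```

Reading the table: the dip red-shifts by ~9.7 nm per 0.002 RIU step and
the tracker follows it across all three bands, clamping at 805 nm once
the dip reaches the window edge. The regression of RW on refractive
index gives the instrument sensitivity; dividing a baseline noise RMS by
it gives the smallest resolvable index change (~3 × 10⁻⁶ RIU here).

A full synthetic experiment — six-channel NaCl staircase frames,
tracking, and a metrics report — can be driven from the shell:

```sh
inst/cli/wsprsim synth  --scenario inst/extdata/scenario_staircase.yaml --out frames/
inst/cli/wsprsim track  --frames frames/ --scenario inst/extdata/scenario_staircase.yaml --out sensorgram.tsv
inst/cli/wsprsim report --sensorgram sensorgram.tsv --calibration my_calibration.yaml --out report.yaml
```

See `vignettes/wsprsim-methods.Rmd` for the optical model, the tracker's
clamping and band-switching rules, the accuracy envelope to expect from
three-point parabola fits on real Fresnel dips, and what the synthetic
generator does and does not emulate.

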