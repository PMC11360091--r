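# ssaxs

Data reduction for **spectral small-angle X-ray scattering (sSAXS)**: the
analysis of elastic scattering collected simultaneously in angle- and
energy-dispersive mode on a 2D spectroscopic photon-counting detector
(HEXITEC-class CdTe sensors and similar), under a polychromatic beam.

It is written for experimentalists who have raw 3D detector data —
per-pixel photon-energy histograms, i.e. a `(energy bin × row × column)`
count array — and need, per energy window of interest:

* a **1D scattering pattern**: counts histogrammed over momentum transfer
  *q*, and
* a **2D detector image**: counts per pixel,

plus, for raster-scanned samples, a **2D spatially resolved scattering
map** in which every scan position is scored by the area under the peak
(AUP) in a chosen q-range.

## The core relations

Every detector cell `(k, i, j)` maps to a momentum transfer

```
q = 4π E sin(θ) / hc ,        θ = 2θ / 2,   hc = 1.24 keV·nm
```

where `E` is the energy-bin center and `2θ = atan(r / SDD)` the pixel's
scattering angle (`r` = in-plane distance from the transmitted-beam
center, `SDD` = sample-to-detector distance). Counts are accumulated into
half-open q bins; energy windows are half-open subdivisions of the
analysis range, so windowed patterns tile the full-range pattern exactly.
Bragg peaks relate to lattice spacings by `q = 2π/d` — the d-spacings of
caffeine, the package's validation material, put its peaks at 8.4 and
18.6 nm⁻¹. Background measurements are subtracted frame-wise, unscaled,
with negative differences retained.

A seeded forward simulator (`simulate_frame()`, `simulate_scan()`)
generates frames containing Debye–Scherrer rings with Gaussian q-profiles
under a tabulated spectrum with Poisson noise; it provides the ground
truth for the package's validation and for end-to-end pipeline tests.

## Worked example

Simulate a caffeine-like two-ring powder measurement on the reference
geometry (SDD 250 mm, 80 × 80 pixels of 0.25 mm, beam center just off one
corner), then reduce it over three 5 keV windows:

```r
library(ssaxs)

geom  <- reference_geometry()
axis  <- energy_axis(200, 1, 0)               # 200 bins of 1 keV
spec  <- flat_spectrum(30, 45, axis)
rings <- list(ring_spec(8.4, 0.15, 20000),    # q_peak, sigma_q, intensity
              ring_spec(18.6, 0.15, 10000))
frame <- simulate_frame(geom, axis, spec, rings,
                        background_rate = 0.005, seed = 7)
frame
#> <detector_frame> 200 energy bins x 80 x 80 pixels, raw, total 36485 counts

res <- reduce_frame(frame, geom, energy_window_spec(30, 45, 1, 5))
for (p in res$patterns) {
  qc <- pattern_q_centers(p)
  cat(sprintf("window [%g, %g) keV: argmax at q = %.2f nm^-1, AUP(7-9) = %g\n",
              p$window_label[1], p$window_label[2],
              qc[which.max(p$counts)], area_under_peak(p, 7, 9)))
}
#> window [30, 35) keV: argmax at q = 8.35 nm^-1, AUP(7-9) = 8641
#> window [35, 40) keV: argmax at q = 8.45 nm^-1, AUP(7-9) = 6471
#> window [40, 45) keV: argmax at q = 18.55 nm^-1, AUP(7-9) = 4937
```

Both injected rings are recovered at their q positions (within one
0.1 nm⁻¹ bin). The windowed view shows the physics the windowing exists
for: higher-energy windows reach higher q, so the 18.6 nm⁻¹ ring only
dominates the 40–45 keV window, while the AUP over 7–9 nm⁻¹ tracks the
first peak. `export_pattern()` / `export_map()` write the CSV outputs;
`load_scan_folder()` + `build_scan_map()` produce AUP maps from a folder
of per-position measurements.

## Command line

The same pipeline is scriptable via the installed `exec/ssaxs` script
(or `ssaxs_main()` from R):

```sh
ssaxs simulate --config run.yaml --out-prefix sim
ssaxs reduce --frame sim.bin --sdd-mm 250 --beam-center=-2,-2 \
      --pixel-pitch-mm 0.25 --n-rows 80 --n-cols 80 \
      --bin-start 30 --bin-end 45 --bin-width 5 --energy-window 5 \
      --out-prefix caffeine
ssaxs map --scan-dir scan/ --rows 2 --cols 2 --aup-min 7 --aup-max 9 ...
```

Modes: `reduce | map | simulate | simulate-scan`. All parameters can live
in a YAML config (`--config`); flags override it. Every run writes
`<out-prefix>.log` echoing the fully resolved parameters, and identical
configs (and seeds) produce byte-identical outputs.

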