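---
title: "Spectral SAXS data reduction: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral SAXS data reduction: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssaxs)
```

## The measurement this package reduces

Spectral small-angle X-ray scattering (sSAXS) records elastic scattering
from a sample irradiated by a polychromatic pencil beam on a 2D
spectroscopic photon-counting detector (a HEXITEC-class CdTe sensor is the
canonical example: 80 × 80 pixels of 0.25 mm pitch, each pixel holding a
200-bin, 1 keV histogram of photon energies). The raw measurement is
therefore a 3D count array indexed by (energy bin, pixel row, pixel
column). Because every pixel sees a known scattering angle and every count
carries an energy, each detector cell maps to a momentum transfer

$$ q = \frac{4\pi E \sin\theta}{hc}, $$

where $E$ is the photon energy, $2\theta$ the full scattering angle of the
pixel, and $hc = 1.24$ keV nm by default (a `physical_constants()` override
accepts the CODATA value). The $\theta$ in the sine is *half* the
scattering angle — the crystallographic convention. That choice is forced
by the companion identity $q = 2\pi/d$: with the full angle in the sine,
the known caffeine d-spacings (7.53–7.40 Å and 3.37–3.30 Å) would not land
at their observed peak positions of 8.4 and 18.6 nm⁻¹.

The package reduces such frames to (1) energy-windowed 1D scattering
patterns — histograms of counts over q bins — and (2) 2D spatially
resolved scattering maps, where each raster-scan position is summarized by
the area under the peak (AUP) in a chosen q-range.

## Geometric conventions

* Pixel (i, j), 1-based, occupies $[i-1, i) \times [j-1, j)$ in pitch
  units; its center is $(i-\tfrac12, j-\tfrac12)$. The beam center is
  expressed in the same fractional coordinates and may lie off the sensor,
  as it does when a beam stop sits near a corner.
* The scattering angle of a pixel is $2\theta = \arctan(r/\mathrm{SDD})$
  with $r$ the pitch-scaled distance from the beam center to the pixel
  center. The detector is treated as flat and each pixel is represented by
  its center; solid-angle and obliquity variations across a pixel are
  neglected, consistent with per-pixel angle treatment at angles below
  ~10°.
* The representative energy of a detector bin is its center. For a 1 keV
  bin this is the unbiased choice and the error it induces in q is far
  below the q-bin width everywhere in the geometry range this tool
  targets.
* All intervals are half-open $[\mathrm{lo}, \mathrm{hi})$: energy
  windows, energy-range selection, and q bins. Half-open intervals make
  window partitions and q-histograms tile exactly, which is what turns
  "sum of windowed patterns equals the full-range pattern" and "no count
  is ever double-binned" into exact identities rather than approximations
  — both are asserted exactly in the test suite.

## Tunable parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `sdd_mm` | mm | — (user) | sample-to-detector distance; 220–300 typical |
| `beam_center` | pitch units | — (user) | transmitted-beam position; required input, not fitted |
| `pixel_pitch_mm` | mm | — (user) | pixel pitch (0.25 for HEXITEC-class) |
| `bin_start/bin_end` | keV | 30 / 50 | analysis energy range $[\mathrm{start}, \mathrm{end})$ |
| `window_width_keV` | keV | 20 | energy-window width; must divide the range |
| `bin_width_keV` | keV | 4 | optional energy re-binning before reduction; integer multiple of the native width |
| `q_bin` | nm⁻¹ | 0.1 | q-histogram bin width |
| `hc_keV_nm` | keV nm | 1.24 | physical constant in the q relation |

The default q grid runs from 0 to just past the geometric maximum q of the
detector at `bin_end`, in 0.1 nm⁻¹ steps. That width resolves peaks
separated by ~10 nm⁻¹ with two orders of magnitude to spare while keeping
counting noise per bin manageable at typical exposures; it is freely
overridable.

Energy re-binning (`bin_width_keV`) aggregates adjacent native detector
bins *before* reduction. It is exposed because coarser energy points can
be preferable for weak signals; it interacts with nothing else — reduction
is linear, so re-binning only coarsens the energy values used in the q
computation.

## Background subtraction

A background measurement, when supplied, is subtracted frame-wise (3D,
element by element) before any reduction, with no exposure-time scaling:
counts are removed as measured. Exposure metadata is carried through I/O
but deliberately unused, since the subtraction semantics are defined on
raw counts. Negative differences are retained in all numeric outputs —
clamping to zero is purely a display concern. Subtracting in frame space
rather than pattern space keeps the 1D patterns and the 2D detector images
consistent by construction; because reduction is linear the two orders are
numerically identical anyway (asserted bin-by-bin in the tests).

## The scan map

A raster scan is a folder of per-position frames plus user-declared grid
dimensions — the files themselves carry no spatial information. Files are
ordered by natural sort of filename (numeric substrings compared
numerically, so `pos_2` precedes `pos_10`), and placed row-major by
default, frame $f$ → (row $\lfloor (f-1)/\mathrm{cols}\rfloor + 1$, col
$((f-1) \bmod \mathrm{cols}) + 1$); a serpentine option reverses
even-numbered rows for hardware that scans boustrophedon. Each position is
reduced with identical geometry, energy range and q grid, and scored by
the AUP: the plain sum of pattern counts whose bin center lies in the
user's q-range (7–9 nm⁻¹ brackets the first caffeine peak). No baseline is
subtracted under the peak, and the sum — not a trapezoidal integral — is
the natural "area" for histogram data. One shared background frame, if
given, is subtracted at every position. There is no per-window mapping;
the single pre-selected energy range applies to the whole map.

## The synthetic frame generator

Real HEXITEC measurements are not redistributable, so validation rests on
a forward simulator that is itself first-class, tested code. It emulates:

* Debye–Scherrer rings, each a **Gaussian profile in q** with a peak
  position, width `sigma_q`, and an expected total intensity. The profile
  lives in q rather than detector radius deliberately: the injected
  ground truth then sits in the same coordinate the reduction measures,
  so peak-recovery tests compare like with like. Each ring's rate is
  normalized over all reachable detector cells, making its expected total
  count equal its `intensity` parameter exactly.
* A polychromatic source as a table of (energy, weight) pairs, normalized
  internally; a flat spectrum over the analysis range is the default
  since spectral shape is irrelevant to validating the reduction
  arithmetic.
* Poisson counting noise, seeded and reproducible.

The reference fixture geometry is SDD 250 mm, 0.25 mm pitch, 80 × 80
pixels, beam center at (−2, −2) fractional pixels — just off one corner,
emulating a beam-stop arrangement — which keeps both caffeine-like rings
(8.4 and 18.6 nm⁻¹) on-detector across 30–45 keV.

The simulator does **not** model charge sharing, pulse pileup, CdTe
fluorescence escape, Compton or multiple scattering, sample attenuation,
or solid-angle roll-off. Passing tests therefore demonstrate that the
geometry and binning arithmetic is correct and self-consistent, not that
real detector artifacts are handled; those corrections belong upstream of
this tool.

## Numerical choices and degenerate inputs

* Frames are stored as little-endian float64 in C order with a JSON
  sidecar; integer counts are exact in float64 up to $2^{53}$, and the
  sidecar is written at 17 significant digits so axis metadata
  round-trips bit-exactly. Writing is deterministic byte-for-byte.
* q-binning uses `findInterval` semantics: counts with q exactly on a bin
  edge go to the upper bin, q outside the grid is dropped, and masked
  pixels carry `NA` q so they can never contribute.
* A window partition whose range is not a multiple of the window width is
  an error reporting the remainder, not a silent truncation. Inverted
  ranges, empty scan folders, shape mismatches and negative counts in
  files marked raw all fail loudly with both offending values named.
* Ring positions unreachable at a given energy (arcsine argument > 1) are
  an error in `ring_radius`; in the simulator such (ring, energy)
  combinations simply contribute no rate, which is the physically correct
  limit.

## Validation strategy and problem sizes

The test suite checks exact identities (count conservation, window
additivity, background linearity, round-trip I/O) and an independent
oracle: a naive per-cell triple loop over (energy bin, row, column) that
re-derives every q from the scalar operations and bins it by linear
search. The vectorized reduction must agree with it *exactly*, count for
count, across 100 random small frames (10 × 8 × 8) and masked variants.
Statistical properties of the simulator (Poisson totals, convergence of
the empirical mean to the model rate, scan-intensity ratios) are tested
at fixed seeds with explicit sigma-based bands: 10 × 8 × 8 frames at 100
replicates for expectation fidelity, and full 200 × 80 × 80 frames for
count conservation and peak recovery. These sizes exercise every code
path, including the full HEXITEC-shaped array, while the suite stays
fast enough to run routinely.

## Known limitations

* No absolute intensity calibration, flat-field, polarization or
  solid-angle correction; patterns are raw summed counts.
* No transmission/thickness correction — samples with strongly varying
  attenuation need upstream correction before the subtraction semantics
  here are meaningful.
* The beam center is a required user input; the package does not fit it
  from the data.
* Scan maps inherit whatever artifacts the AUP sees — e.g. strong
  scattering at well edges appears as high-AUP rings; no correction is
  attempted.
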