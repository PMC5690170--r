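---
title: "Transmission film QA: model, assumptions and design choices"
author: "rcfqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission film QA: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcfqa)
```

## The measurement problem

In-vivo transmission QA places a radiochromic film on an acrylic tray in
the linac accessory holder, 56.8 cm from the source, and leaves it there
for the whole delivery.  Because the tray rides with the gantry, the beam
is always perpendicular to the film, so the measurement is independent of
gantry angle and works for modulated and rotational techniques.  The
treatment planning system, however, reports its dose on the coronal
central plane of a phantom at 100 cm, with every field forced to gantry
0°.  The package's job is to make the two planes comparable and decide
whether the delivery matched the plan.

The verdict is Pass when, simultaneously,

* the percent dose difference at the normalization point,
  $100\,(D_\mathrm{film}-D_\mathrm{TPS})/D_\mathrm{TPS}$, is strictly
  below 5% in magnitude, and
* the fraction of points passing a 3%/3 mm gamma test (10% low-dose
  threshold) strictly exceeds 95%.

Both inequalities are strict: a delivery sitting exactly at 5% or exactly
at 95% fails.  Verdicts are computed on full-precision values; one-decimal
rounding is applied only for display.

## Calibration: tying tray response to isocenter dose

Calibration films are irradiated on the tray itself with 50, 100, 200,
400 and 600 MU of a 10 cm × 10 cm field and scanned 24 h later at 75 dpi /
12 bits.  Each ROI-mean pixel value is paired not with the dose at the
film, but with the dose the TPS calculates at the phantom center at
100 cm for the same MU.  The fitted curve therefore maps pixel values
directly onto the TPS dose scale, and two systematic factors cancel by
construction because calibration and QA films share the tray geometry:
the tray transmission (0.942 for the 6 MV beam) and the inverse-square
factor between 56.8 cm and 100 cm.  The test suite verifies the
cancellation by regenerating calibration and QA scans at several
transmission values and observing an unchanged recovered dose.

The functional form of the curve is not prescribed, so `build_calibration`
offers three monotone models and records which one was used:

* `rational` (default): $D = a + b/(\mathrm{PV} - c)$, the usual
  saturating dose–response shape; it extrapolates sanely and its pole is
  required to lie outside the pixel-value domain, otherwise the fit is
  refused as non-monotone.
* `monotone_spline`: a Hyman-filtered cubic interpolant — assumption-free,
  zero residuals, no extrapolation ability.
* `netod_poly`: a quadratic in net optical density
  $\log_{10}(\mathrm{PV}_0/\mathrm{PV})$, for workflows that prefer OD.

The digitizer's polarity (whether more dose means lower or higher pixel
values) is never assumed; any strictly monotone direction is accepted.
The unexposed-film pixel value may be supplied as a zero-dose anchor; the
five MU levels alone leave the low-dose end of the domain at 42 cGy, and
without the anchor the film background cannot be converted.  Pixels
beyond the *low-dose* (background) edge of the domain are clamped freely
and logged — they carry no dose information.  Pixels beyond the
*high-dose* edge would silently truncate real dose, so more than 1% of
them is an error.

## Geometry: divergence projection, registration, smoothing, resampling

`project_to_isocenter` rescales the film plane about the beam central axis
by the SDD ratio $100/56.8 \approx 1.7606$, leaving dose values untouched.
Carrying the values unchanged is the methodology's validated assumption:
Monte Carlo transport through this tray geometry found the distributions
at the two distances to agree at the ≥ 99.75% gamma level, so any
disagreement found downstream reflects the delivery, not beam divergence.

`coregister` automates the manual two-profile alignment used in film QA:
the central horizontal and vertical profiles of both planes are
cross-correlated, the per-axis peak is refined by parabolic interpolation,
and the combined translation is returned.  Scale is fixed (divergence is
already handled) and rotation is off by default, matching the practice of
aligning on two perpendicular profiles; a `manual_shift` bypasses the
search entirely.  A correlation peak on the search-window boundary is an
error; flat, featureless planes return zero shift flagged
`low_confidence`.

The full chain in `qa_analyze` runs: calibrate → project → estimate the
registration (on least-processed data) → Gaussian-smooth the film on its
native fine grid → resample both planes onto the comparison grid, the
film through the registration transform.  Smoothing before the film
leaves its ~0.6 mm (projected) pixel grid matters: once resampled to the
comparison grid, a 1 mm kernel can no longer average out pixel noise.
The kernel is separable, unit-sum, with reflective boundaries; the
default width of 1 mm is a package choice (the kernel used in the
original in-house analysis is unstated) and is exposed as `--sigma-mm`.
Smoothing only the measured side introduces a small bias where the dose
surface is curved (about $\tfrac{\sigma^2}{2}\nabla^2 D$); at 1 mm this
stays well below the 5% criterion and is absent on noiseless data when
`sigma = 0`.

Resampling is bilinear on the same physical extent, by default to 0.5 mm
— the "2 mm to 0.5 mm" interpolation of the original workflow, which
quadruples the per-axis point density ($4N-3$ nodes from $N$).  Original
nodes that coincide with new nodes keep their values exactly, and affine
surfaces are reproduced to machine precision.

## Gamma analysis

For each reference (TPS) point $r$ above the threshold, the gamma index is

$$\gamma(r) = \min_{r'} \sqrt{\frac{|r-r'|^2}{\Delta d^2} +
\frac{(D_e(r') - D_r(r))^2}{\delta^2}},$$

with $\Delta d$ the 3 mm distance-to-agreement, $\delta$ the 3% dose
criterion expressed in absolute dose via the normalization dose (global
maximum of the reference plane by default, or the dose at a named point),
and $D_e$ the evaluated plane interpolated on a sub-grid with step at
most $\Delta d/10$.  Numerical choices:

* the sub-grid is aligned with the reference nodes, so reference points
  sit exactly on it; halving the step must not move the pass rate by more
  than 0.1% (a convergence test in the suite enforces this);
* the spatial search is capped at $3\Delta d$: beyond it the distance
  term alone exceeds 3, which cannot change $\gamma \le 1$ status;
* the fast search (compiled, offsets sorted by distance with early exit)
  is verified against `gamma_oracle`, a pure-R exhaustive scan with no
  pruning, to within $10^{-6}$ over 100 seeded fixtures;
* points below threshold, and points where the evaluated plane has no
  data anywhere in the search radius, carry an `NA` sentinel and are
  excluded from the pass-rate denominator — never counted as zeros.

### Relative gamma in the pipeline

`qa_analyze` rescales the film plane to the TPS dose at the normalization
point before the gamma test (option `gamma_relative`, on by default).
This makes the two criteria orthogonal: the gamma test judges the *shape*
of the distribution, the point-dose criterion its *absolute level*.  The
choice reproduces the characteristic commissioning signature of a uniform
monitor-unit deficit — gamma pass rates above 95% alongside point-dose
differences of −10% to −37% — which an absolute gamma would conflate into
a second failed criterion.  A removed field, by contrast, distorts the
shape and collapses the gamma rate regardless of renormalization.  Pass
`--absolute-gamma` (or `gamma_relative = FALSE`) for a strictly absolute
comparison.

## What the synthetic module emulates — and what it does not

`make_square_field` and `make_imrt_plane` build error-function-edged
fields (50% isodose exactly at the nominal edge, 3 mm penumbra by
default) on 2 mm grids at 100 cm.  `simulate_film_scan` demagnifies a
plan to 56.8 cm, applies an optional placement misalignment and the tray
transmission, maps dose to pixels through a strictly monotone film
characteristic whose inverse is exactly the rational calibration form,
adds seeded Gaussian pixel noise (default 1% of the 12-bit range) and
quantizes.  `synthetic_calibration` runs the same forward model for the
five MU levels at 0.845 cGy/MU, so fitted curves see the same physics as
the QA scans.

The 25-scenario study (`make_error_scenarios`) delivers each of five
fixed modulated plans five ways: faithfully; faithfully again with fresh
noise (a second session); with a small random film misalignment of up to
0.7 mm (a surrogate for delivering at real gantry angles); with a uniform
MU deficit drawn from 10–37%; and with the heaviest field removed.  The
first three are expected to Pass, the last two to Fail, and the suite
requires at least 24 of 25 correct verdicts — the misaligned variant is
legitimately the most fragile, just as real-gantry deliveries are.

Deliberately not modelled: film-grain spatial noise correlation,
scanner lateral-response nonuniformity, film aging and lot variation,
multichannel dosimetry, and any radiation transport — the synthetic plans
are analytic fluence patterns, not linac simulations.  Passing the
synthetic study therefore demonstrates that the *pipeline* detects
absolute-dose and shape errors at the stated magnitudes under realistic
quantization and pixel noise; it does not certify film handling or
scanner behaviour.

## Problem sizes and runtime

The test suite and the acceptance script use 16 cm plans on 2 mm grids
compared at 1 mm (the package default is 0.5 mm, matching the original
workflow); at these sizes one full analysis takes a fraction of a second
and the whole 25-scenario study well under a minute.  The map-vs-oracle
equivalence sweep uses 10 × 10 reference grids, where the exhaustive
oracle is affordable.  These sizes are the package's chosen test
conditions; the pipeline itself handles 30 cm planes at 0.5 mm
comfortably.

## Known limitations

* Registration searches translations only; in-plane rotation must be
  handled by film placement (or a future rotation search).
* The DICOM RT Dose reader covers single-frame, uncompressed, Explicit
  VR little-endian exports only; anything else should be converted to the
  documented `ascii_grid` text format.
* The normalization point defaults to the central axis; plans whose
  reporting point lies elsewhere must pass `--norm-point`.
* Patient positioning is outside the scope of transmission QA by
  construction — the film never sees the patient.
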