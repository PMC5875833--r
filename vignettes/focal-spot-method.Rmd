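---
title: "Measuring the focal-spot offset from portal images: model, numerics, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the focal-spot offset from portal images: model, numerics, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalspot)
```

## 1. The physical model

A linac beam originates from a focal spot on the x-ray target. The machine's
collimator rotation axis — the reference for all field-placement QA — is
defined by the collimating hardware, not by the source. Let `s` be the
lateral displacement of the focal spot from that axis, measured in a plane
through the source perpendicular to the beam.

Consider an aperture centred on the collimator axis at source distance
`d_col`, and an imaging panel at source distance `d_epi`. A ray from the
displaced source through the aperture centre reaches the panel at

```
u_center = -s (d_epi - d_col) / d_col
```

(implemented in `project_center()`). Two properties drive the method:

1. **The projection shrinks with `d_col`.** Collimators closer to the
   source (small `d_col`) magnify the offset more. The jaws
   (`d_jaw_y` = 319 mm, `d_jaw_x` = 406 mm by default) and the MLC
   (`d_mlc` = 490 mm) therefore project the *same* source offset to
   *different* panel positions.
2. **The projection does not rotate with the collimator.** An aperture
   miscalibration (a field centred off the collimator axis) flips sign
   under a 180° collimator rotation; the source offset does not. Averaging
   the field centres measured at collimator 90° and 270° cancels the
   former exactly and keeps the latter.

Subtracting the jaw pair-average centre from the MLC pair-average centre
leaves a separation `D_EPI` on the panel that depends only on `s`:

```
D_EPI = s [ (d_epi - d_jaw)/d_jaw - (d_epi - d_mlc)/d_mlc ]
s     = a · D_EPI,   a = 1 / [ (d_epi - d_jaw)/d_jaw - (d_epi - d_mlc)/d_mlc ]
```

`proportionality_factor()` evaluates `a`. With the default geometry:

```{r factors}
geo <- linac_geometry(d_epi = 1000)
c(X_1000 = proportionality_factor(geo, "X"),
  X_1050 = proportionality_factor(geo, "X", d_epi = 1050),
  Y_1000 = proportionality_factor(geo, "Y"),
  Y_1050 = proportionality_factor(geo, "Y", d_epi = 1050))
```

Because the X and Y jaws sit at different heights, each detector axis has
its own factor; the factor is scale-invariant (multiplying all distances by
a constant leaves it unchanged) and only weakly sensitive to `d_epi`
(a ±1 mm SID error moves a sub-millimetre offset by well under 0.002 mm —
an acceptance-tested property).

### Sign and axis conventions

* Detector frame: columns `u` increase rightward, rows `v` increase
  downward; positions in mm relative to the pixel-grid centre, with the
  centre of 1-based pixel `i` at `(i - 0.5 - N/2) · pitch`.
* `centroid_separation()` is **MLC minus jaw**; with `a` as above this makes
  a positive separation correspond to a positive source offset.
* Axis mapping (`axis_mapping = "xjaw_inplane"`, the default): detector
  columns `u` are the crossplane direction bounded by the **Y jaws** and
  the MLC leaf *sides*; rows `v` are the inplane direction bounded by the
  **X jaws** and the MLC leaf *ends*. The alternative
  `"xjaw_crossplane"` swaps the roles for machines with the other collimator
  layout. The mapping only selects which `d_jaw` pairs with which detector
  axis; the algebra is unchanged.

### The ion-chamber cross-check

An independent, imager-free check: half-block the field with one jaw so a
small chamber at source distance `d_ic` (default 750 mm) sits on the
penumbra, and record charges `q_90`, `q_270` at the two collimator angles.
Aperture miscalibration again cancels in `(q_90 - q_270)/2`; dividing by a
separately measured sensitivity (charge per mm of deliberate jaw travel,
`ic_sensitivity()`, an ordinary least-squares slope with an R² linearity
check) gives the apparent edge shift at isocentre. Scaling to the jaw plane
(`· d_jaw / sad`) and applying the lever arm

```
d_ic / (d_ic - d_jaw)   →  1.74 (Y jaws), 2.18 (X jaws)
```

(`ic_lever_arm()`) yields the same physical offset the EPID method reports,
from entirely different hardware. `compare_methods()` summarises paired
EPID/chamber measurements (mean, SD, max |diff|).

## 2. Parameters

All distances are mm from the source along the beam axis.

| Parameter | Default | Meaning |
|---|---|---|
| `d_jaw_x`, `d_jaw_y` | 406, 319 | Effective height of the X / Y jaw pairs |
| `d_mlc` | 490 | Effective height of the MLC leaf bank |
| `d_epi` | 1000 | Source-to-imager distance (SID); 1050 on some platforms |
| `d_ic` | 750 | Chamber plane for the cross-check |
| `sad` | 1000 | Source-to-axis distance (isocentre) |
| `median_kernel` | 3 | Median filter window (fixed 3×3) |
| `threshold` | 0.5 | Field-edge level on the unit-normalised image |
| `target_effective_pitch` | 0.0392 | Post-upsampling pixel size, mm |
| `edge_band_fraction` | 0.8 | Central fraction of the field extent used for edge averaging |
| `pixel_pitch` | 0.784 or 0.392 | Native panel pitch, mm (warned if otherwise) |

Constructor invariants are enforced at build time: `linac_geometry()`
requires `0 < d_jaw < d_mlc < d_epi` and `d_jaw < d_ic`; images must carry a
positive pitch, a plausible SID, and a collimator angle of 90° or 270°; a
`measurement_set()` must mix exactly the four expected images with matching
pitch and SID (0.1 mm tolerance).

## 3. The image-analysis chain

Each portal image passes through `preprocess()` then `find_field_center()`:

1. **3×3 median filter** — removes salt-and-pepper outliers (dead pixels,
   direct-hit spikes) without displacing edges, implemented as a
   fully-vectorised sorting network.
2. **Min–max normalisation** to [0, 1] so the 50 % threshold is meaningful
   regardless of dose or detector gain. A constant image is rejected.
3. **Upsampling** to a 0.0392 mm effective pitch (×20 from 0.784 mm panels,
   ×10 from 0.392 mm), via separable *interpolating* natural cubic splines.
4. **Binarisation at 0.5** and connected-component labelling; the field
   must be one region covering 1–90 % of the frame and must not touch the
   border (a clipped field is a hard error, not a silent bias).
5. **Edge extraction**: within the central 80 % band of the field's extent
   (excluding rounded corners), each row's two edges are located as
   half-value crossings, *linearly interpolated* between the outermost
   above-threshold pixel and its neighbour; the field centre is the mean of
   the per-row edge midpoints (and symmetrically per column).

`measure_focal_spot()` runs this on the four images, averages the
collimator-opposed pairs, forms the MLC-minus-jaw separation, and applies
the per-axis factor `a`.

### Why an interpolating spline, and why sub-pixel crossings

Two numerical choices matter at the micrometre level because `a` amplifies
any centring error by up to ×2.37:

* **Interpolating spline vs cubic-convolution kernel.** The common
  cubic-convolution resampler (Keys, a = −0.5) is an *approximating*
  filter: on a penumbra profile it shifts the reconstructed 50 % crossing
  by up to ~0.008 mm depending on where the edge falls within a native
  pixel — a phase-dependent bias that does not cancel between jaw and MLC
  images. A natural interpolating cubic spline (`stats::spline`)
  reproduces the samples exactly and shows ~8× less phase bias
  (~0.001 mm) in the same experiment, so the package uses it. This is the
  same order-3 interpolation used by standard scientific image resizers.
* **Sub-pixel edge refinement.** Taking the outermost above-threshold
  *pixel index* as the edge quantises each edge to the effective pitch.
  For a noiseless, axis-aligned field every row quantises *identically*,
  so the error does not average out and can reach half a pitch per edge
  (~0.02 mm) — multiplied by `a`, a 0.05 mm offset error. Linear
  interpolation of the actual threshold crossing removes this bias while
  reproducing the pure-binary-image result exactly (on a hard 0/1 edge the
  crossing lands halfway between the two pixels).

With both choices, a noiseless simulated set is recovered to better than
0.0005 mm, and ±1 mm single-bank miscalibrations perturb the result by
about 0.001 mm (both acceptance-tested with margins: < 0.005 mm and
< 0.01 mm).

### Reporting conventions

Reproducibility statistics (`repro_stats()`) use the sample (n−1) standard
deviation, and reported values are rounded half-away-from-zero to three
decimals — matching how such QA tables are conventionally printed.
`fs_repro_example()` and `fs_validation_example()` ship a published-style
four-linac dataset (three repeats per machine, and paired EPID/chamber
measurements) whose recomputed statistics are locked down in the tests.

## 4. The synthetic image generator

`render_measurement_set()` produces the four-image set from a known ground
truth, for validation and for pipeline testing without a linac.

**What it models.** Each aperture edge at collimator height `d` and
transverse position `e` (including any per-bank miscalibration, given in mm
at isocentre) is projected from the displaced source to the panel with the
same similar-triangles optics the measurement inverts — but the code paths
are independent, and a `uniroot`-based ray-trace oracle in the test suite
confirms the forward projection to 10⁻⁶ mm. The collimator rotation is
modelled by flipping the aperture sign at 270°. The fluence is a separable
product of Gaussian-convolved edges (`pnorm` profiles, `penumbra_sigma` mm
at the panel), sampled at pixel centres, with multiplicative Gaussian noise
(`noise`, fractional SD). Images carry only realistic metadata (pitch, SID,
angle, defining system); the ground truth lives in a separate
`manifest.json`, so the measurement code cannot cheat.

**What it deliberately omits.** Scatter and off-focal radiation, the
panel's glare/optical point-spread function, beam-profile horns and
flatness, tongue-and-groove and inter-leaf leakage, detector lag and gain
maps, and source-spot *size* (only its position is modelled). These affect
absolute penumbra shape far more than the 50 %-point *symmetry* the method
relies on, which is why the simple model is adequate for validating the
centring chain; it is not adequate for dosimetric questions.

**Determinism.** `seed` fixes the noise; each of the four images uses
`seed + k - 1` so sets are reproducible image-by-image, and the generator
saves and restores the caller's RNG state.

The test and acceptance suites run the generator on a 160×160 grid at
0.784 mm pitch (a ~125 mm field of view, comfortably holding the 100 mm
field plus penumbra). That size is this package's own choice: it is the
smallest frame at which the field, its penumbra, and a border margin
coexist, keeping the ×20 upsampling (→ 3200×3200) fast enough for dozens of
end-to-end measurements per test run. Nothing in the method depends on the
frame size; production panels are simply larger.

## 5. Files and formats

* **DICOM RT Image** — a minimal built-in Explicit-VR-Little-Endian codec
  (no R DICOM package is required). Written tags include pixel spacing
  (3002,0011), RT Image SID (3002,0026), beam-limiting device angle
  (300A,0120) and an RT Image Label naming the defining system; pixels are
  16-bit. The reader also accepts Implicit VR and fails with a *named*
  missing attribute rather than a silent default.
* **Raw TIFF + YAML sidecar** — 16-bit grayscale TIFF with
  `pixel_pitch_mm`, `sid_mm`, `collimator_angle_deg`, `defining_system`
  alongside, for panels exported outside DICOM.
* **Reports** — JSON via `write_report()`/`read_report()`, carrying the
  offsets, separations, factors, per-image centres, geometry and package
  version.
* **CLI** — `inst/cli/focalspot` wraps the whole chain
  (`simulate`, `measure`, `ic`, `repro`, `compare`) for cron-style QA use;
  validation failures exit with status 2.

## 6. Limitations

* The method measures the focal-spot position **relative to the collimator
  rotation axis**, in the two transverse directions only; it says nothing
  about spot size, shape, or longitudinal position.
* It assumes the offset is constant during the four-image acquisition;
  energy- or gantry-dependent spot motion needs per-condition measurement
  (the functions accept any geometry, so per-gantry runs are possible).
* Accuracy inherits the uncertainty of the collimator heights `d_jaw`,
  `d_mlc`; these are vendor drawings, not measured per machine. The factor
  `a`'s sensitivity to them is easy to audit with
  `proportionality_factor()` on perturbed geometries.
* The 50 %-threshold centring assumes a penumbra symmetric about the
  geometric edge; strongly asymmetric penumbras (very large spots, heavily
  tilted panels) would bias both field systems, though largely in common
  mode.
* The chamber cross-check measures one direction per setup and requires a
  sensitivity scan with adequate span and linearity (enforced with errors
  and warnings).
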