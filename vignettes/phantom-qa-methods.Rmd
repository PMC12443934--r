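---
title: "Phantom QA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom QA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomqa)
```

phantomqa analyses 2D magnitude images of a fillable-cylinder MRI phantom —
an 18 cm outer / 14.8 cm inner diameter water-filled cylinder holding up to
24 sample tubes on an insertable plate — and ships a digital model of that
phantom plus a slice simulator so every stage of the analysis is testable
without scanner access. This vignette is the package's own account of the
science: the models, their assumptions, the tunable parameters, and the
choices made where the design was genuinely open.

## The digital phantom

The phantom frame has its origin at the midpoint of the cylinder axis, z
along the axis, units of millimetres. Two plate styles are modelled: the
Cor/Sag plate (tube axes along y, so coronal/sagittal slices cut circular
cross-sections) and the Axial plate (tube axes along z). `build_default_phantom()`
places tubes on a regular grid; list order defines the "consecutive" order
used by the distortion metric.

Key dimensions and their status:

| parameter | default | status |
|---|---|---|
| outer / inner diameter | 180 / 148 mm | fixed by the physical design |
| total length, flat / domed top | 160 / 214 mm | fixed by the physical design |
| body (water-column) length | 120 mm | **assumed**, configurable |
| along-row tube spacing | 24 mm | **assumed**, configurable |
| 15 ml tube outer/inner radius | 8.5 / 7.0 mm | typical conical-tube values |
| 5 ml tube outer/inner radius | 6.1 / 5.0 mm | typical cryo-tube values |
| plate capacity (Cor/Sag, Axial) | 15+9, 18+6 tubes | fixed by the physical design |

The along-row spacing is not a published design dimension; 24 mm is adopted
because measured inter-vial averages cluster there, and the package treats
whatever the configuration says as ground truth. Tubes are modelled as
finite cylinders (conical tips ignored; imaged cross-sections are mid-tube).
The water column is modelled as the body interior rather than the full
phantom length: the flat-top total length would leave no air margin inside
the 180 mm field of view, while real acquisitions show clear background
corners — and the corner noise regions need them.

**Placement tilt.** The phantom may sit at an angle in the scanner; this is
modelled as intrinsic z–y–x rotations in degrees. Ground-truth circles in an
image plane (`ground_truth_centers()`) are the *orthogonal projections* of
the rotated mid-tube centres into the plane; a tube tilted by θ against the
plane normal traces an ellipse, treated as a circle of the mean semi-axis
radius. Under this convention an out-of-plane tilt θ of the row scales
consecutive in-plane distances by cos θ — the mechanism that makes the
absolute spacing unrecoverable from a single scan and motivates comparing
scans only when the placement is unchanged. (The alternative convention —
intersecting each infinite tube axis with the plane — would scale distances
by 1/cos θ; the projection reading is the one the package's contracts and
acceptance checks pin down, and for the ≤5° tilts of interest the
difference is below 0.8%.)

## The slice simulator

Each pixel takes the closed-form magnitude signal of the material at its
(inverse-distorted) world coordinate:

- inversion-recovery spin echo (T1 weighting):
  $S = \mathrm{PD}\,\lvert 1 - 2e^{-TI/T_1} + e^{-TR/T_1}\rvert\,e^{-TE/T_2}$
- (fast) spin echo with an effective echo time (T2 weighting):
  $S = \mathrm{PD}\,(1 - e^{-TR/T_1})\,e^{-TE/T_2}$

Intensities are arbitrary units scaled so a fully recovered PD = 1 sample
gives 1000. Tube walls, the printed shell and the sealant contain no mobile
protons at these echo times and render as zero; exterior air is zero. Edges
are anti-aliased by 4×4 subpixel supersampling (configurable); at a
ground-truth centre the rendered intensity matches the closed form to
better than 1%.

Two preset families mirror the 64 mT protocol: IR-SE with TR 1.5 s, TI
0.3 s, TE 0.006 s, 24 averages, 1.6 mm pixels; and FSE modelled by its
effective TE (0.231 s coronal, 0.203 s axial) with TR 2 s, 80 averages,
1.5 mm pixels; 5 mm slices; fields of view 180 mm (left/right,
superior/inferior) and 220 mm (anterior/posterior). The pixel grid is always
`round(FOV / resolution)` per axis.

**What the effective-TE model ignores.** The scanner's 3D FSE echo-train
weighting, B1 inhomogeneity and slice-profile effects are not modelled; the
mono-exponential effective-TE decay is an approximation, and the vendor's
reconstruction is proprietary. Signal averaging enters only through the
effective noise scale σ/√NEX — no per-average simulation.

**Noise.** Magnitude-image noise is Rician:
$\sqrt{(S+n_1)^2 + n_2^2}$, $n_i \sim N(0, \sigma_{\mathrm{eff}}^2)$,
reducing to Rayleigh where S = 0 (mean σ√(π/2), sd σ√(2−π/2)). A truncated
gaussian option exists for calibration tests. Noise is seeded and leaves
the caller's RNG state untouched, so renders are bit-reproducible.

**Distortion.** Affine (`w = Au + b`) or radial (`w = u(1 + k|u|²)`) fields
are applied in world coordinates *before* rasterisation: each pixel looks up
the material at the inverse-mapped coordinate and the ground-truth centres
are pushed through the forward map, so image and truth warp identically and
no interpolation ambiguity arises. The radial inverse is solved by Newton
iteration and rejects non-invertible coefficients over the footprint.

**Material relaxation defaults.** No reference relaxometry exists for the
store-bought samples at 64 mT, so the shipped T1/T2/PD values are
placeholders chosen once to reproduce the observed qualitative contrast:
oil is the brightest vial in T1-weighted images; in T2-weighted images
water > copper solutions (darkening monotonically with capsule count) > oil.
They are labelled non-authoritative and are configurable in the geometry
config's `[materials]` section.

```{r materials}
vapply(default_materials(), function(m) c(t1 = m$t1, t2 = m$t2, pd = m$pd),
       numeric(3))
```

## Vial detection

The ROI identification pipeline is: binarise the image (Otsu by default, a
fixed threshold optionally), mark edge pixels (binary-boundary pixels
unioned with a gradient-magnitude ridge — partial-volume wall pixels can
hover just above the intensity threshold, but their gradients cannot hide),
seed circle candidates by circular Hough accumulation over the radius range,
refine each candidate by iterated least-squares (Kåsa) circle fitting with
gradient-magnitude weights, score it by angular perimeter coverage, and
enforce a minimum centre separation. Detected circles sit on the wall
mid-circle, `(r_inner + r_outer)/2`, because the edge mask marks both wall
boundaries; when a vial interior falls below threshold only the outer
boundary contributes and the fitted radius shifts outward by under a pixel.

Free parameters (`detection_params()`):

| parameter | default | why |
|---|---|---|
| `radius_range` | 5–12 mm | brackets both tube classes with margin |
| `min_separation` | 15 mm | below any plausible tube spacing, above a diameter |
| `min_fit_score` | 0.5 | true rings score ≥ 0.8 noise-free; the rectangular fill footprint's corners produce arc artefacts scoring ≈ 0.36 |
| `expected_count` | unset | when set, exactly that many must be found (shortfall is an error) |
| supersampled sub-pixel accuracy | — | gradient-weighted refinement localises centres to ≤ 0.3 px on noise-free renders |

"Consecutive" ordering projects the centres onto their principal axis
(eigenvector of the centre covariance), with ties broken by the orthogonal
coordinate and then radius — reproducing the along-row numbering for any row
orientation, including misaligned acquisitions.

## QA metrics

- `inter_vial_distances()`: Euclidean distances between world-coordinate
  centres of consecutive ROIs; `average_distance()` is their exact
  arithmetic mean (full precision internally; table-style output rounds to
  0.1 mm).
- `compute_snr()` / `compute_cnr()`: mean of the 5×5 signal region over the
  sample (n−1) standard deviation of the *pooled* 10×10 noise regions (200
  pixels; the pooled reading of "the noise pixel values" — with 200 pixels
  the n−1 choice matters at the 0.3% level but is fixed for
  reproducibility). No Rician bias correction is applied, matching
  convention; because air-background noise is Rayleigh (sd 0.655 σ), the
  uncorrected SNR overestimates S/σ by ×1.53, and a corrected estimate is
  attached as attribute `"rician_corrected"` for information.
- `auto_place_regions()` reconstructs the conventional layout: T1w signal
  region centred on the highest-interior-mean ROI (oil), T2w signal region
  at the fill centroid outside all ROI disks dilated by 2 px, noise regions
  in opposite corners inset 3 px, slid along the border until clear of a
  dilated low-threshold structure mask (partial-volume edge pixels count as
  structure). Exact corner placements in real acquisitions are unknown, so
  manual `region_spec()`s are accepted everywhere.
- `compare_scans()` reports |d̄_a − d̄_b|, the relative difference against
  the mean of the two averages, and a within-one-pixel flag using the
  *smaller* of the two pixel spacings (the conservative reading). The
  comparison is only meaningful when the phantom was not moved between the
  scans; that assumption is the caller's and is recorded.

## The synthetic fixture set

`make_fixtures()` renders the four-scan experiment: T1w/T2w coronal pairs
with the flat top (placement: no tilt) and the domed top (placement differs
by a small rigid move: 2° out-of-plane + 3° in-plane). Within each pair the
placement is identical — the precondition for a valid comparison — and the
noise scales (σ = 10 for T1w, 1.75 for T2w on the 0–1000 scale) were chosen
once so the measured SNRs sit at order 10² (T1w) and 10³ (T2w), reproducing
the characteristic order-of-magnitude gap between the two protocols.

What a green test on these fixtures establishes — and what it does not: the
fixtures share the simulator's idealisations (2D slice, mono-exponential
FSE, no B0/gradient-nonlinearity distortion unless injected, no ghosting,
uniform coil sensitivity), so passing tests validate the *analysis* given
images that obey the stated model, not the scanner. Real-data features not
emulated: structured artefacts, intensity non-uniformity, partial-volume
effects along the 5 mm slice, and vendor reconstruction filters.

## Numerical choices and degenerate inputs

- Otsu's threshold uses a 256-bin histogram; a constant image raises a
  "no contrast" detection error rather than returning an arbitrary mask.
- A fixed threshold of 0 on a positive image marks everything as foreground;
  there are then no edges and detection reports zero candidates (contract
  tested).
- Circle refinement shrinks its inlier band (2.5 → 1.5 → 1.2 px) across
  iterations so neighbouring vials' wall rings cannot contaminate a fit at
  tight spacings.
- NIfTI output is float64 so write→read round trips are bit-exact; 16-bit
  PNG quantises to 1/65535 of full scale (and carries no physical spacing —
  reading PNG requires an explicit spacing).
- SNR with zero noise standard deviation is an error, not infinity; empty
  distance lists are refused at report construction.
- All randomness (noise, fixtures) is seed-derived; identical seeds give
  byte-identical images and reports.

## Known limitations

- One-dimensional distortion only: a single row of vials cannot separate
  scale from shear, and says nothing about through-plane distortion.
- The detector fits circles; strongly tilted vials (elliptical sections)
  and 3D cylinder fitting across slices are out of scope.
- DICOM support is read-only, single-frame, uncompressed explicit VR little
  endian; TIFF is not supported (NIfTI or 16-bit PNG cover interchange).
- Reported SNR follows the uncorrected convention and is therefore
  noise-region-statistics dependent; use the attached Rician-corrected
  value when an absolute S/σ estimate is needed.
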