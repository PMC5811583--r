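---
title: "Methods: quantitative dosimetry for holmium-166 scout-dose imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative dosimetry for holmium-166 scout-dose imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Before radioembolisation of liver tumours, a small scout dose of
holmium-166 microspheres (about 250 MBq) is administered intra-arterially
and imaged, to predict where the therapeutic dose will go. Two safety
questions are quantitative:

1. **Lung shunting** — what fraction of the administered activity bypasses
   the liver capillary bed and lodges in the lungs?
2. **Extrahepatic depositions** — when activity accidentally lodges outside
   the liver (duodenum, stomach wall, falciform ligament), what absorbed
   dose does that tissue receive?

`scoutdose` implements the full quantitative chain for both questions, plus
the phantom calibration that underpins the volume estimate, plus a
synthetic image generator with known ground truth so every stage can be
validated end to end without patient data.

## Lung shunt fraction

On anterior and posterior planar scintigrams, lung and liver
regions-of-interest are summed and combined via the geometric mean:

$$\mathrm{LSF} = \frac{\sqrt{L_a L_p}}{\sqrt{L_a L_p} + \sqrt{H_a H_p}}$$

with $L$ the lung and $H$ the liver ROI count sums on the anterior ($a$)
and posterior ($p$) views. A source at depth $d$ in a body of thickness $T$
is attenuated by $e^{-\mu d}$ anteriorly and $e^{-\mu (T-d)}$ posteriorly;
the geometric mean is $e^{-\mu T/2}$ regardless of $d$, and the common
factor cancels in the ratio. `lung_shunt_fraction()` implements the
equation; `lsf_from_planar()` builds the four sums from images and masks.
One organ's geometric mean being zero is treated as a valid degenerate
input (LSF exactly 0 or 1); only both being zero is an error, since the
ratio is then undefined. The result is a fraction; percentage formatting
happens only at the reporting layer, so the value is never scaled twice.

## Quantifying an extrahepatic deposition

Three deliberately asymmetric estimators, each biased in the safe
direction:

* **Activity** (`estimate_activity`): the sum of all voxel values (Bq)
  inside a generous manual *margin* delineation around the deposition, with
  **no threshold**. Counts displaced by breathing, motion and the
  partial-volume effect are retained, so the activity — and hence the dose —
  is over- rather than underestimated. The margin is taken as given; its
  volume is recorded in the output for provenance.
* **Volume** (`estimate_volume`): all in-margin voxels at or above a fixed
  fraction (default 30%) of the **in-margin** maximum voxel value, times
  the voxel volume. Taking the maximum inside the margin means hepatic
  activity can never set the threshold. Ties at exactly the threshold are
  inside (deterministic and testable); no connected-component filtering is
  applied — the simplest rule, recorded in the report.
* **Dose** (`absorbed_dose`):
  $$D\,(\mathrm{Gy}) = 15.87\ \tfrac{\mathrm{mJ}}{\mathrm{MBq}} \times
  \frac{A\,(\mathrm{MBq})}{V\,(\mathrm{cm}^3) \times 1.06\ \tfrac{\mathrm{g}}{\mathrm{cm}^3}}$$
  15.87 mJ/MBq is the total beta energy absorbed per unit holmium-166
  activity (beta decay carries 96% of the emitted energy) and 1.06 g/cm³
  the soft-tissue density; mJ/g is numerically Gy. The mean beta range
  (2.5 mm) is small against the delineated volumes, so all beta energy is
  assumed absorbed locally; the high-energy gamma contribution to the local
  dose is negligible by the inverse-square argument and is set to zero.
  Both constants are overridable via `dose_constants()`.

`quantify_deposition()` composes the three into one record;
`cohort_summary()` aggregates records. For an even-sized cohort it reports
three median conventions — the interpolated median and the lower/upper
order-statistic medians — because small clinical cohorts are commonly
summarized by an observed value, which for even *n* is one of the order
statistics (for this package's reference cohort of six, the reported
medians are the upper medians, i.e. the 4th order statistic).

## Phantom calibration of the threshold

The volume threshold is not arbitrary: it is calibrated on an
image-quality phantom — six fillable spheres of 0.5–26.5 ml in a 9.7 L
water background, imaged with the same protocol as the patients.
`sweep_thresholds()` delineates every sphere at a grid of candidate
fractions (default 0.05–0.95 in steps of 0.05; the grid is a package
choice, coarse enough to be fast and fine enough to bracket any plausible
operating point) and `select_threshold()` returns the smallest fraction at
which **no** sphere of at least 1 ml overestimates its true volume:
"approximate or underestimate, but not overestimate", operationalized as
estimated ≤ true, per sphere, with an optional relative tolerance
defaulting to 0 (the strictest reading). Underestimating the volume
overestimates the dose, which reduces the chance of falsely declaring a
deposition safe (a type-II error in the safety assessment). The sub-1-ml
sphere is exempt: at that size simultaneous activity underestimation can
flip the dose bias, which is accepted as clinically irrelevant because
observed depositions are an order of magnitude larger.

Two calibration behaviours deserve a note:

* The selected fraction depends on the system PSF. At the default 12 mm
  FWHM the package selects 0.70 on the default noiseless phantom — wider
  than the 30% a sharper clinical reconstruction yields — because heavier
  blur pushes more of the spread-out signal above any fixed fraction of the
  reduced maximum. What is invariant, and what the acceptance tests assert,
  is the conservatism property: at the selected threshold every sphere
  ≥ 1 ml has estimated volume ≤ truth and estimated dose ≥ truth.
* Even with **no** blur, low thresholds overestimate: the rasterizer is
  partial-volume-aware, so boundary voxels carry fractional values, and any
  of them above the threshold is counted as a whole voxel. The selection is
  therefore tested against an independent scan of the sweep table rather
  than against a presumed "smallest fraction wins" outcome.

## The synthetic generator: what it emulates and what it does not

`generate_phantom()` and `generate_patient_scene()` produce quantitative
voxel images (Bq per voxel, 4.8 mm isotropic grid by default, matching the
128×128 reconstruction matrix of the quantitative scans) in three steps:

1. **Rasterization with sub-voxel partial volume.** Boundary voxels get a
   semi-analytic fill fraction: the in-object column length along the axial
   direction is computed exactly, and the transaxial integral by a 16×16
   midpoint sub-grid (8×8 for the large ellipsoids). A coarse binary
   sub-voxel count was tried first and rejected: its discontinuous
   integrand converges too slowly to meet the 0.5% activity-conservation
   tolerance for millilitre-scale spheres on 4.8 mm voxels, which the test
   suite asserts and the semi-analytic scheme meets with ample headroom.
2. **System blurring.** Separable convolution with an isotropic Gaussian,
   default FWHM 12 mm — a typical medium-energy-collimator SPECT
   resolution; the true system PSF of a Monte-Carlo reconstruction is not
   publicly stated, so this is a single documented, adjustable parameter.
   Kernel taps are normalized to sum to one, so total activity is conserved
   to numerical precision whenever objects keep a margin from the grid
   border.
3. **Noise.** Optional voxel-wise Poisson draws on `value × counts_per_bq`
   (default 1), seeded, with the global RNG state restored afterwards.
   Fixed seed implies bit-identical output.

The patient scene is a stated world, chosen once: a 220 MBq liver
(ellipsoid), 30 MBq in two lung fields (the cohort's median lung shunt was
about 13%), and a 3.7 MBq deposition in 15.3 ml — the median deposition of
the reference cohort. The deposition sits far enough from the liver
(>10 blur sigmas between the liver surface and the margin boundary) that
margin sums are unbiased, which the conservation tests rely on. The margin
delineation is a sphere of the true radius plus 2.5 PSF FWHM, restricted to
exclude liver voxels — wide enough to cover the blurred support, emulating
the "large enough margin" of a manual delineation. Phantom sphere
concentration defaults to 1 MBq/ml; all calibration properties are
concentration-invariant. The phantom background is cold (water-filled), with
a hot-background option.

Deliberately **not** modelled: collimator-detector response beyond the
Gaussian, scatter, attenuation in SPECT (the planar projector has an
optional single-μ exponential, default off, precisely so tests can exercise
the geometric-mean cancellation), breathing and motion, heterogeneous
uptake, and realistic anatomy. A green test therefore establishes the
correctness of the quantification chain on its stated input model — not the
accuracy of any scanner's reconstruction.

## Numerical and design choices

* **Grids and coordinates.** Voxel indices are 0-based in coordinate
  arithmetic; physical coordinates refer to voxel centers; generated grids
  are centered on the physical origin. One grid per analysis — no
  resampling between SPECT and CT grids is attempted, and the grid in use
  is whatever the input image declares.
* **I/O.** NIfTI-1 for volumes and masks (written float64 so activities
  round-trip exactly; masks as uint8), CSV for planar images, masks and
  tables (with a one-line spacing/label comment header), JSON for
  specifications and reports. The NIfTI codec is a minimal implementation
  validated against an independent reader; it intentionally supports only
  the diagonal-affine subset this pipeline produces.
* **Reproducibility vs timestamps.** Every report file embeds its effective
  configuration (stage, parameters, seed, package version) so it can be
  regenerated bit-for-bit; timestamps would break that and are emitted only
  in the stderr log.
* **Rounding.** One decimal for MBq, ml and Gy at the display/report layer
  only; full precision is kept internally. Recomputing a dose from
  already-rounded activity/volume pairs can differ from a dose computed on
  unrounded inputs by up to ~0.2 Gy at this cohort's magnitudes — the
  reason two of the six reference-cohort doses disagree with their
  recomputation at the second decimal.
* **Degenerate inputs.** Empty margin masks error ("nothing delineated");
  an all-zero margin errors in the volume path (threshold of a zero maximum
  is undefined) while the activity path returns 0; zero volume errors in
  the dose; threshold fractions outside (0, 1] error.

## Limitations

The dose model ignores beta-range spatial redistribution and gamma dose;
both assumptions are conservative or negligible at these volumes but break
down below ~1 ml. The calibration transfers from a homogeneous-sphere
phantom to heterogeneous depositions only approximately. The synthetic
scenes validate the software chain, not the physics of any particular
scanner; users analysing real reconstructions should calibrate the
threshold on a phantom scanned with their own protocol.
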