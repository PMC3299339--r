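---
title: "Calibrating CBCT densities for orbital implant monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating CBCT densities for orbital implant monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbcal)
```

## The problem

After enucleation of an eye, the lost volume is replaced with a porous
spherical implant (hydroxyapatite or aluminium oxide, 16–20 mm diameter,
nominal porosity around 80%) buried in the orbital soft tissues. Fibrous and
vascular tissue grows into the pores over months to years, and the apparent
radiodensity of the implant region is a candidate non-invasive marker of
that process. Cone beam CT (CBCT) is attractive for serial monitoring
because of its low dose, but CBCT scanners report a linear "HU-like"
intensity scale that is not water-calibrated: the same tissue can read
hundreds of HU apart on different acquisitions, so raw CBCT densities are
not comparable across scans or patients.

`orbcal` implements the correction used to make them comparable, together
with everything needed to exercise it end to end: the 30-scan study table it
reanalyses, voxel region statistics, sphere-based diameter estimation,
longitudinal trend fits, and synthetic ground-truth generators.

## The two-point correction

The Hounsfield scale is defined from linear attenuation coefficients as

$$\mathrm{HU} = 1000\,\frac{\mu_x - \mu_\mathrm{water}}{\mu_\mathrm{water} - \mu_\mathrm{air}},$$

an affine map pinned at water (0 HU) and air (−1000 HU)
(`hounsfield_from_attenuation()`). A CBCT scan's scale is linear but with
unknown gain and offset. If two regions of known reference density are
visible in the scan, the unknown affine map can be inverted from their
measured values alone. Two such regions exist in every orbital scan of this
design:

* the **contralateral corpus vitreum (CV)** — the vitreous body of the
  intact eye, a large homogeneous water-like region (low anchor), and
* the maximum of the **dedicated orbital volume (DV)** — dense cortical
  bone, the densest voxel in the anatomically bounded orbital sub-volume
  (high anchor).

Reference-side values come from a water-calibrated MSCT control group:
CV mean 5.93 HU (SD 3.97) and DV max 2024.67 HU (SD 103.49), the defaults of
`msct_reference()`. With scan anchors $(c, d)$ and reference anchors
$(C, D)$, `build_calibration()` constructs

$$x \mapsto \frac{D - C}{d - c}\,(x - c) + C,$$

which sends both anchors exactly onto their reference values. Every
acquisition gets its own map — that is the heart of the method — and the
scalar (`correct_hu()`) and voxelwise (`correct_volume()`) paths share one
implementation.

Two numerical choices matter here:

* **Degeneracy tolerance** (`tol_hu`, default 1 HU): anchors closer than
  noise produce a meaningless map with an exploding gain; the wider the
  anchor spread, the more accurate the correction. Anchor pairs within the
  tolerance are an error, as are swapped anchors.
* **The literal additive term** (`literal`): the correction as published
  ends with "+ reference CV mean" (+5.93 HU), which makes both anchors
  exact fixed points; dropping it (`literal = FALSE`) pins the corpus
  vitreum at 0 HU instead. Recomputing the study table's corrected column
  reproduces it to about 1.3% on average under either reading — the printed
  column was evidently computed from unrounded per-scan inputs that the
  printed table does not carry — so both readings are exposed and the
  literal equation is the default. The discrepancy is reported by
  `run_study_reanalysis()`, never asserted.

## The packaged study table

`load_study_table()` ships the printed 30-record table verbatim: factory and
sphere-fit estimated diameters, implant lifespan (79–2636 days), the
uncalibrated implant-volume mean/SD, the published corrected mean, and each
scan's CV-mean and DV-max anchors. Three packaging decisions:

* The two scans excluded by the original analysts, and the implant material
  of each record, were encoded only as table shading/colour, which does not
  survive into text. No labels are fabricated: all 30 records load with
  `included = TRUE`, exclusions are caller-supplied IDs, and material maps
  are a caller-supplied `id_label`/`group` table.
* Record 1.26's factory diameter is printed as 10 mm against an estimated
  19.66 mm and a 16/18/20 mm manufactured size list. It is kept as printed,
  flagged `suspect_diameter`, and excluded from the diameter-deviation SD
  (a sample SD, n − 1 — the source does not state its denominator).
* The loader verifies an md5 checksum so silent fixture corruption fails
  loudly.

```{r}
summarize_cohort(load_study_table())
```

(The deviation SD over the 29 typo-free rows is 0.57 mm; dropping the two
largest-deviation rows — a plausible but unverifiable guess at the two
excluded scans — gives 0.34 mm, near the study's reported 0.2839 mm. None of
these figures is asserted anywhere: the exclusion IDs are unrecoverable.)

## Region statistics and geometry

Volumes are plain 3D arrays with isometric-capable voxel spacing and a
voxel-center world origin (`voxel_volume()`; the study's CBCT used 0.25 mm
voxels). `region_statistics()` reports mean, sample SD (n − 1; a one-voxel
region has SD 0), max, count and physical volume over a boolean mask.
`crop_dedicated_volume()` cuts the minimal sub-grid whose voxel centers fall
in a world-space box, preserving world coordinates — the dedicated orbital
volume is delineated this way.

Implant diameters are estimated by sphere fitting:

* `sphere_from_three_points()` — the three-point construction used in the
  original workstation analysis is undocumented, so it is interpreted as the
  only geometry three points determine: the circle through them is taken as
  a great circle (circumcenter + circumradius). Points spanning a triangle
  area below 1e−9 mm² are rejected as collinear.
* `fit_sphere_least_squares()` — the algebraic (Kåsa) linearisation for
  n ≥ 4 noisy surface points; exact on points that lie on a sphere.
* `estimate_implant_diameter()` fits the least-squares sphere to the voxel
  centers of the mask's surface shell. Inner-surface voxel centers sit up to
  one spacing *inside* the continuous surface, which biases the fitted
  diameter low by roughly 0.2 mm at 0.25 mm spacing; the default shell is
  therefore the union of inner-surface voxels and their outer 6-neighbours,
  which straddles the surface and leaves a residual bias below 0.01 mm on
  noiseless phantoms. On noiseless 16/18/20 mm phantoms the estimate is
  within one voxel spacing of truth, consistent with the study's
  observation that its 0.2839 mm diameter SD is within acquisition
  resolution.

`classify_against_factory_sphere()` splits implant-mask voxels by whether
their centers lie within the factory sphere. The original images show
"spikes" of implant-density material beyond the factory diameter; whether
those are implant material or CBCT artefact is explicitly unresolved in the
source, so the classifier reports geometry only.

## Longitudinal trends

`ols_fit()` is the closed-form simple least-squares estimator (slope,
intercept, R², slope SE; R² defined as 0 for a constant response), with the
daily slope also scaled per year (`days_per_year = 365.25`; the source never
states its year convention). No p-value machinery is attached — the source
reports none. `density_trend()` fits corrected (per-record anchors),
published-column, or raw densities against lifespan, pooled or per group.

## Synthetic ground truth

Two generators make every stage testable without image downloads; both are
bit-reproducible for a fixed seed and restore the caller's RNG state.

**`generate_phantom()`** rasterises (by voxel-center membership) a porous
implant sphere, a water-like CV sphere, and a small dense bone focus into a
background of soft tissue, then applies an affine distortion
(gain, offset) and additive Gaussian noise to produce the "observed" scan.
Defaults: 128³ grid at 0.25 mm (a 32 mm desk-scale cube, not the full 16 cm
clinical field of view), 18 mm implant with bulk density 2000 HU and 80% of
implant voxels carved to soft-tissue density — porosity is modelled as
sub-resolution density reduction, not the real 150–400 µm pore
microarchitecture, which a 0.25 mm grid cannot represent. The true-scale CV
and bone densities default to the MSCT reference values (5.93 and
2024.67 HU), so the default reference is exact for the phantom and the
calibration round-trip recovers the true volume to numerical precision
(< 1e−9 HU) from the observed anchors alone. Noise defaults to 30 HU SD — a
free parameter, as the study reports no noise magnitude; it is additive
Gaussian only, since the analysis consumes region means and maxima for
which that suffices. Optional radial spikes emulate the beyond-diameter
protrusions, with the spiked voxel set recorded as ground truth.

**`generate_cohort()`** emulates the statistical structure of the study
table: two groups of n = 17 and 11 with true corrected-density slopes of
−10 and −14 HU/year, lifespans uniform over 79–2636 days, residual scatter
150 HU, and per-scan anchors drawn from a normal CV-mean and floor-truncated
anchor-span model fitted by eye to the table's anchor columns. Day-0
baselines (700/750 HU) match the spread of the printed corrected column;
the source prints no intercepts, so these are the generator's own choices.
Each record's *raw* implant mean is back-computed by inverting the literal
correction on that record's anchors, so running the pipeline's correction
recovers the generated truth exactly — a self-inverse construction that
makes slope-recovery tests sharp. Over 200 replicates, both slopes are
recovered within 3 standard errors in ≈ 98% of fits.

What passing these tests shows — and does not show: they validate the
affine algebra, the estimators and the pipeline plumbing under the
generators' assumptions (linear scale distortion, Gaussian noise,
homogeneous anchor regions). They cannot validate what the generators do
not model: beam hardening, scatter, partial-volume effects at anchor
boundaries, patient motion, or a CV region that is not actually
water-equivalent.

## Problem sizes

The test and driver workloads are sized for interactive use: 64³ phantoms
for property checks, 168×96×96 phantoms for the three factory-size diameter
recoveries, 100 random distortions for the round-trip property and 200
cohort replicates for slope recovery; all complete in seconds to a few
minutes on one CPU.

## Known limitations

* **The pooled trend on the printed table is positive.** Recomputing
  corrected densities from the printed anchors and regressing on lifespan
  gives +42 HU/year pooled (+41.6 on the published corrected column, +13.2
  raw; lifespan–density correlation +0.39). The published conclusion of
  densities *decreasing* by 10 and 14 HU/year was drawn per material on 28
  scans, and the material labels, the two exclusions and the fitted
  regression equations all live in colour coding and figures that are not
  recoverable from the printed data. No two-record exclusion flips the
  pooled sign (exhaustive search: minimum +36.6 HU/year). The package
  therefore reproduces the published per-record corrections to ~1.3% but
  cannot — and does not claim to — reproduce the pooled decline from the
  printed table; the corresponding sign check in the acceptance suite is
  deliberately left failing rather than weakened.
* The corrected-column comparison is reported, never asserted, for the
  provenance reasons above.
* No beam-hardening/scatter modelling, no automatic anatomical
  segmentation, no surface meshing or rendering; masks and bounds are
  inputs.
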