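---
title: "Quantifying interfraction positional variation of rectal tumor volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interfraction positional variation of rectal tumor volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rectvar)
```

## The problem

Rectal tumors treated with long-course radiotherapy are irregular,
deformable, and move from day to day relative to the bony anatomy used for
patient positioning. Planning target volume (PTV) margins must absorb this
interfraction variation, so its magnitude has to be measured: too-large
margins irradiate bladder and small bowel unnecessarily, too-small margins
risk missing tumor. `rectvar` quantifies the variation of a delineated
primary gross tumor volume (GTVp) across repeat scans of the same patient,
using two complementary measures, and decomposes the population uncertainty
into the quantities margin recipes consume.

The expected input is, per patient, one baseline delineation and several
repeat delineations (five in the motivating design of six scans), each
already co-registered to the baseline frame by a rigid bony-anatomy
registration whose transform is supplied alongside the contours. All
geometry lives in the patient LPS frame: +x left, +y posterior, +z cranial,
millimetres throughout.

## The two measures

**Center of mass (COM).** Each structure's volume centroid is computed from
its planar contours by the shoelace area/centroid formulas, slices weighted
by area × slab thickness. The COM shift of a repeat scan relative to
baseline is a rigid-motion surrogate: cheap and robust, but blind to
deformation that leaves the centroid in place.

**Bidirectional local distance (BLD).** The baseline surface is sampled as
a dense point cloud and, for every baseline point *b*, three steps define
the displacement to a test surface:

1. find the nearest test point to *b* (forward nearest neighbour);
2. find every test point whose nearest baseline point is *b* (the reverse
   set);
3. among these candidates, take the one at the **largest** distance as the
   mapped point.

The reverse step is what distinguishes BLD from a plain closest-point
distance: a baseline point that "owns" a far-away patch of the test surface
cannot report a deceptively small displacement. Taking the maximum over all
baseline points of the BLD recovers the symmetric Hausdorff distance (this
identity is asserted in the test suite against an independent computation).
All nearest-neighbour and arg-max ties resolve to the smallest point index,
which makes results machine-exact and lets the accelerated k-d-tree
implementation be compared *exactly* against an exhaustive O(N·M) oracle.

**Signing.** Displacement vectors are decomposed into RL/AP/CC components
and signed. The in-plane components receive a common sign — positive when
the mapped point lies outside the baseline structure (tissue moved out),
negative when inside. The text this package models says only that the
cranio-caudal sign is set "in relation to the COM"; we operationalize it as
*outward from the COM plane*: for baseline points at or above the COM a
cranial displacement is positive, for points below the COM a caudal
displacement is positive. Both conventions are isolated in
`sign_components()`. Two genuinely open readings were settled here: the
in-plane sign is applied jointly to |dx| and |dy| (per-component independent
signing is not supported by the source's wording), and the CC rule is the
COM-plane rule above.

## Surface sampling

The sampling scheme of the original analysis is unreported, so the package
documents its own: each contour is resampled uniformly in arc length, with
a per-slice point budget proportional to the local lateral surface area —
`ceil(P·c·slab / spacing²)` for perimeter `P` and a frustum slant factor
`c` estimated from the slice-to-slice change of effective radius — floored
at `ceil(P/spacing)` so the arc step never exceeds `spacing`. Top and
bottom slices additionally receive an interior grid (end caps) so that
cranio-caudal motion at the tumor ends is represented. The total count then
scales as surface area / spacing², and the default `spacing = 1` mm places
study-sized tumors in the 7000–28000-point range reported for real
delineations; a discretized sphere lands within a few percent of its
analytic area.

Rigid transforms are applied to point clouds and COMs, never by re-slicing
contours, which avoids resampling artifacts. Containment queries classify
boundary points as *outside*; a sign flip at displacement ≈ 0 is
numerically irrelevant.

## Per-patient and population statistics

For each baseline point and direction, the mean and sample SD (n−1) across
the patient's test scans summarise the local displacement distribution. A
patient's representative values are the 95th percentiles over baseline
points of these per-point means and SDs — percentile first selects the
mobile region, then patients are compared. The alternative order (95th
percentile per scan, then moments across scans) is available as
`mode = "stats_of_p95"` for sensitivity analysis, because the two orders
answer subtly different questions. Pooled per-direction median, IQR and
95th percentile over all points and scans describe the global displacement
distribution.

Percentiles use linear interpolation between order statistics,
`h = 1 + (n−1)q/100` (R's default type 7). With ~10⁴ surface points the
convention is immaterial; with 12–16 patients it is not, hence it is fixed
and documented.

Population uncertainty follows the standard Van Herk decomposition, whose
formulas the source text cites but does not print:

* **GM** (group mean) = mean over patients of the per-patient mean;
* **Σ** (systematic error) = sample SD over patients of the per-patient
  means — preparation error;
* **σ** (random error) = root-mean-square over patients of the per-patient
  SDs — execution error.

Sample (n−1) SDs are used at both levels. Note that Σ estimated this way
contains an inflation of `σ²/n_test` from the finite number of repeat
scans; with five test scans and study-like magnitudes this is a ~5% upward
bias. The package reports the conventional, uncorrected estimator.

On rigid-motion-only synthetic cohorts the COM path recovers the
generator's (GM, Σ, σ) up to Monte-Carlo error; with percentile selection
the surface path systematically shows smaller Σ and larger σ than the COM
path — percentile selection picks each patient's most mobile region
regardless of location, which compresses between-patient differences and
inflates within-patient scatter. Both behaviours are asserted as tests.

## Mapping onto a reference rectum

Local variation is resolved by location on a common tubular reference
rectum: slices every 1.5 mm along the central axis (CAX) from the anal
verge, 120 equidistant surface points per slice, azimuth 0° at anterior
turning counter-clockwise towards patient left. The radius (default 15 mm)
and length are configurable — the reference geometry of the original
analysis is unreported, and on a straight tube the azimuth/CAX coordinates,
not the radius, carry the information.

Each patient's baseline points receive a CAX coordinate (arc length along
the patient's centerline from the anal verge to the point's nearest
centerline vertex — absolute millimetres, since the height bands are stated
in mm), are re-expressed about the reference axis by translating their
centerline foot onto it, and are assigned to their nearest reference point
— the reverse-assignment step of the BLD construction. Every patient point
maps to exactly one reference point (mass conservation is a tested
invariant), and multiple points landing on one reference point are averaged
*within* the patient first, so large tumors do not dominate the
inter-patient variance.

Per reference point, GM/Σ/σ are then computed across patients as above.
Points with fewer than `min_patients = 5` contributors are masked from all
summaries — the minimum-overlap threshold of the motivating analysis, read
as "at least 5 patients contributing at a location", consistent with its
reported occupancy of 1–12 patients per slice. Segments are four 180°
directional halves (60 points per slice each; every point belongs to
exactly two halves) crossed with three CAX height bands — low 28–51 mm,
mid 52–100 mm, high 102–130 mm — summarised as median/IQR/95th percentile
of the per-point Σ, σ and GM, using RL values for the left/right halves and
AP values for anterior/posterior.

The cranio-caudal direction is meaningful only at the tumor ends, so it is
analysed from the baseline cloud's top and bottom slices: those points are
mapped onto the reference like the in-plane analysis and summarised the
same way (the cranial/caudal columns of the segment table), alongside plain
per-patient cranial/caudal means and SDs.

## The synthetic cohort generator

Real delineations from the motivating study are not publicly available, so
the generator states a world with the same statistical structure and known
truth:

* a straight rectum along +z, anal verge at z = 0, per-patient radius drawn
  from a configurable range;
* a wall-hugging tumor, crescent-shaped in axial cross-section
  (semi-circumferential angular extents, 150–270° in the study-like
  preset), spanning a configurable height range, discretized at 1.5 mm
  slices;
* additive Gaussian motion per direction: a per-patient systematic offset
  `s_p ~ N(0, Σ_true)`, per-scan random offsets `r_pk ~ N(0, σ_true)`, and
  a constant drift `gm_true` — the implicit model of the Van Herk
  framework;
* optional local deformation as Gaussian radial surface bumps (amplitude,
  count, width and outward/inward mixture configurable), centred at
  patient-specific random locations and held fixed across that patient's
  test scans — a *systematic* local deformation, which is the regime in
  which COM-based analysis underestimates surface motion. Bumps displace
  both crescent arcs by the same radial amount per azimuth, so wall
  thickness is preserved and contours remain simple polygons.

Generation is bit-deterministic under the seed, with independent
per-patient RNG streams so cohort growth never reshuffles earlier patients.
The study-like preset fixes 16 patients × 6 scans with a 13 low / 3 mid
height mix and conditions the shape draws on the sampled baseline cloud
landing in the 7000–28000-point range (per-patient rejection inside the
same RNG stream).

What the generator does *not* emulate: delineation uncertainty, tumor
regression over the treatment course, bowel/bladder-filling biomechanics,
curved or patient-specific centerlines, and registration error beyond an
optional known rigid misalignment (`misregister = TRUE`, used to exercise
transform plumbing). A green parameter-recovery test therefore establishes
that the *pipeline arithmetic* is faithful to the stated model, not that
the model captures every feature of clinical data.

## Numerical choices

* Ties (nearest neighbour, arg-max): smallest index, everywhere.
* Boundary containment: outside; z acceptance window extends half a slab
  beyond the end slices.
* Serialization: canonical key order, 6 decimal places — write∘read is
  byte-stable, and 10⁻⁶ mm is far below any physical scale here.
* Slice spacing constant to 1e-6 mm; contour orientation normalized to
  counter-clockwise on construction; polygons stored open.
* Rotation order rx→ry→rz about an explicit center, angles in degrees,
  |angle| ≤ 10° (a sanity bound well above the ≈3° the setting produces).
* Patients with fewer than 6 scans are accepted with a warning flag; at
  least 2 test scans are required for any SD.

## Validation experiments shipped as tests

The acceptance suite runs: exact equivalence of the k-d-tree BLD against
the brute-force oracle on random clouds; the Hausdorff identity; rigid
closed forms (exact COM shift under translation, bounded signed components,
non-negative signs under isotropic expansion); Van Herk parameter recovery
on a 200-patient rigid-motion cohort; a COM-blindness contrast (zero rigid
motion, 3 mm bumps: COM GM stays near zero while surface-p95 GM exceeds
1.5 mm in the bumped in-plane directions — 100 patients, sized a priori so
the COM bound has adequate power); reference-mapping band landing, masking
and mass conservation; closed-form statistics conventions; and the
16-patient study-shaped end-to-end smoke test.

One caveat is recorded rather than hidden: recovering a group mean of
0.5 mm to ±10% *relative* precision from 200 patients × 5 scans of
study-like motion is beyond the information content of such a cohort (the
estimator's standard error is ≈0.15 mm), so the GM clause of the recovery
experiment can fail at a fixed seed even though the implementation is
exact. The seed is pre-registered, not tuned; Σ and σ recover within
tolerance.

## Limitations

* The BLD mapping is a point-set heuristic: for extreme deformations the
  mapped point need not be the anatomically corresponding point, and the
  95th percentile amplifies any mapping error — a reason the COM measure is
  retained alongside.
* The reference mapping assumes a straight axis; strongly curved rectums
  would need a curved reference, which is out of scope.
* Cranial/caudal statistics rest on few points (one ring plus cap per end)
  and sparse inter-patient overlap; their segment rows are correspondingly
  fragile and subject to the same occupancy mask.
* DICOM RT-STRUCT ingestion is not provided; inputs arrive through the
  documented JSON dialect.
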