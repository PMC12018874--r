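# rectvar

Interfraction positional variation of rectal primary tumor volumes.

Rectal tumors (GTVp) delineated on repeat scans of the same patient shift
and deform from day to day relative to the bony anatomy used for treatment
setup. `rectvar` quantifies that variation for radiotherapy margin work
with two complementary measures against a baseline scan:

* **COM displacement** — the shift of the structure's volume centroid, a
  rigid-motion surrogate;
* **BLD surface displacement** — per baseline surface point, the
  *bidirectional local distance*: candidates are the forward nearest
  neighbour on the test surface plus every test point reverse-assigned to
  the baseline point, and the mapped displacement is the candidate at the
  largest distance. Vectors are decomposed into signed RL/AP/CC components
  (in-plane: + out of / − into the baseline structure; CC: + away from the
  COM plane).

Per patient, per-point means and SDs across repeat scans are summarised by
their 95th percentiles; across patients the package computes the Van Herk
decomposition

    GM = mean_p( mean_p,k ),  Σ = SD_p( mean_p,k ),  σ = RMS_p( SD_p,k )

per direction (systematic, random and group-mean errors, mm) for both
methods, and maps per-patient surface statistics onto a common reference
rectum (120 points per slice, CAX distance from the anal verge) with
directional halves × height bands (low 28–51, mid 52–100, high 102–130 mm)
plus a cranial/caudal end-slice analysis. A seeded synthetic-cohort
generator with known ground truth (per-patient systematic offsets, per-scan
random offsets, group drift, local Gaussian surface bumps on a tubular
rectum) supports validation; the study's own MRI delineations are not
publicly available.

## Worked example

```r
library(rectvar)

cohort <- generate_cohort(cohort_config(
  n_patients = 8, n_test_scans = 5,
  Sigma_true_mm = c(1.3, 1.7, 2.0),   # RL, AP, CC
  sigma_true_mm = c(1.2, 2.1, 2.2),
  gm_true_mm    = c(0.5, -0.3, -0.3),
  bump_amplitude_mm = 2, bump_count = 3, bump_sigma_mm = 8,
  seed = 2026))

fit <- positional_variation(cohort, spacing_mm = 2, min_patients = 3)
fit
#> Interfraction positional variation: 8 patients (both)
#>
#> Population errors (com method, 8 patients):
#>                         RL   AP   CC
#> Systematic Sigma (mm) 1.46 2.18 2.37
#> Random sigma (mm)     1.33 1.81 1.65
#> Group mean (mm)       0.08 0.18 0.25
#>
#> Population errors (surface_p95 method, 8 patients):
#>                         RL   AP   CC
#> Systematic Sigma (mm) 0.53 0.96 1.18
#> Random sigma (mm)     1.95 2.47 1.79
#> Group mean (mm)       1.86 1.89 1.12
```

The COM rows recover the configured rigid-motion magnitudes (Σ ≈ 1.3–2.0,
σ ≈ 1.2–2.2 mm up to 8-patient Monte-Carlo noise, GM near its small true
values). The surface rows show the characteristic pattern of
95th-percentile surface statistics: smaller Σ and larger σ than the COM
path, and clearly positive GM — the outward local deformations (2 mm bumps)
that barely move the centroid. `coef(fit)` returns these six rows as a
matrix; `fit$segments` holds the per-location summaries, e.g. the low band:

```r
subset(as.data.frame(fit$segments), band == "low",
       select = c(direction, n_points, median_Sigma_mm, median_gm_mm))
#>    direction n_points median_Sigma_mm median_gm_mm
#> 1   anterior      407           1.521        0.049
#> 4  posterior      220           0.628       -0.047
#> 7      right      198           0.914        0.135
#> 10      left      429           0.868       -0.066
```

`plot(fit)` draws azimuth × CAX maps of the inter-patient errors with
under-occupied reference points masked in black.

Cohorts round-trip through a canonical JSON dialect (`write_patient()` /
`read_patient()`), and the disk pipeline `pv_simulate()` → `pv_analyze()`
→ `pv_aggregate()` (also exposed via `inst/scripts/pv-pipeline.R`) writes
per-patient summaries, a population-errors table, the reference map and
segment tables as CSV with run manifests; outputs are byte-deterministic
for a given configuration and seed.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the 16-patient study-shaped synthetic preset from the given
seed and runs the full simulate → analyze → aggregate pipeline at 1 mm
sampling (clouds of 7000–28000 points per tumor), printing the resulting
population error table and writing the JSON report to `--out`.
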