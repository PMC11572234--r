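# wmhshape

Three-dimensional shape analysis of white matter hyperintensities (WMH),
the hallmark MRI lesion of cerebral small vessel disease in older adults.
WMH *volume* is the standard quantitative marker but is disease-unspecific;
lesion *shape* — how irregular, fragmented or elongated a lesion is —
carries additional information about the underlying vascular pathology and
about who will progress. `wmhshape` implements the full analysis path from
co-registered binary masks to a marker-by-outcome regression report, plus a
synthetic phantom and cohort generator so that every stage is testable
without clinical data.

For whom: imaging scientists with ventricle + WMH segmentations (NIfTI)
who want per-participant shape markers, and methodologists who want a
reproducible, oracle-tested reference implementation of the markers.

## The markers

Lesions are first typed by distance to the lateral ventricles, using 3 mm
and 10 mm inflations of the ventricle mask (exact anisotropic Euclidean
distance transform): a connected component with no voxel within 3 mm of the
ventricular wall is **deep**; one within 3 mm that stays inside 10 mm is
**periventricular**; one that also extends beyond 10 mm is **confluent**.
Periventricular and confluent lesions are merged for shape analysis.

Per lesion, with volume $V$, surface area $S$ (sub-voxel isosurface) and
convex hull volume/area $V_H$, $S_H$ (hull of voxel corner points):

| marker | formula | direction |
|---|---|---|
| solidity | $V/V_H$ | lower = more irregular |
| convexity | $S_H/S$ | lower = more irregular |
| concavity index | $(2-\mathrm{convexity})+(1-\mathrm{solidity})$ | higher = more irregular |
| fractal dimension | box-counting slope of $\log N(s)$ vs $\log(1/s)$ | higher = more complex |
| eccentricity | $\sqrt{1-\lambda_3/\lambda_1}$ (second moments) | higher = more elongated |

Solidity, convexity, concavity index and fractal dimension are computed for
periventricular/confluent WMH; eccentricity and fractal dimension for deep
WMH; all are averaged per participant. Baseline markers are then related to
5-year outcomes: linear models of WMH-volume change ($B$ per 1-SD,
age/sex/ICV-adjusted) and logistic models of new subcortical infarcts,
microbleeds, enlarged perivascular spaces, cerebellar infarcts and cortical
infarcts (OR per 1-SD, age/sex-adjusted, at-risk population).

## Worked example

Render a phantom participant (two ventricle lobes, three lesions of
varying irregularity), type the lesions, and extract markers:

```r
library(wmhshape)

g <- vol_geom(c(96, 96, 48), spacing = c(1, 1, 2))   # mm
spec <- phantom_spec(geometry = g, lesions = list(
  lesion_spec(c(63, 30, 46), c(3, 3, 3),  kappa = 0.2, seed = 1),
  lesion_spec(c(66, 65, 46), c(10, 4, 4), kappa = 0.5, seed = 2),
  lesion_spec(c(85, 20, 46), c(5, 3, 3),  kappa = 0.1, seed = 3)))
imgs <- make_participant_images(spec)

cls <- classify_wmh(imgs$wmh, imgs$ventricles)
cls$table
#>   id            type n_voxels volume_ml
#> 1  1       confluent     3003     6.006
#> 2  2 periventricular      177     0.354
#> 3  3            deep      174     0.348

extract_markers(imgs$wmh, imgs$ventricles)
#>   n_pvc n_deep n_skipped solidity convexity concavity_index fd_pvc eccentricity
#> 1     2      1         0    0.636     1.279           1.084  2.211        0.823
#>   fd_deep wmh_volume_ml volume_pvc_ml volume_deep_ml
#> 1   2.318         6.708          6.36          0.348
```

The two periventricular/confluent lesions average solidity 0.64 (the big
kappa = 0.5 lesion is far from space-filling) and the single deep lesion is
strongly elongated (eccentricity 0.82). Simulate a full cohort with
reference-matched distributions and fit the association grid:

```r
cohort <- simulate_cohort(cohort_config(), seed = 1)   # n = 2297
res <- run_association(cohort)
tab <- build_results_table(res)
tab[c("concavity_index", "eccentricity"), c("delta_wmh", "microbleed_new")]
#>                 delta_wmh              microbleed_new
#> concavity_index 2.24 (1.90-2.59)***    1.11 (0.97-1.26)
#> eccentricity    -1.95 (-2.30--1.60)*** 1.08 (0.95-1.23)
```

Each linear cell is B (95% CI) in ml of extra 5-year WMH growth per 1-SD
of the raw marker: the simulated cohort was generated with a concavity
slope of 2.28 ml/SD and the fit recovers 2.24 (2.28 is inside the CI).
Logistic cells are OR (95% CI) per 1-SD with solidity, convexity and
eccentricity inverted so every OR reads "per 1-SD more irregular / less
elongated". Stars mark p < 0.05 / 0.01 / 0.001.

A command-line front end over the same functions lives at
`inst/cli/wmhshape.R`:

```sh
Rscript inst/cli/wmhshape.R run --out runs/demo --n 20 --seed 1
Rscript inst/cli/wmhshape.R classify --wmh P01_wmh.nii.gz --vent P01_vent.nii.gz --out-prefix P01
```

`run` executes simulate -> classify -> extract -> associate and writes CSVs,
typed NIfTI masks, a text report and a JSON manifest (config fingerprint,
seed, per-stage counts) under `--out`.

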