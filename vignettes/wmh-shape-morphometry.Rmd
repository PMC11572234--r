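---
title: "Quantifying white matter hyperintensity shape in 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white matter hyperintensity shape in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

White matter hyperintensities (WMH) are the most common MRI signature of
cerebral small vessel disease in older adults. Total WMH volume is the
standard quantitative marker, but it is crude: two lesion loads of equal
volume can look very different, and histopathology links smooth versus
irregular lesion boundaries to different tissue damage. This package
quantifies the *shape* of WMH lesions on co-registered binary masks and
relates baseline shape to longitudinal cerebrovascular outcomes.

The pipeline has four stages:

1. **Masks and geometry.** Each participant contributes a lateral-ventricle
   mask and a WMH mask on the same grid (NIfTI; anisotropic spacing such as
   0.86 x 0.86 x 3.00 mm is the norm for FLAIR-based segmentations). All
   geometry is computed in physical millimetres.
2. **Typing.** The ventricle mask is inflated by 3 mm and 10 mm (exact
   Euclidean distance thresholding, not iterated structuring elements, so
   anisotropic voxels are handled exactly). A WMH connected component that
   does not touch the 3 mm inflation is *deep*; one that touches it and
   stays inside the 10 mm inflation is *periventricular*; one that touches
   it and extends beyond 10 mm is *confluent*. Periventricular and
   confluent lesions overlap spatially and are merged for shape analysis.
3. **Shape markers.** Per lesion: solidity, convexity, concavity index and
   box-counting fractal dimension for periventricular/confluent WMH;
   eccentricity and fractal dimension for deep WMH. Markers are averaged
   (unweighted) per participant and type.
4. **Association models.** Linear regression of WMH-volume change on each
   standardized baseline marker (adjusted for age, sex and mean
   intracranial volume) and logistic regression of each new-lesion outcome
   (adjusted for age and sex), reported as a marker-by-outcome grid of
   B / OR with 95% confidence intervals.

## Shape markers: definitions and numerical choices

Let $V$ and $S$ be a lesion's volume and surface area, and $V_H$, $S_H$
those of its convex hull.

* **Solidity** $= V / V_H$. Lower values mean a less space-filling,
  more irregular lesion.
* **Convexity** $= S_H / S$. Surface roughness grows $S$ while barely
  changing $S_H$, so lower values mean a rougher boundary.
* **Concavity index** $= (2 - \mathrm{convexity}) + (1 - \mathrm{solidity})$,
  a composite of the two deficits: exactly 1 for an ideal convex body and
  strictly increasing as either ratio falls. The formula is a named,
  swappable strategy (`concavity_index(..., formula = )`) so an alternative
  composite can be substituted without touching callers.
* **Fractal dimension**: the least-squares slope of $\log N(s)$ against
  $\log (1/s)$, where $N(s)$ counts occupied cubic boxes of side $s$
  voxels on a power-of-two ladder anchored at the lesion bounding-box
  corner. The ladder runs to half the bounding-box side (extended to at
  least three scales for small lesions, never beyond the side). Counting is
  done in index space at the native grid: a solid cube of side $2^k$ gives
  exactly 3, a one-voxel plane 2 and a line 1 whenever the box sizes divide
  the side, and the slope is clamped to $[0, 3]$.
* **Eccentricity** $= \sqrt{1 - \lambda_3 / \lambda_1}$ from the
  eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ of the second central
  moments of the voxel-centre coordinates (mm), with each voxel
  contributing its own box moment ($\mathrm{spacing}^2/12$) so thin rods
  keep a positive minor axis and stay strictly below 1. A single voxel is
  defined as eccentricity 0 on an isotropic grid.

**Surface area** is measured on a sub-voxel isosurface (marching
tetrahedra at level 0.5) after smoothing the binary occupancy field with a
small Gaussian, $\sigma = 0.7$ voxels. The sigma was calibrated once
against the analytic sphere: raw (midpoint) isosurfaces of binary volumes
overestimate smooth surfaces by roughly a quarter and voxel-face counting
by half, while $\sigma = 0.7$ brings a radius-10 digitized ball within 1%
of $4\pi r^2$ without erasing small lesions (for lesions so small that
smoothing removes the 0.5 level set, the sigma is halved until the surface
survives). Voxel-face counting remains available as
`surface_area(method = "voxel_faces")` for sensitivity checks. A
consequence worth knowing: surface detail narrower than about two voxels
is treated as discretization noise and does not register in $S$.

**Convex hulls** are built over the corner points of the lesion's surface
voxels, so a single voxel already has its full box as hull and
$V_H \ge V$ (hence solidity $\le 1$) holds *by construction* — the hull of
the voxel union contains the voxel union. The cost of this choice is a
digitization bias on smooth bodies: the staircase corners of a
centre-digitized ball of radius 10 voxels genuinely protrude, and the hull
of that solid measures about 1.18x the analytic ball volume (verified
against an independent Qhull implementation). Centre-point hulls would sit
closer to the analytic value for balls but *underestimate* the solid and
break hull dominance (solidity above 1 for convex digitized bodies), which
we consider the worse failure mode. Convexity and solidity are therefore
comparable *between* lesions measured at the same resolution, not
absolutely calibrated against continuum solids; the irregularity orderings
the package is validated on are unaffected.

Lesions below `min_voxels = 2` voxels are excluded from shape scoring
(a single voxel spans no usable box-counting scale); their count is
reported per participant.

## The synthetic data

No imaging data ships with the package; a generator stands in for it.

**Phantoms.** `make_ventricles()` renders two elongated ellipsoidal lobes
(defaults: semi-axes 5 x 28 x 7 mm, 18 mm apart) as a ventricle stand-in.
`make_lesion()` renders a star-convex lesion: the radius along direction
$u$ is the ellipsoid radius times $1 + \kappa \cdot 0.36 \, g(u)$, clipped
to $[0.45, 1.2]$, where $g$ is a fixed band-limited zero-mean noise field
(60 random plane-wave harmonics, frequencies log-uniform on 3-20 with a
$1/\sqrt{f}$ spectrum, unit variance) drawn from the lesion seed, and the
base semi-axes additionally grow by $1 + 2.4\kappa$. $\kappa = 0$
reproduces the exact digitized ellipsoid; star-convexity keeps every
lesion connected; everything is byte-reproducible from the seed.

The extent coupling deserves a note, because the obvious generator —
roughen the radius at fixed size — fails to reproduce the empirical marker
pattern. For solid box counting at a lesion's native scale the fitted
slope is approximately $3 + \log(c \cdot V/L^3)/\log(L/2)$ ($L$ the
bounding-box side), so at fixed extent the fractal dimension *cannot* rise
while solidity falls: pure radial roughening lowered both in every
parameterization we examined. In cohort data, irregular confluent lesions
are not merely rougher — they are larger and more sprawling, and that size
channel is what carries their higher fractal dimension. Coupling $\kappa$
to spatial extent reproduces exactly this: along
$\kappa \in \{0, .2, .4, .6, .8\}$ (20 seeds per step) median solidity and
convexity decrease strictly while median concavity index and fractal
dimension increase strictly, and the ordering was checked for stability on
four independent seed banks before being frozen. The calibration
experiment uses base semi-axes (9, 7, 6) mm on a 96^3 1 mm grid; the
default phantom grid elsewhere is 96 x 96 x 48 at 1 x 1 x 2 mm to keep
tests fast, with the protocol-like 0.86 x 0.86 x 3.0 mm geometry available
for fixtures.

`make_participant_images()` assembles ventricles plus lesions, subtracts
ventricle voxels from the WMH mask, and records for each lesion its
intended type under the 3/10 mm rule together with the margin (mm) to the
nearest decision boundary — computed from the lesion's own voxel distances,
independent of the component-based classifier it validates. Lesions whose
margin exceeds one voxel diagonal must classify identically to their truth
label; the suite checks 100% agreement there.

**Cohort tables.** `simulate_cohort()` draws age (74.5 ± 4.7 years), sex
(61% female), six markers with means/SDs taken from the shipped reference
summary of the source cohort (e.g. solidity 0.19 ± 0.12), log-normal
baseline WMH volume matching mean 16.56 / SD 17.21 ml, and binary outcomes
from logistic models with configurable odds ratios per 1-SD of a linked
marker plus age and sex terms (intercepts calibrated by root-finding so
marginal incidences hit their targets, e.g. 13% new microbleeds). The
WMH-volume change is exactly linear in the marker z-scores with Gaussian
noise; follow-up volume is baseline plus that change *without* flooring at
zero, because censoring the rare negative follow-up volume (about 1% of
draws) measurably degrades the confidence-interval coverage the generator
exists to validate. Markers are drawn independently of each other — real
markers are strongly correlated — and the cohort table carries no spatial
information; passing the statistical suite therefore shows correctness of
the estimation machinery, not realism of joint marker distributions.

## Statistical conventions

Predictors are transformed in this order: solidity and baseline WMH volume
are multiplied by 100 and natural-log transformed (both are right-skewed);
every predictor is z-scored over its analysis sample; and solidity,
convexity and eccentricity are sign-flipped ("inverted") for the logistic
models so that every reported OR reads "per 1-SD more irregular (or less
elongated)". Inversion is implemented as a sign flip of the standardized
predictor, which leaves |z| statistics and p-values exactly unchanged and
maps the OR to its reciprocal; a config switch (`invert_scope`) extends it
to the linear models or disables it. Linear models use OLS with exact
t-quantile confidence intervals; logistic models use IRLS (tolerance 1e-8,
at most 50 iterations) with Wald intervals $\exp(\beta \pm 1.96\,SE)$, and
apparent separation is flagged rather than silently returned. New-lesion
models by default exclude participants already positive for that lesion
type at baseline (`at_risk_only = TRUE`), since "new lesion" is only
defined for the at-risk population; the alternative is selectable because
the published table cannot adjudicate the choice. Participants lacking a
lesion type have missing markers and drop case-wise from that marker's
models, so the reported n differs between marker families. No
multiple-testing adjustment is applied; p < 0.05 is starred in the report,
matching the source analysis.

## Problem sizes and runtime

The test suite and the acceptance script are sized for a single CPU:
random-mask oracles at 12-16^3 voxels, canonical solids at up to 68^3, the
irregularity ladder at 100 lesions on 96^3 grids, phantom pipelines with
4-20 participants at 64 x 64 x 32 to 96 x 96 x 48, and the statistical
recovery runs at n = 2300 with 100 coverage replicates and 400 permutation
replicates.

## Known limitations

* Corner-point hulls carry the digitization bias discussed above; marker
  values are resolution-dependent and should only be compared within one
  acquisition protocol.
* The surface estimator suppresses sub-voxel-scale spikes; markers on
  lesions only a few voxels across are dominated by discretization.
* Box-counting fractal dimension conflates boundary complexity with lesion
  extent; the generator models this deliberately, but users should not
  interpret FD differences between lesions of very different size as pure
  shape differences.
* The cohort generator emulates marginal distributions and configured
  effects, not registration error, scanner noise, segmentation bias, or
  marker-marker correlation.
* The pipeline consumes masks; segmentation itself (FLAIR lesion
  segmentation, T1 ventricle segmentation) is out of scope.
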