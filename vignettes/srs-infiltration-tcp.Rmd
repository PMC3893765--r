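---
title: "Evaluating radiosurgery plans under tumour-cell infiltration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating radiosurgery plans under tumour-cell infiltration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srstcp)
```

## The problem

Stereotactic radiosurgery (SRS) delivers a high single-fraction dose to an
intracranial target with a very steep dose falloff outside it. Plan quality
is usually judged geometrically — how well the prescription isodose conforms
to the delineated target. That view silently assumes every tumour cell sits
inside the contour. Several brain tumours treated with SRS (anaplastic
astrocytoma and other invasive gliomas) infiltrate the surrounding brain:
autopsy–MRI comparisons in glioblastoma have found tumour cells 6–14 mm
beyond the imaging boundary. If clonogenic cells sit in the dose-gradient
region just outside the target, the steep falloff that protects normal
tissue also protects them.

`srstcp` quantifies this trade-off. It evaluates a 3D dose distribution
against a voxelized Poisson model of tumour control under explicit
assumptions about where clonogenic cells are.

## The model

For doses $D_i$ (Gy) in voxels $i$ of volume $V_i$ (mm³) carrying an
initial clonogen density $\rho_i$ (cells/mm³), the expected number of
clonogens surviving a single fraction is

$$ N_s \;=\; \sum_i \rho_i\, V_i\, e^{-\alpha D_i - \beta D_i^2}, $$

using the linear-quadratic (LQ) survival model, and the tumour control
probability is the Poisson probability that no clonogen survives:

$$ \mathrm{TCP} \;=\; e^{-N_s}. $$

The sum applies to any target shape and dose distribution. There is no
proliferation/repopulation term: treatment is a single fraction. The LQ
model's validity at very large doses is debated, but the decisive
contributions here come from the *fringe* around the target, where doses
are moderate and LQ is uncontroversial; in-target survival at 20–32 Gy is
negligible either way.

Parameter defaults, with units and origin:

| parameter | default | meaning |
|---|---|---|
| $\alpha$ | 0.24 Gy⁻¹ | LQ linear radiosensitivity (glioblastoma literature value) |
| $\beta$ | 0.03 Gy⁻² | LQ quadratic term; $\alpha/\beta$ = 8 Gy is derived, not enforced |
| clonogens | 10⁶ | in-target clonogen number, giving a TCP-curve slope typical of gliomas |
| prescription | 16 Gy at the 50 % isodose | Gamma-Knife-style prescription; grid maximum is therefore 32 Gy |
| $d_{\max}$ | 10 mm | maximum infiltration distance (average of the 6–14 mm autopsy range) |
| decay length | 1 mm | $f(d) = e^{-d/\ell}$; the source model states $f(d)=e^{-d}$ without a unit, we read $d$ in mm and expose $\ell$ because it controls the infiltrating burden |

## Infiltration scenarios

All scenarios share the uniform in-target density
$\rho_0 = \text{clonogens}/V_\text{target}$ (constant in-target density is
an explicit assumption; imaging-derived heterogeneity is out of scope).
They differ outside the target, as a function of the distance $d$ (mm) from
each voxel centre to the nearest target voxel:

* **none** — $\rho = 0$ outside. The classical, geometry-only view.
* **continuous** — $\rho(d) = \rho_0 e^{-d/\ell}$ for $0 < d \le d_{\max}$,
  0 beyond. A smooth margin of decreasing cell density.
* **heterogeneous** — each outside voxel with $d \le d_{\max}$ is occupied
  independently with probability $e^{-d/\ell}$; occupied voxels carry the
  full density $\rho_0$. The per-voxel *expectation* equals the continuous
  scenario, so the two agree on average while the realizations are patchy.
  No published stochastic law exists for astrocytoma infiltration; Bernoulli
  occupancy is the minimal model with the right expectation structure, and
  is the package's own design choice. It is seed-deterministic, and the
  evaluator can average over seeds (`replicates`).

Infiltrating cells are *additional* to the 10⁶ in-target cells: only the
in-target population is normalized. This is documented because it affects
absolute TCP values.

## Geometry

* **Distance maps** use the exact separable Euclidean distance transform
  with anisotropic spacing, measured voxel-centre to nearest target voxel
  centre. Centre-to-centre (rather than surface) distance is well defined
  on digitized masks and matches the resolution at which the TCP sum is
  evaluated; it is the convention behind every number the package reports.
* **Resampling.** Dose grids are redefined onto the structure grid by
  trilinear interpolation at structure voxel centres (exact for affine
  fields). The interpolation scheme is a package choice — treatment
  planning exports specify only that grids are redefined. Structure voxels
  outside the dose grid's physical extent get 0 Gy with a logged count:
  SRS dose grids are local and the surrounding tissue genuinely receives
  negligible dose.
* **Coordinates.** `origin` is the physical position of the *centre* of
  the first voxel; voxel (i, j, k) (1-based in R) sits at
  `origin + (c(i,j,k) - 1) * spacing`. Fixed and tested for I/O
  interoperability (NRRD round-trips exactly; NIfTI is read support only,
  restricted to grid-aligned orientations).
* **Conformity index** is the coverage form: the fraction of target volume
  receiving at least the prescription dose, with ties at exactly the
  prescription counted as covered. Selectivity-style indices are
  deliberately not implemented.

## Synthetic plans

Real Leksell shot profiles are not modelled. Synthetic plans use Gaussian
kernels summed over shots and renormalized so the *grid maximum* equals
prescription/isodose-fraction — normalizing to the sampled maximum mirrors
what a planning-system export contains. Gaussians reproduce the property
the framework needs — a steep, closed-form falloff with a 50 % isodose
radius $r_{50} = \sigma\sqrt{2\ln 2}$ — which makes isodose radii testable
analytically. They do not emulate collimator sizes, sector weights or
treatment times, so passing tests demonstrate correctness of the
*evaluation machinery*, not fidelity to any clinical case.

`fitShotToTarget()` places one isotropic shot at the target centroid and
sizes $\sigma$ so the prescription isodose radius equals the target's
equivalent-sphere radius times a **coverage factor**: 1.0 puts the 16 Gy
surface exactly at the (equivalent) target surface, >1 creates margin,
<1 under-covers.

## What the framework shows

```{r contrast}
mask <- makeEllipsoidMask(c(0, 0, 0), 10, shape = c(55, 55, 55),
                          spacing = 1, origin = rep(-27, 3))
dose <- composeDose(fitShotToTarget(mask, coverageFactor = 1.3))
dmap <- distanceToTarget(mask)

none <- computeTCP(dose, clonogenDensity(mask, config = infiltrationConfig("none")))
cont <- computeTCP(dose, clonogenDensity(mask, dmap, infiltrationConfig("continuous")))
c(none = tcpPercent(none, 0), continuous = tcpPercent(cont, 0))
```

With a well-covering plan (coverage factor 1.3, minimum target dose
≈ 21 Gy) the no-infiltration TCP rounds to 100 %, while the identical plan
under continuous infiltration rounds to 0 % — about `r round(expectedSurvivors(cont))`
expected surviving clonogens sit in the fringe. The mechanism is volume:
a 10 mm margin around a 2 cm sphere holds $((20^3-10^3)/10^3) = 7$ times
the target volume, so even densities down-weighted by $e^{-d}$ integrate
to a large surviving population where the dose has fallen to 6–17 Gy.
Adding clonogen density anywhere can only lower TCP, and raising dose
anywhere can only raise it — both monotonicities are enforced by tests.

## Numerical choices

* The TCP sum is accumulated in extended precision (R's long-double
  `sum()`); per-voxel survivor counts span ~20 orders of magnitude between
  the target core and the fringe. Tests require agreement with brute-force
  summation to 1e-12 relative.
* TCP underflows cleanly: $N_s \gtrsim 750$ gives exactly 0; $N_s = 0$
  gives exactly 1.
* The heterogeneous draw uses an isolated RNG stream (`set.seed` under a
  saved-and-restored `.Random.seed`), so library calls never perturb a
  caller's simulation.
* Degenerate inputs fail loudly: empty masks, negative doses or densities,
  geometry mismatches between dose/mask/distance grids, non-3D rasters and
  missing spacing metadata are all errors, not warnings.

## Problem sizes

The shipped checks run on desk-scale grids chosen as the smallest that
keep digitization error well inside the asserted tolerances: 55³ voxels at
1 mm for the scenario contrast (10 mm sphere plus the 10 mm fringe and
clearance), 89³ at 0.5 mm for the margin-volume ratio (digitized ratio
6.89 vs the analytic 7), ≤ 10³ voxels for brute-force oracle equivalence,
and 200 seeds for the Bernoulli-expectation check (three-standard-error
band). Larger clinical grids differ only in runtime.

## Limitations

* Infiltration is isotropic in distance; no white-matter-tract anisotropy,
  reaction–diffusion dynamics or imaging-derived density.
* Uniform in-target density; no contrast-uptake weighting.
* Single-fraction LQ survival only; no NTCP, no alternative high-dose
  survival models.
* No DICOM RT I/O and no contour rasterization: masks and doses enter as
  NRRD/NIfTI rasters or via the synthetic generator.
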