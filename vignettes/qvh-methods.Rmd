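---
title: "Quality-volume histogram dosimetry comparison: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-volume histogram dosimetry comparison: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvhdose)
```

## The problem

Radioembolization of liver tumours injects ⁹⁰Y-labelled microspheres
into the hepatic arterial tree. A simulation session with ⁹⁹ᵐTc-MAA
surrogate particles yields a *predictive* absorbed-dose matrix; the
post-treatment ⁹⁰Y PET/CT yields the dose actually delivered. DVH
indices of the two distributions often agree even when the spatial
patterns do not, because a DVH carries no spatial information. The QVH
methodology compares the two matrices voxel by voxel once they have
been brought onto a common grid.

## Model

For each in-VOI voxel of the aligned pair, the quality ratio is
$Q_i = \log_{10}(D_i^{post} / D_i^{pred})$. The log, rather than the
plain ratio, makes under- and over-delivery symmetric around zero:
swapping the two dosimetries flips the sign of every $Q_i$ and leaves
$|Q_i|$ unchanged.

The clinical weighting limits the analysis to dose levels where
discrepancies matter for resin-sphere treatment of metastatic
colorectal cancer. Each dose is scored by a trapezoid: weight 0 up to
10 Gy, linear rise to 1 at 40 Gy, 1 through 120 Gy, linear fall to 0 at
200 Gy. The voxel weight is the maximum of the predictive and
post-treatment scores, with one override: if one dose is below 40 Gy
while the other exceeds 120 Gy (strict inequalities), the weight is
forced to 1. This straddle rule exists precisely for voxels whose two
single weights both vanish — 5 Gy predicted against 250 Gy delivered is
the most clinically alarming voxel in the map, not an ignorable one.

The QVH is the distribution of $Q_i$ with each voxel contributing
(voxel volume × $W_i$); the quality factor
$QF = \sum_i |Q_i| W_i / \sum_i W_i$ summarizes its spread from zero.
Categories are assigned on half-open intervals: good $[0, 0.18)$,
acceptable $[0.18, 0.3)$, poor $[0.3, \infty)$. The cut-offs have an
analytic reading: a map uniformly lower than the other by a fraction
$f$ has $QF = -\log_{10}(1-f)$, so 0.18 and 0.3 correspond to 33% and
50% systematic reduction. We adopt the half-open convention (0.18 is
acceptable, 0.30 is poor) because it partitions the line without gaps;
the alternative reading that places 0.3 itself in "acceptable" differs
only on a measure-zero boundary.

Weighting is applied to the voxel's *volume contribution*, never to
$Q_i$ itself: a weight of ½ means half the voxel's volume participates
in the histogram, not that the measured discrepancy is halved. (Scaling
$Q_i$ by $W_i$ is a recognisable alternative; it conflates magnitude
of discrepancy with clinical relevance, so we do not offer it.)
Both a cumulative $|Q|$ curve and a signed differential histogram are
produced, since the cumulative form summarizes spread while the signed
form shows the direction of mis-delivery.

All four thresholds plus the straddle bounds live in `weight_spec()`
as configuration with the resin-sphere/mCRC defaults, because the
calibration must change for glass spheres or other histologies.

## Alignment frame

`align_dosimetry()` (used internally by `qvh(..., dvf = )`) reproduces
the clinical processing order: the predictive dose is deformed into the
post-treatment anatomy by applying a supplied displacement field, then
the post-treatment dose is trilinearly resampled onto the
deformed-predictive grid. The comparison therefore runs at the coarser
(simulation, ~5 mm) resolution; resampling fine PET onto the coarse MAA
grid attenuates residual mis-registration rather than inventing
high-frequency detail. Computing the deformable registration itself is
out of scope — the field is an input, produced by validated clinical
software; the package's responsibility is to apply it and to diagnose
it (Jacobian determinant of $x \mapsto x + u(x)$, which must stay
positive for an invertible, fold-free field).

Masks are resampled with nearest-neighbour only and dose with
trilinear only; the two methods are deliberately not interchangeable
(interpolating a binary mask manufactures partial membership,
nearest-neighbour dose aliases gradients), and `resample_to()` enforces
the pairing.

## Dose model

Predictive dosimetry follows the standard chain: net administered
activity (prepared − residual), distributed over voxels proportionally
to the MAA counts, integrated over the full mono-exponential physical
decay (microspheres are permanent implants), giving voxel
time-integrated activity $A_{net} \cdot c_i/\sum c \cdot T_{1/2}/\ln 2$.
Conversion to absorbed dose uses the **local deposition model**: every
decay deposits the ⁹⁰Y mean β energy in its own voxel, and dose is
energy over voxel mass at uniform density. This is the minimal
defensible model at PET/SPECT voxel sizes (the β range is comparable to
the voxel); kernel convolution and Monte Carlo transport are explicit
non-goals, and every dose grid produced this way is labelled
`"local-deposition"`.

Physical constants are configuration, not literals:
`y90_constants()` defaults to $T_{1/2} = 64.05$ h and mean β energy
0.9337 MeV/decay; tissue density defaults to 1.03 g/mL (soft tissue).
Against these constants, 1 GBq deposited in 1 kg of tissue gives
≈ 49.8 Gy, the usual rule-of-thumb check, which the test suite verifies
from the constants alone.

## DVH and index extraction

`compute_dvh()` uses binary voxel membership (each in-VOI voxel
contributes its full volume; no partial-volume weighting, consistent
with nearest-neighbour mask handling) and a default 1-Gy bin from 0 to
the maximum dose. $D_X$ — the minimum dose received by at least X% of
the volume — is read off the cumulative curve by linear interpolation
at fraction X/100, with two conventions fixed here because the
clinical workstations leave them unstated:

* when the curve equals X/100 exactly over a plateau of bins, the
  *lowest* dose of the plateau is taken ("minimum dose received by at
  least X%"); exact plateaus are measure-zero for continuous dose data;
* the interpolated value is capped at the maximum voxel dose, so a
  uniform VOI yields $D_X$ equal to that uniform dose instead of
  overshooting inside the final bin.

$D_{mean}$ is always the arithmetic mean of the raw voxel doses, never
a binned approximation. The property suite checks every index against
an inverse-ECDF order-statistics oracle to within one bin width, on
1000 randomly generated VOIs.

## Segmentation

Lesions are delineated on an SUV volume by the PERCIST fixed threshold
1.5 × SUV_mean(background) + 2 SD(background), with the background
taken from a 3-cm reference sphere in healthy parenchyma. Two
conventions the source workflow left to the operator are fixed:
threshold comparison is inclusive (≥), and connected components use the
26-neighbourhood. Manual correction of lesions bridged by thin uptake
necks is replaced by an optional one-voxel morphological opening
(`open = TRUE`, off by default). The minimum lesion volume defaults to
0 mL — no silent filtering. TL is the boolean union of lesions, NTL the
liver minus TL; lesion voxels outside the liver are clipped (with a
warning) so TL and NTL always partition the liver exactly.

## Cohort statistics

Paired predictive/post comparisons of DVH indices gate on the
D'Agostino–Pearson omnibus normality test (α = 0.05) of the paired
differences: normal → paired t, otherwise Wilcoxon signed-rank. The
omnibus test is implemented in the package from the standard skewness
and kurtosis z-score transformations (no installed R package provides
it) and is validated in the tests against frozen reference statistics
from an independent implementation. Below n = 8 the kurtosis
transformation is unreliable, so the test reports NA and the caller
falls back to the rank branch — the conservative choice for tiny
groups.

Univariate QF associations dichotomize continuous covariates at the
cohort median, ties going to the "≤ median" group; two-level covariates
use unpaired t (equal-variance) or Mann-Whitney U, three-level use
one-way ANOVA or Kruskal-Wallis, all gated per group by the same
normality test. No multiple-testing correction is applied, mirroring a
univariate screening design; the output carries an explicit
`multiplicity_correction = "none"` flag. Quartiles use linear
interpolation between order statistics (R type 7). p-values print to
4 decimals, below 10⁻⁴ as "< 0.0001".

The processing-influence analysis bins in-VOI voxels by their original
dose (1-Gy bins, 0–250 Gy) and reports the mean processed-minus-original
difference per bin with a t-based 95% CI; empty bins are NA, not zero.

## The synthetic phantom

`generate_phantom()` emulates the *scale* of a clinical case — an
ellipsoidal liver of ≈ 1.4 L (semi-axes 90 × 70 × 54 mm), spherical
lesions of a few to ~17 mL, lesion mean dose 60 Gy and non-tumoural
mean dose 32 Gy, on a 96³ grid at 3 mm — values chosen once to sit in
the middle of the reported clinical ranges. Dose texture is log-normal
multiplicative noise (σ = 0.3 on the log scale, 15 mm correlation
length), non-negative by construction and mimicking heterogeneous
microsphere deposition; each region is rescaled after noising so its
mean dose hits the target exactly. All randomness flows through the
spec's single seed, and regeneration is bit-identical.

`apply_mismatch()` composes controllable discrepancy modes (global or
lesion-only scaling, hot/cold Gaussian spots, translation, blur) that
stand in for the clinical discrepancy sources — flow redirection,
particle-size differences, registration residue. `generate_dvf()`
produces smooth random displacement fields with a hard amplitude cap of
one third of the correlation length; the steepest slope of a smooth
feature of height $a$ and width $\sigma$ is ≈ 0.61 a/σ, so the cap
keeps the Jacobian well clear of zero, and every generated field is
verified fold-free before being returned.

What the phantom does *not* emulate: anatomically realistic organ
shapes, imaging physics (PSF, scatter, reconstruction artefacts),
breathing motion, or true registration error fields. Passing tests
therefore demonstrate the correctness of the computational chain on
controlled inputs — not the clinical accuracy of MAA-based prediction,
which only patient data can address.

## Numerical choices and degenerate inputs

* **Dose floor.** Both doses are clamped at 0.01 Gy before the log
  ratio, so Q is finite on zero-dose voxels. Such voxels carry weight 0
  unless the straddle rule fires — in which case |Q| is large and
  finite, which is exactly the intended signal.
* **Out-of-support resampling** fills 0 Gy (not NaN): downstream
  weighting assigns those voxels W = 0 (below 10 Gy), neutralizing
  border effects without NA bookkeeping.
* **Zero weighted volume.** A VOI whose doses all fall outside the
  clinically weighted range has no defined QF; the package returns NaN
  with category `"undefined"` and a warning rather than a misleading 0.
* **Jacobian borders.** Central differences in the interior, one-sided
  at grid borders; border voxels are excluded from the `fold_free`
  predicate since one-sided estimates are first-order only.
* **Signed QVH bins** are centred on multiples of the bin width (one
  bin centred at Q = 0), so a sign-symmetric map yields a
  mirror-symmetric histogram rather than an off-by-one-bin artefact.
* **QVH bin width** defaults to 0.01 in Q; display clips to [−2, 2].
* **Geometry checks** are exact-match for all voxelwise operations;
  alignment is never performed implicitly except through the documented
  `dvf` path of `qvh()`.

## Problem sizes used in the test suite

The suites run on phantoms of 32³–96³ voxels, 100-seed displacement
sweeps on 20³ grids, 1000 random VOIs of 397 voxels for the DVH oracle,
and 10 000 replicates for the null calibration of the two-group cohort
test — sizes chosen so the full suite completes in well under ten
minutes on one CPU while leaving each property with substantial
statistical force.

## Known limitations

* Axis-aligned grids only: no direction cosines; oblique NIfTI inputs
  are rejected at read time rather than silently mis-interpreted.
  Orientation normalization is assumed upstream.
* NIfTI is the only volume format (no NRRD or DICOM RT adapters).
* Local deposition with uniform density is the only dose engine; no
  CT-derived density, kernels, or Monte Carlo.
* The weighting calibration is specific to resin spheres in metastatic
  colorectal cancer; other products or histologies require a different
  `weight_spec()`.
* QF category cut-offs are first-estimate conventions, not
  outcome-validated decision thresholds; linking them to clinical
  endpoints is future work outside this package.
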