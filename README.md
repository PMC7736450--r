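# qvhdose

Voxel-by-voxel agreement analysis between **predictive** and
**post-treatment** absorbed-dose distributions in hepatic
radioembolization (SIRT) with ⁹⁰Y microspheres.

Before treatment, a ⁹⁹ᵐTc-MAA SPECT/CT simulation predicts where the
microspheres will lodge; after treatment, quantitative ⁹⁰Y PET/CT shows
where they actually went. Classical dose-volume histogram (DVH) indices
can agree even when the two spatial dose patterns differ badly, because
a DVH discards all spatial information. `qvhdose` implements the
**quality-volume histogram (QVH)** methodology, which compares the two
dose matrices voxel by voxel, for nuclear-medicine physicists and
dosimetrists evaluating how well simulation-based dosimetry predicted
the delivered dose.

## The method

For each voxel *i* of a volume of interest (VOI), with aligned
predictive dose $D_i^{pred}$ and post-treatment dose $D_i^{post}$ (Gy):

$$Q_i = \log_{10}\!\frac{D_i^{post}}{D_i^{pred}}$$

$Q_i = 0$ means perfect agreement; the log makes the distribution
symmetric under swapping the two dosimetries. Because ratios of two
clinically irrelevant doses (both < 10 Gy, or both > 200 Gy) can
produce large $|Q_i|$, each voxel receives a weight $W_i \in [0,1]$:
0 below 10 Gy, rising linearly to 1 at 40 Gy, 1 through 120 Gy, falling
to 0 at 200 Gy, combined across the two dose maps as
$W_i = \max(W_i^{pred}, W_i^{post})$ — overridden to $W_i = 1$ when one
dose is below 40 Gy while the other exceeds 120 Gy (a discrepancy that
must never be masked). The QVH is the distribution of $Q_i$ with each
voxel's volume contribution scaled by $W_i$, and is summarized by the
**quality factor**

$$QF = \frac{\sum_i |Q_i|\, W_i}{\sum_i W_i},$$

classified as **good** (QF < 0.18), **acceptable** (0.18 ≤ QF < 0.3) or
**poor** (QF ≥ 0.3); the two cut-offs correspond to one dose map being
systematically 33% and 50% lower than the other.

Around this core the package provides: DVH computation with the
D₉₀/D₇₀/D₅₀/D_mean/D₂₀ indices; PERCIST-threshold lesion delineation
(1.5 × SUV_mean + 2 SD) and tumoural / non-tumoural liver (TL/NTL) VOI
algebra; MAA-count → time-integrated-activity → absorbed-dose
conversion under a local deposition model; trilinear dose resampling,
displacement-field application and Jacobian folding diagnostics;
cohort-level statistics; NIfTI I/O; and a digital liver phantom
generator so the entire chain is testable without clinical data.

## Worked example

Generate a phantom, corrupt the "post-treatment" dose with a 30% dose
reduction inside the lesions plus a 5-mm blur, and compare:

```r
library(qvhdose)

ph   <- generate_phantom(phantom_spec(seed = 7))
post <- apply_mismatch(ph$dose, list(
  mismatch_spec("lesion_scale", 0.7),
  mismatch_spec("blur_mm", 5)), vois = ph$vois)

fit_tl <- qvh(ph$dose, post, ph$vois$TL)
fit_tl
#> Quality-volume histogram comparison
#>   VOI: TL
#>   QF = 0.1837 -> acceptable concordance
#>   weighted fraction of VOI: 1.000 (990 voxels)

summary(fit_tl)
#>   DVH indices (Gy):
#>                 D90  D70  D50 Dmean  D20
#> predictive     51.0 57.5 60.0  60.0 64.8
#> post_treatment 30.4 37.5 41.4  39.5 44.2

qvh(ph$dose, post, ph$vois$NTL)
#> Quality-volume histogram comparison
#>   VOI: NTL
#>   QF = 0.0502 -> good concordance
#>   weighted fraction of VOI: 0.714 (51850 voxels)
```

The tumoural liver lands in the *acceptable* band: the 30% lesion
under-delivery corresponds to $|Q| \approx 0.155$ on most lesion
voxels, inflated slightly by the blur. The non-tumoural liver, touched
only by the blur, stays *good* (QF ≈ 0.05). Only 71% of NTL voxels
carry weight — the rest sit below the 10-Gy clinical floor or on the
ramp. `plot(fit_tl)` draws the cumulative |Q| curve;
`plot(fit_tl, "signed")` shows the direction of the discrepancies;
`residuals(fit_tl)` returns the per-voxel Q map, exportable with
`q_map_export()`.

A command-line front end is installed with the package
(`system.file("scripts", "qvh", package = "qvhdose")`), with
`qvh compare --pred ... --post ... --voi ... --out report/` and
`qvh phantom --out dir/` subcommands over the same functions.

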