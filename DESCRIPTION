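Package: qvhdose
Title: Quality-Volume Histogram Analysis for Radioembolization Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-by-voxel comparison of predictive (99mTc-MAA SPECT/CT
    based) and post-treatment (90Y PET/CT based) absorbed-dose matrices
    from hepatic radioembolization, via the quality-volume histogram
    (QVH): the distribution over a volume of interest of the per-voxel
    log10 dose ratio, with clinically motivated dose weighting, summarized
    by a quality factor (QF) and classified as good, acceptable or poor
    concordance. Includes cumulative dose-volume histogram (DVH) indices
    (D90, D70, D50, Dmean, D20), PERCIST-threshold lesion delineation and
    tumoural / non-tumoural liver VOI algebra, conversion of MAA count
    maps to absorbed dose via time-integrated activity and a local
    deposition model, geometry-aware trilinear resampling and displacement
    field application with Jacobian folding diagnostics, cohort-level
    statistics, and a digital liver phantom generator for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
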