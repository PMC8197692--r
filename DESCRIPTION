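Package: phantomrad
Title: Phantom-Based Identification of Robust PET Radiomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-phantom simulation and analysis pipeline for assessing
    the robustness of positron emission tomography (PET) radiomic features
    against degrading factors: scanner system (point-spread function and
    noise), reconstruction voxel size, CT metal-artifact induced bias, and
    tumor segmentation method. Provides NEMA-IQ-like, heterogeneous-lesion
    and calibration-cylinder ("cheese") phantom generators with exact ground
    truth; fixed-threshold, contrast-oriented and region-growing
    segmentation; fixed-bin-width, fixed-bin-number and equal-probability
    intensity discretization plus wavelet band-pass filtering; a
    133-feature roster spanning SUV statistics, histogram, shape and
    GLCM/GLRLM/GLSZM/NGTDM texture families; and a paired robustness
    analysis based on Wilcoxon signed-rank tests, Bland-Altman bias and
    Bonferroni-corrected Spearman correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
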