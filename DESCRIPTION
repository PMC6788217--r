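Package: bandbold
Title: Band-Limited EEG Power Coupling with BOLD in Resting-State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking band-limited
    electrophysiological power to hemodynamic (BOLD fMRI) signals in
    resting-state brain networks such as the default mode network.
    Includes cleaning of EEG recorded in the MR environment (average
    artifact subtraction and optimal basis set removal of gradient and
    ballistocardiogram artifacts, bad-channel detection and interpolation,
    ICA-based rejection of ocular and myogenic components), eLORETA
    distributed source reconstruction, short-time Fourier band power on a
    cortical voxel grid, network detection by temporal ICA (EEG) and
    spatial ICA (fMRI) with MDL model-order selection and template
    matching, canonical-HRF-convolved voxelwise EEG-BOLD correlation,
    group-level mass-univariate inference with Benjamini-Yekutieli FDR
    control, and Pearson/Dice quantification of the spectral specificity
    of network maps. A synthetic EEG+BOLD generator with known ground
    truth exercises the full chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
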