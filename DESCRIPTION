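Package: specunmix
Title: Multispectral Absorbance Imaging with PCA-Derived Endmember Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing multispectral transmission images of thin
    tissue sections. Converts per-wavelength acquisitions (repeated frames,
    reference and sample) into Beer-Lambert absorbance cubes, decomposes them
    by principal component analysis in wavelength space, constructs endmember
    spectra from the eigenvector structure of the band covariance, estimates
    per-pixel non-negative abundances by NNLS, and summarises abundance maps
    statistically. Includes a synthetic eye-like phantom generator with known
    chromophore ground truth so every pipeline stage can be validated without
    microscope data, and a command-line front-end for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    tiff,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    png,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
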