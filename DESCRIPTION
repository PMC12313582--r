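Package: mrspipe
Title: Headless Pipeline Processing for In Vivo MR Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable node-graph pipeline engine for single-voxel and
    imaging magnetic resonance spectroscopy (MRS/MRSI) data, for 1H and
    X-nuclei acquisitions. Provides the standard preprocessing nodes (coil
    combination, frequency/phase alignment against the median spectrum,
    Klose eddy-current correction, outlier transient rejection, apodization,
    zero filling, overall/blocked/moving averaging, 3D k-space Hanning
    filtering, entropy-minimization phasing), spectral quality metrics (SNR
    and water linewidth), LCModel interchange formats (.RAW, control files,
    .COORD parsing), NIfTI-MRS reading and writing, pipeline serialization
    (.pipe), batch-mode orchestration, tissue-fraction water-concentration
    scaling, and CRLB-thresholded metabolite map construction. A
    deterministic synthetic-data generator emulates multi-transient,
    multi-channel free induction decays and 3D CSI grids so every pipeline
    can be exercised end-to-end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
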