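Package: fluorinfo
Title: Ground-Truth Simulation and Estimation of Spatial Information in
    Spike and Functional Fluorescence Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates place-coding neurons on a virtual linear track with
    exactly known spatial mutual information, generates inhomogeneous
    Poisson spike trains and indicator-kernel fluorescence (dF/F) traces
    from them, and quantifies how well rate-map (Skaggs-style), binned
    plug-in, and k-nearest-neighbor (KSG) mutual information estimators
    recover the ground truth from spikes versus fluorescence.  Includes
    library-scale bias experiments (kernel height/width and bin-count
    sweeps), significant-transient detection, place-field identification,
    and Bayesian position decoding.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
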