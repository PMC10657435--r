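Package: simsef
Title: Spatially Scheduled Exhaustive Fragmentation for TIMS-MS Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans mobility-multiplexed MS2 fragmentation experiments across an
    already-acquired trapped ion mobility (TIMS) MS1 imaging dataset and
    evaluates the resulting MS2 data. The scheduler distributes fragmentation
    events for multiple collision energies over the sample raster under
    isolation-purity, spatial-distance, pixel-intensity and quadrupole
    switch-time constraints, exports per-spot precursor lists, assigns acquired
    MS2 scans back to image features, merges replicates into consensus spectra
    and computes coverage and spectral-quality statistics. A synthetic data
    generator produces complete TIMS-MS1 imaging datasets with known ground
    truth for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
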