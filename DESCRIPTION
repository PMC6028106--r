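Package: neuropilr
Title: Dense-Reconstruction Morphometry of Cortical Neuropil
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphometry of densely reconstructed cortical layer-1 neuropil
    from volume electron microscopy: unbiased synapse density estimation in a
    counting brick with inclusion/exclusion planes, synapse size estimation
    from the maximum-diameter proxy with quadratic calibration against contact
    surface area, log-normal size-distribution fitting, perforation counting by
    mesh topology, neurite length/surface/volume densities in 5-micron
    sub-volumes, vesicle-to-membrane distance profiles, mitochondria census,
    and the group statistics (unpaired t, Kolmogorov-Smirnov, linear fits,
    slope comparison, excitation/inhibition ratio, percent change). Includes a
    synthetic neuropil generator with exact ground truth so every estimator is
    testable without image data, and the published per-animal measurement
    tables as fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
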