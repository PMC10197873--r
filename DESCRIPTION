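Package: sporesort
Title: Raman Spore-Sorting Gates and Cell-Envelope Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-cell Raman microspectroscopy based sorting of
    bacterial specialized resting cells (endospores, exospores, myxospores,
    cysts, akinetes) and for cryo-electron micrograph morphometry of their
    cell envelopes. Implements min-max spectrum normalization, spectral-window
    statistics, a catalog of phenotype-specific Raman marker bands (including
    the calcium dipicolinate endospore marker), the two-threshold
    waste/vegetative/endospore sorting gate built on the Pc and P_CaDPA
    ratios, width-averaged grey-value line profiles with half-depth envelope
    width measurement, and fully seeded synthetic spectrum and band-image
    generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
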