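Package: nanofa
Title: Quantification of Focal-Adhesion Nano-Architecture from
    Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for ultrafast PALM/dSTORM studies of focal
    adhesions: fluorophore photophysics fitting (stretched-exponential
    on-times, exponential photon counts, geometric blinking), localization
    merging and molecule grouping, Gaussian rendering, Voronoi-tessellation
    segmentation of adhesions and protein islands, Monte-Carlo correction
    of island sizes for localization error, FFT pair auto- and
    cross-correlation of island localizations, molecular copy-number
    arithmetic, picket-fence hop-diffusion trajectory analysis, and
    immobilization-site mapping, together with synthetic-data generators
    that emulate the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    polyclip,
    pracma,
    minpack.lm,
    jsonlite,
    tiff,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    spatstat.geom
Config/testthat/edition: 3
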