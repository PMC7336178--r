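Package: saxscan
Title: Scanning Small-Angle X-Ray Scattering Analysis of Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput scanning small-angle
    X-ray scattering (SAXS) of adherent cells: dark-field contrast images,
    adaptive (Bradley) plus per-cell Otsu segmentation into background,
    cytoplasm and nucleus regions of interest, azimuthal integration to
    radial intensity profiles, exposure normalization, background-matched
    power-law (Porod) fitting at window, per-cell and single-pattern level,
    X-ray dose estimation, orientation/anisotropy maps, and cell-population
    statistics (area quartiles, two-sample Kolmogorov-Smirnov comparisons).
    Includes a forward simulator of scanning-SAXS datasets -- elliptical
    cell phantoms with known power-law parameters, Poisson counting noise,
    a weakly anisotropic instrument background, and analytic sphere, rod
    and disc form factors -- so every stage is testable without beamline
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    minpack.lm,
    pracma,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
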