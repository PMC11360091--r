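Package: ssaxs
Title: Data Reduction for Spectral Small-Angle X-Ray Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reduces three-dimensional spectroscopic photon-counting
    detector data (energy bin x pixel row x pixel column counts) into
    energy-windowed one-dimensional scattering patterns in momentum
    transfer (q) space and into two-dimensional spatially resolved
    scattering maps built from area-under-peak values across a raster
    scan. Includes background subtraction, a documented open frame
    format, a forward simulator of Debye-Scherrer rings on a flat
    pixellated detector for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
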