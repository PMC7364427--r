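Package: stereoloc
Title: Stereotactic Localizer Geometry and Monte Carlo Noise Propagation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward and inverse geometric models of two stereotactic
    fiducial localizers, the N-localizer and the V-shaped Sturm-Pastyr
    localizer, together with a reproducible Monte Carlo engine that
    propagates uniform image noise through the fiducial coordinates to
    quantify the root-mean-square and maximum error of the reconstructed
    section height. Includes parameter sweeps over section height, tilt
    angle and noise amplitude, least-squares error-scaling fits, and a
    command-line interface that emits deterministic CSV/JSON tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
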