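Package: fossilCR
Title: Capture-Recapture Models for Fossil Biodiversity Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open-population capture-recapture modelling of fossil occurrence
    data binned into stratigraphic time intervals. Fits the Jolly-Seber model
    in the POPAN formulation to estimate per-bin genus richness, and the
    Pradel survival/seniority model to estimate per-bin survival and
    seniority probabilities, which are transformed into per-Myr origination
    and extinction rates on unevenly spaced bins. Computes per-bin cohort
    forward and backward survivorship and overall genus longevity at fixed
    richness levels, relative diversification, second-for-third turnover
    rates for comparison, and single-changepoint detection on rate series.
    Includes a birth-death-sampling occurrence simulator with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
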