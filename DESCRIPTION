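Package: tabletrace
Title: Front Tracking and Dissolution Kinetics for Immersed Tablets
Version: 0.1.0
Authors@R: person("tabletrace", "maintainers", email = "maintainers@tabletrace.org", role = c("aut", "cre"))
Description: Tracks wetting, gel-formation and erosion boundaries in
    time-lapse images of a tablet immersed in dyed medium, converts the
    calibrated distance-versus-time series into rates by linear regression,
    fits cumulative dissolution profiles with the F0-modified
    Korsmeyer-Peppas and Peppas-Sahlin models under R2/AIC/MSC selection,
    and correlates the physical rates with dissolution and disintegration
    parameters. Includes a deterministic synthetic-scene generator with
    ground truth so the whole pipeline is testable without external data,
    and a command-line interface tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
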