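Package: plumeED
Title: Distance-Decay Modelling of Dredging Pressure Fields and Coral Smothering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how far the environmental pressure field of a
    large marine dredging project extends, and how far corals respond to it.
    Converts raw water-quality logger streams (turbidity, underwater light,
    optical-backscatter deposition) into fortnightly pressure metrics, manages
    categorical sediment- and mucus-cover score panels for tagged coral
    colonies, summarises seabed particle-size compositions, fits Bayesian
    linear mixed models of transformed responses against log10 distance from
    the dredging source by a purpose-built Gibbs sampler (site and fortnight
    random intercepts, conjugate priors, split R-hat diagnostics), and inverts
    the fitted decay curves into ED10/ED50 effect distances with 95% credible
    bands. A synthetic-data module generates monitoring datasets with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without access to proprietary monitoring data.
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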