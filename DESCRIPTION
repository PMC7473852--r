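Package: mangrovetyper
Title: Biophysical Typology of Mangrove Coastlines
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Delineates coastal embayments from a planar coastline, classifies
    them as delta, estuary, lagoon or bay (rule-based delta flagging plus a
    two-pass random-forest classifier on ten shape, catchment and
    precipitation covariates), attributes mangrove patches to typological
    units, classifies the sedimentary setting of lagoonal and open-coast
    units as terrigenous or carbonate with a binomial GLM on tidal amplitude
    and suspended particulate matter, and runs extent-change accounting and a
    variance-structured generalized least squares analysis of above-ground
    biomass by type. Ships a synthetic coastal-world generator with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    nlme,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
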