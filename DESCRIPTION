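Package: ecoland
Title: Urban Ecological-Land Assessment from Categorical Land-Use Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A raster pipeline for assessing urban ecological land change from
    co-registered categorical land-use maps: land-transformation matrices with
    Markov projection and contribution/probability statistics, landscape
    pattern metrics (edge density, patch density, shape, largest patch,
    contagion, Shannon diversity and evenness, area-weighted contiguity),
    equivalent ecological-area quality scoring from normalized ecosystem
    service values, center-of-gravity migration analysis, and logistic
    modelling and mapping of the probability that ecological land converts to
    non-ecological use. Includes a seeded synthetic-landscape generator so the
    whole route is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
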