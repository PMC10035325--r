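Package: wellprox
Title: Longitudinal Disparities in Population Proximity to Oil and Gas Wells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for longitudinal, proximity-based exposure-disparity
    analysis of upstream oil and gas development. Classifies wells into
    life-cycle stages (new, active, retired, plugged) per study period from
    spud, completion, production, and abandonment records; estimates census
    block-group exposure with 1 km well buffers by areal apportionment and by
    centroid-radius intensity; and computes demographic group risk ratios at
    state, county, and exposure-quintile scope, plus within-block-group panel
    change summaries. Includes a seeded synthetic-landscape generator with
    planted disparities and closed-form expected risk ratios so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
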