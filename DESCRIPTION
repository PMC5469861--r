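Package: punacarbon
Title: Ecosystem Carbon Accounting for High-Andean Forest-Grassland Mosaics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to account for carbon stocks in high-elevation Andean
    ('puna') forest-grassland landscapes. Implements per-plot stand
    structure metrics from tree inventories, soil-profile fine-earth mass
    and bulk density with rock-fragment correction, soil organic carbon
    and root carbon stocks, base saturation and rule-based soil
    classification (Mollic Leptosol, Phaeozem, Umbrisol), allometric
    aboveground tree carbon, indicator species analysis (IndVal) with a
    permutation null, trait-syndrome scoring via principal components,
    and an actual-versus-potential landscape carbon-stock scenario that
    contrasts human-accessible with inaccessible terrain. Includes a
    synthetic-data generator that emulates the structure of field data
    from all four habitat types so the full pipeline is testable without
    external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
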