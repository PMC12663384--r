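Package: landconvert
Title: Detection and Accounting of Agricultural Conversion of Natural Land Covers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying agricultural expansion into natural
    ecosystems from multi-epoch categorical land-cover maps. Harmonizes
    product-specific class legends into a common scheme (cultivated land,
    grassland & shrubland, non-forested wetland, forestland), detects
    per-pixel conversion and reversion between epochs, aggregates areas by
    zone and grid cell in equal-area terms, identifies conversion hotspot
    cells and countries, quantifies conversion inside Protected Areas by
    IUCN category, and computes biodiversity impact summaries
    (threatened-species richness, affected species by habitat affinity,
    Key Biodiversity Area overlap). Includes a seeded synthetic-landscape
    generator with known ground truth so every stage is testable without
    multi-gigabyte global inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
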