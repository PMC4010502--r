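Package: cascadr
Title: Simulation of Hierarchical Land-Clearing Caps in a Tropical Catchment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sequential, stochastic land clearing of pastoral and
    agricultural properties under a nested "cascade" of percentage clearing
    caps (property, sub-catchment, vegetation type, whole catchment) with
    prohibited riparian buffer zones, as used in the clearing guidelines for
    the Daly River catchment in northern Australia. Provides a tabular
    landscape data model, a seeded synthetic-landscape generator emulating
    the catchment's cadastre, vegetation mapping and land-suitability index,
    four property-ordering scenarios plus an unconstrained variant, a
    cap-ledger engine with grandfathering of features already over their cap,
    and summary statistics of clearing outcomes by tenure, sub-catchment and
    vegetation type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
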