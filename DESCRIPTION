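Package: methanocosm
Title: Methane Flux, Isotopes, and Microbial Communities in Soil Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for closed-chamber soil microcosm experiments on
    methane cycling. Converts headspace CH4 concentration time series into
    quality-controlled surface fluxes and cumulative emissions, estimates the
    isotopic signature of the CH4 source by Keeling-plot regression and
    classifies the dominant methanogenic pathway from delta13C/delta2H
    signatures, summarizes methanogen and methanotroph guilds and
    generalist/specialist niche occupancy (multinomial CLAM classification)
    from amplicon count tables, calibrates qPCR standard curves and converts
    quantification cycles to gene copies per gram of dry soil, and tests
    factorial treatment effects with aligned-rank-transform ANOVA. Includes a
    synthetic-data generator that emulates a full factorial
    temperature-by-flooding incubation so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
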