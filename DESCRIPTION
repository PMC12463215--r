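Package: ldgsim
Title: Mechanistic Simulation of the Latitudinal Diversity Gradient on
    Dynamic Paleo-Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit eco-evolutionary simulation of clade
    diversification on time-varying gridded landscapes, together with the
    physiographic and macroecological analyses built on it. Generates
    synthetic paleo-worlds (drifting continents, orogeny pulses, a transient
    climate-driven extinction pulse), computes terrain morphometrics
    (topographic position index, slope, water-flux classes) and a Shannon
    equitability physiographic-diversity index, runs forward-in-time
    dispersal / allopatric-speciation / trait-evolution / ecology dynamics
    under four eco-evolutionary scenarios, and quantifies latitudinal
    diversity gradients through hyperbolic-tangent fits, diversification-rate
    surfaces and simplified Koeppen climate belts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
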