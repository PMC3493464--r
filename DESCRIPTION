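Package: lignindesign
Title: Design-Space Screening of Metabolic Channeling in Monolignol Biosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates admissible topological configurations and metabolite-level
    crosstalk patterns for the guaiacyl/syringyl branch of monolignol biosynthesis
    in Medicago, builds randomly parameterized power-law (Generalized Mass Action
    and S-system) models under steady-state flux and kinetic-order constraints,
    simulates enzyme down-regulation and knockout lines, and scores every design by
    the number of parameterizations that reproduce observed or synthetic changes in
    the S/G lignin ratio. Includes exact vertex enumeration and sampling of the
    constrained steady-state flux polytope, a log-linear S-system steady-state
    solver with a numerical GMA cross-check, a synthetic-scenario generator for
    ground-truth recovery tests, a one-edge-difference topology graph for
    connectivity analysis of robust designs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
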