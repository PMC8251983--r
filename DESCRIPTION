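Package: dynamete
Title: Dynamic Maximum Entropy Theory of Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid maximum-entropy plus mechanistic modelling of community
    macroecology. Solves the static METE structure function (log-series species
    abundance distribution and metabolic rate distribution over individuals)
    from the state variables S, N and E; evaluates mechanistic transition
    functions for demography, ontogenic growth, migration, speciation and
    extinction; derives closed-form near-steady-state dynamics, steady states
    and species-area scaling; and implements the iterative constrained-MaxEnt
    procedure that yields time-varying abundance and metabolic-rate
    distributions under disturbance, including the frozen-multiplier
    first-iteration analysis of perturbed communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
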