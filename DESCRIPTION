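Package: dnfba
Title: Constraint-Based Modeling of a Dopaminergic Nerve Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A curated constraint-based (stoichiometric) model of a
    dopaminergic nerve cell together with a flux-balance-analysis toolkit.
    The package provides the network data structures (irreversible bounded
    reactions in micromolar-per-hour units, boundary input/output reactions,
    currency metabolites, functional reaction groups), a deterministic
    linear-programming engine with parsimonious tie-breaking and flux
    variability analysis, a brute-force vertex-enumeration oracle for small
    instances, SBML and TSV model exchange, seeded synthetic-network
    generators with planted feasible fluxes, and the experiment suite used
    to probe the cell model: grouped min/max apoptosis and degradation
    objectives plus input-flux scans (oxygen, ATP, MPTP, alpha-synuclein,
    tyrosine) with feasibility-window and onset-threshold detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
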