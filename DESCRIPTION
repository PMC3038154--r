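Package: fluxseries
Title: Flux-Balance Computation Series for Stoichiometric Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of stoichiometric metabolic networks built
    around batch series of heterogeneous flux-balance optimizations. A basic layer
    solves single problems (biomass maximization, weighted flux minimization,
    L1-MOMA, ROOM, fitness maximization under partial enzyme inhibition,
    expression-profile matching, metabolic flux analysis fitting, and a
    concentration-based thermodynamic feasibility MILP); an upper layer runs
    simulation series from a concise description file with automatic evaluation,
    plus flux variability analysis, leak analysis, and pruning to the functional
    subnetwork. Models are read and written as SBML or a plain-text flat format;
    optimization problems are exchanged with external solvers (GLPK, HiGHS) in
    CPLEX LP format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: GLPK stand-alone solver (glpsol) on the PATH; optionally
    Python 3 with scipy for the 'highs' backend.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
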