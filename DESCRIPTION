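Package: fossilplace
Title: Backbone-Constrained Parsimony Placement of Fossil Taxa
Version: 0.1.0
Authors@R:
    person("fossilplace", "developers", email = "fossilplace@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the systematic position of fossil taxa on a
    fixed molecular backbone using discrete morphological characters under
    maximum parsimony. Reads NEXUS and TNT character matrices with missing
    and polymorphic cells, scores trees with the Fitch algorithm (Hartigan
    generalisation for polytomies) under equal and Goloboff implied
    weighting, exhaustively inserts a floating taxon on every backbone
    branch and maps the resulting scores onto branches, runs a constrained
    heuristic search for several floating taxa, and simulates Mk-model
    morphological matrices with fossil-style missingness for placement
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
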