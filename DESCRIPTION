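Package: phagelattice
Title: Individual-Based Simulation of Phage-Bacteria Dynamics on Structured Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based model of bacteria and bacteriophages on a
    two-dimensional lattice whose environmental structure ranges from fully
    well-mixed to fully structured. Bacteria occupy at most one cell per
    location, compete for free space through fitness-proportionate (roulette
    wheel) selection, and can evolve resistance to antibiotics and to phage
    attachment phenotypes. Phages can be virulent or temperate; temperate
    phages decide between lysis and lysogeny through a density-dependent Hill
    response, integrate as prophages, are vertically inherited, and induce
    spontaneously or under antibiotic stress. Antibiotic fields diffuse and
    degrade on the same lattice. The package includes scenario presets for
    community dynamics under antibiotic and phage pressure, resistance
    emergence scans, coevolutionary arms races and lysogen invasion, plus an
    experiment layer: replicate ensembles, emergence-time statistics,
    population-level adsorption estimation, early-lysogenization fits and a
    random-forest permutation-importance harness with a dummy-parameter noise
    floor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
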