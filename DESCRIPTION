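Package: evoligand
Title: Genetic-Algorithm De Novo Design of Small-Molecule Ligands
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A generation-based genetic algorithm over small molecules
    represented as SMILES: elitism, reaction-based mutation driven by
    SMIRKS reaction libraries with complementary reactant pools,
    crossover through the largest common substructure of two parents,
    drug-likeness and structural-alert filtration with automatic refill,
    docking-score-convention fitness with ligand efficiency and a
    Dice-similarity diversity score, and Ranking, Roulette and Tournament
    seed selection. Includes a deterministic surrogate fitness function
    for desk-scale runs, an external docking-adapter contract for
    receptor-based scoring, BRICS fragmentation for lead-optimization
    seed preparation, and lineage tracing for every generated compound.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    parallel,
    tools,
    stats,
    utils,
    jsonlite,
    igraph,
    ChemmineOB
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, StructuralPrediction
RoxygenNote: 7.3.3
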