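# evoligand

Genetic-algorithm de novo design of small-molecule ligands, in R.

## The problem

De novo structure-based design searches a chemistry space of 10^20+
synthesizable molecules that no enumerated library can cover. A
generation-based genetic algorithm explores it on demand: starting from
a seed population of fragments (de novo design) or known ligands (lead
optimization), each generation is bred from the fittest and most
structurally unique compounds of the previous one and scored against
the design objective. `evoligand` is for computational chemists who
want that loop as a scriptable, deterministic, fully testable R
package: every operator is exposed, every compound's lineage is
recorded, and scoring is a pluggable contract so the same run drives a
docking program in production and a deterministic surrogate on a
laptop.

## The algorithm

Each generation *n* is assembled from three operators, seeded by
subselections of generation *n−1* (Ranking, Roulette, or Tournament
selection over the primary score and a diversity score):

* **elitism** — the fittest compounds advance unchanged;
* **mutation** — an in silico chemical reaction, drawn from a SMIRKS
  reaction library (bundled sets of 36, 58, and their union of 94
  reactions, 79 of which consume a second reactant drawn from a
  complementary library), is applied to a parent;
* **crossover** — two parents are merged around their largest common
  substructure, with decorating moieties recombined at random.

Candidates are deduplicated, passed through drug-likeness filters
(Lipinski, Lipinski\*, Ghose, Ghose\*, Van de Waterbeemd, Mozziconacci)
and structural-alert catalogs (BRENK, NIH, PAINS), refilled on
shortfall, then scored. The primary score follows the docking
convention (kcal/mol scale, lower = better); the diversity score of
molecule *M* is

> d(M) = Σ_{N≠M} s(F_M, F_N),  s(F_A, F_B) = 2|F_A ∩ F_B| / (|F_A| + |F_B|)

with `F` the Morgan-fingerprint bit sets and `s` the Dice coefficient
(0 = completely different, 1 = perfectly matched). Small `d` marks a
structurally unique compound. Ligand efficiency (score per heavy atom)
is available to counter the drift toward ever-heavier molecules.

## A worked example

```r
library(evoligand)
set.seed(1)
seeds <- tempfile(fileext = ".smi")
writeFixtureLibrary(seeds)   # 24 synthetic fragments, 6 functional classes

cfg <- runConfig(seeds, generations = 3, nElitism = 5, nMutation = 20,
                 nCrossover = 20, filterChain = "Lipinski", rngSeed = 7)
res <- runEvolution(cfg)
res$summaries[, c("generation", "n_population", "best", "mean", "top10_mean")]
#>   generation n_population best      mean top10_mean
#> 1          1           45 -5.3 -3.157778      -4.69
#> 2          2           45 -8.1 -4.868889      -6.70
#> 3          3           45 -9.5 -6.413333      -8.64
```

The surrogate best score improves from −5.3 to −9.5 over three
generations (lower is better; with at least one elite per generation the
best-so-far can never worsen). The winner and its ancestry:

```r
res$records[[1]]
#> MoleculeRecord g3_X7 [gen 3, crossover]
#>   CCCn1nncc1Cc1ccccc1CCn1nnnc1CC#N
#>   scores: primary=-9.5, diversity=14.57, ligand_efficiency=-0.38

tree <- traceLineage("g3_X7", res$ledger)  # full ancestry down to seeds
```

`g3_X7` is a third-generation crossover child; the lineage tree walks
back through its two parents to the generation-0 seed fragments. Every
run also writes per-generation ranked SMI files, a lineage ledger TSV
and a summary TSV when `outputDir` is set.

Operator-level entry points work standalone, e.g. the worked
transesterification:

```r
applyReaction("transesterification",
              c("O=C(Oc1ccccc1)c1ccccc1", "CO"),
              bundledReactionLibrary("RobustRxn"))
#> [1] "COC(=O)c1ccccc1"     # methyl benzoate, lighter than its parent ester
```

For receptor-based scoring, supply `fitness = dockingAdapter(...)` with
an executable that converts SMILES batches to docked top-pose scores
(Vina-compatible wrappers fit the contract); nothing in the package
performs docking itself. A command-line front end
(`inst/scripts/evoligand`) wraps runs, filtering, BRICS fragmentation,
scoring and lineage queries.

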