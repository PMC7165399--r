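---
title: "Evolutionary de novo ligand design with evoligand: models and methods"
author: "evoligand authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary de novo ligand design with evoligand}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The method

`evoligand` implements a generation-based genetic algorithm over small
molecules represented as SMILES. A run starts from a source population
(generation 0): chemically diverse fragments for de novo design, or known
ligands for lead optimization. Each new generation is assembled by three
operators, each seeded by its own pool selected from the previous
generation:

* **Elitism** advances a sub-population of the fittest compounds
  unchanged. Seed selection is decoupled from elitism, so the number of
  compounds advanced this way is controlled independently of the number
  used to seed mutation and crossover. Elites optionally get rescored
  (`rescoreElites`), which matters when the fitness function is a
  stochastic docking program; under the deterministic surrogate it is a
  no-op and the best-so-far score is then monotonically non-increasing.
* **Mutation** applies an in silico chemical reaction to a parent. A
  reaction is drawn uniformly from the (reaction, slot) pairs whose
  per-slot functional-group query matches the parent; bimolecular
  reactions draw the second reactant uniformly from the complementary
  library group of the other slot; when a template matches at several
  sites one site is drawn uniformly. The product keeps its largest
  fragment (co-products such as the phenol leaving transesterification
  are discarded) and is sanitized and canonicalized.
* **Crossover** merges two parents around the largest substructure they
  share. Both parents are decomposed into the shared core plus
  "decorating moieties" hanging off core positions; at every decorated
  position the child inherits the moiety set of one parent or the other
  with equal probability (positions decorated in only one parent choose
  between that moiety set and nothing). The child therefore always
  contains the core.

Generated candidates are deduplicated by canonical SMILES within the
generation, pushed through the configured filter chain, and -- when too
few survive -- the engine loops back to the operators until the
configured operator sizes are met or a retry budget
(`maxRefillAttempts` per missing molecule) is exhausted, at which point
the run stops and names the bottleneck operator and chain.

## Fitness

The primary score follows the docking convention: lower (more negative)
is better, on a kcal/mol-like scale. Scoring is a pluggable contract
(`fitnessFunction()`): the bundled deterministic surrogate is defined
exactly as

$$\mathrm{score} = -(0.1\,\mathrm{heavy} + 1.0\,\mathrm{rings} +
  0.5\,(\mathrm{HBD} + \mathrm{HBA}))$$

and is a test double, not a binding-affinity predictor: it rewards
molecular growth, ring formation and polar decoration, which gives the
optimizer a smooth landscape so the whole loop can be exercised without
a receptor. Receptor-based runs use `dockingAdapter()`, a documented
batch contract (SMILES in, top-pose score out) for Vina-compatible
wrappers; no docking program ships with the package. `nnscore1` /
`nnscore2` rescoring names are registered but intentionally not
implemented. A ligand-efficiency score (primary score divided by the
heavy-atom count) can be attached to penalize bulk.

The secondary score is the diversity score: with Morgan fingerprint bit
sets $F$, pairwise similarity is the Dice coefficient
$s(F_A,F_B) = 2|F_A \cap F_B| / (|F_A|+|F_B|)$ and a molecule's
diversity score is $d(M)=\sum_{N \neq M} s(F_M,F_N)$ over its
generation. Small $d$ means structurally unique, so diversity
subselection minimizes $d$. Two empty fingerprints are defined as
completely different ($s = 0$); this 0/0 corner is unreachable for real
molecules but is pinned down for the arithmetic's sake.

## Selection

Three selectors are provided. *Ranking* takes the best $k$
(deterministic; ties broken by canonical SMILES then id). *Roulette*
draws without replacement with wheel areas
$w_i = (\mathrm{worst}-s_i) + \epsilon(\mathrm{worst}-\mathrm{best})$,
$\epsilon = 0.01$: a shifted-linear transform chosen because raw docking
scores are negative and the transform guarantees the least-fit record a
non-zero area; a softmax alternative was rejected because it introduces
a temperature hyperparameter. *Tournament* repeatedly samples
$\lceil f\cdot|\mathrm{pool}|\rceil$ records (default $f = 0.1$) and
advances the best, removing winners between rounds; $f = 1$ degenerates
to ranking and a one-record tournament to uniform sampling. Each
generation performs three subselections (elitism / mutation /
crossover), each mixing `seedsByScore` picks on the primary score with
`seedsByDiversity` picks on the diversity score, without duplicates
within a pool. With ranking the three subselections coincide; with the
stochastic selectors they are independent draws.

# Reaction libraries

Reactions are data, not code: JSON entries
`{name, smirks, num_reactants, slot_queries, source_set,
example_reactants}`. The SMIRKS dialect requires full atom mapping on
every reactant-template atom; product templates reuse those maps, may
drop mapped atoms (deleting them and, implicitly, their fragments — how
co-products disappear) and may add concrete unmapped atoms. Three sets
ship with the package: 36 click-chemistry-style reactions
(`AutoClickChemRxn`), 58 robust coupling and ring-forming reactions
(`RobustRxn`), and their 94-reaction union (`AllRxn`), 79 of which take
two reactants. The bundled SMIRKS were authored for this package in the
spirit of the published click-chemistry and robust medicinal-chemistry
collections those set names refer to; every entry carries example
reactants, and `selfTestReactionLibrary()` applies each reaction to its
examples and asserts a valid product. Load-time validation covers
SMIRKS syntax, template/slot arity, and slot-query syntax, so a broken
custom library fails fast rather than mid-run.

Complementary libraries are built by `buildComplementaryLibrary()` the
way large vendor-derived reactant sets are curated: candidates above
250 Da or logP 5, or failing the strict no-violation Lipinski rule, are
discarded; candidates matching no slot query are discarded; each
(reaction, slot) group keeps at most 5000 molecules, preferring low
molecular weight (ties broken lexicographically). The packaged reactant
set (`complementary_seeds.smi`) is a small curated stand-in covering
the functional groups the default reactions consume; production runs
should supply their own SMI file.

Inputs are mildly neutralized before reaction matching (protonated
amines deprotonated, O/S anions protonated) since protonation-state
enumeration is delegated to the variant contract.

# Filters

Nine filters are registered by default. Six are descriptor-bound rules
encoded as data (bounds, strictness, allowed violations): Lipinski
(logP $\le$ 5, HBD $\le$ 5, HBA $\le$ 10, MW $\le$ 500 Da; one
violation allowed), its strict no-violation variant Lipinski*, Ghose
(logP $-0.4$..$5.6$, MW 160..480, molar refractivity 40..130, 20..70
atoms), Ghose* (MW relaxed to 500), Van de Waterbeemd (MW < 450,
PSA < 90 Å² — strict inequalities as published), and Mozziconacci
($\le$ 15 rotatable bonds, $\le$ 6 rings, $\ge$ 1 N, $\ge$ 1 O, $\le$ 7
halogens; the literature definition is adopted where published
tabulations are typographically ambiguous about column alignment).
Violations are counted per bound, so a molecule over both the weight
and logP limits accrues two. Boundary values pass non-strict bounds.

Three are structural-alert catalogs shipped as plain-text SMARTS lists
with provenance headers: BRENK (105 alerts), NIH (180) and PAINS (480).
Disconnected (dot-separated) alert patterns are matched per component
with multiplicities. Chains apply with AND semantics, short-circuit in
order, and attribute each rejection to the first rejecting filter; the
survivor set is order-independent by construction. Custom filters
(descriptor rules, catalogs, or arbitrary predicates) join the registry
via `registerFilter()`.

## Descriptor conventions

The filter bounds only mean something relative to fixed descriptor
definitions; published rule sets do not pin down every estimator, so the
package documents its choices: hydrogen-bond donors and acceptors use
the Lipinski convention (donors = O–H plus N–H bonds, acceptors = N
plus O atoms) for consistency with the rule-of-five bounds; logP and
molar refractivity are Open Babel's atom-contribution estimates
(Crippen-type); polar surface area is the topological (TPSA) estimate;
rotatable bonds are non-ring single bonds between two non-terminal
heavy atoms excluding amide C–N (the strict definition); ring count is
the number of independent rings (cyclomatic number); molecular weight
sums standard atomic masses including implicit hydrogens. Numeric
boundary cases can differ from pipelines using other estimators —
a molecule near a logP bound may pass here and fail elsewhere.

# The common-substructure search

Crossover needs a maximum common connected substructure under element,
aromaticity, charge and bond-order matching. By default ring atoms and
bonds only match ring atoms and bonds (`ringMatchesRingOnly`), which
keeps cores chemically meaningful (shared ring systems rather than
accidental chain/ring overlaps). The search is a McGregor-style
branch-and-bound over frontier extensions, implemented in C++: it
branches on mapping a frontier atom to each consistent image or
excluding it, prunes with an incumbent bound, and runs under a fixed
node-expansion budget. The budget makes the search *deterministic
anytime*: given enough budget the result is exact; when the budget runs
out the best core found so far is returned (an early greedy dive almost
always finds a large core first). Returning the incumbent instead of
nothing is a deliberate choice: on larger evolved molecules a strict
timeout-means-no-core rule starves the crossover operator, while an
incumbent core is still a valid (possibly non-maximum) common
substructure and every downstream invariant — core containment,
reconstruction — holds for it. Seed pairs are tried in decreasing
degree order and capped, which bounds the per-pair floor cost. Cores
smaller than `minCoreAtoms` (default 4 heavy atoms; a one-atom "core"
degenerates the operator) are rejected.

Decomposition cuts every core/non-core bond; a fragment touching the
core through more than one bond (a ring through the core) makes the
attempt fail rather than produce a multiply-attached moiety.
Reassembly recomputes hydrogen counts and validates valences; invalid
assemblies are re-sampled up to `maxAttempts`. Operator products are
additionally required to carry chemically complete valences on neutral
carbon, nitrogen and oxygen (no radical-like centers), so a
mis-assembled edit is rejected instead of propagating through later
generations.

# Numerical and engineering choices

* **Canonicalization** is delegated to Open Babel; the package's own
  parser/writer handles graph editing and validates syntax and
  valences first. Canonicalization is a fixed point, and two spellings
  of one molecule map to one string. Stereochemistry is dropped
  throughout: the operators edit graphs in ways that routinely destroy
  stereocenters, and tracking partial stereochemistry would give a
  false sense of precision.
* **Morgan fingerprints** hash atom invariants (atomic number, heavy
  degree, H count, charge, aromaticity, ring membership) and iterate
  neighbor environments to radius 2, folding into 2048 bits (both
  configurable); the mixing hash is a fixed 32-bit FNV-type function so
  fingerprints are identical across platforms.
* **Determinism**: all stochastic choices flow through R's RNG; a fixed
  `rngSeed` makes whole runs reproducible to the byte under the
  surrogate scorer (the common-substructure budget is a node count,
  not wall time, for exactly this reason).
* **Caching**: canonical SMILES, parsed graphs, descriptor rows,
  fingerprints, reaction-match tables, decompositions and cores are
  memoized package-wide. All are pure functions of their inputs, so
  caching cannot change results, only timing.
* **Duplicate policy**: deduplication is per generation; re-creating a
  compound from an earlier generation is allowed (no global taboo
  list). The bookkeeping identity
  `created - filtered - duplicates - failures = population` is asserted
  for every generation summary.
* **Variant contract**: an optional enumerator maps one SMILES to up to
  `maxVariantsPerMolecule` ionization/tautomer variants before scoring;
  scores reduce to the best per compound. The default is the identity
  (one variant); the pH range is carried in the configuration for
  enumerators that want it.
* **Parallelism**: candidate generation and scoring are expressed as
  order-independent maps; the bundled implementation maps serially, so
  results do not depend on a worker count.

# The synthetic seed generator

`generateFixtureLibrary()` builds small molecules (at most 20 heavy
atoms, all passing the strict Lipinski rule) guaranteed to carry a
requested functional-group class — alcohols, carboxylic acids, primary
amines, azides, terminal alkynes, aryl halides — by combining random
aliphatic/aromatic stems with the class group. It emulates the role of
a vendor-derived fragment seed library at desk scale: known reactive
handles, drug-like property ranges, deterministic under a seed. It does
*not* emulate real screening libraries' scaffold diversity, tautomeric
ambiguity, counterion noise or property distributions; runs on it
demonstrate the optimizer's mechanics (improvement, monotone elitism,
reproducibility), not chemistry-space coverage. The desk-scale study
configuration used throughout the tests is 5 generations with 10/50/50
elitism/mutation/crossover per generation (population 110), ranking
selection and the surrogate scorer — sizes chosen so a full run
finishes in under a minute on one CPU while still being large enough
for selection pressure to show.

# Known limitations

* The SMARTS/SMIRKS engine implements a documented subset (element,
  aromaticity, degree/connectivity/H-count/valence predicates, ring
  membership, charges, recursive SMARTS, the standard bond primitives).
  Ring-size (`r<n>`) and ring-bond-count (`x<n>`) predicates and
  isotopes are not supported in reaction templates; alert catalogs are
  matched through Open Babel and are not limited by this subset.
* Aromaticity bookkeeping in products relies on the template author:
  a ring-forming template can produce a system that is not actually
  aromatizable (the canonicalizer then warns about kekulization), and
  hydrogen recomputation on heavily edited centers can occasionally
  accept a strained product. The canonicalization round trip rejects
  outright valence violations; subtler chemical nonsense survives, as
  it does in any purely graph-based reaction engine.
* The common-substructure search is exact only within its node budget;
  on large, highly similar molecules the returned core may be
  sub-maximum.
* Scores under the surrogate say nothing about binding; conclusions
  about real receptors require a docking adapter.
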