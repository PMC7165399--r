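# Reaction libraries and the mutation operator.

test_that("bundled reaction sets have their documented sizes", {
  expect_length(clickRxn, 36L)
  expect_length(robustRxn, 58L)
  expect_length(allRxn, 94L)
  nbi <- sum(vapply(reactions(allRxn),
                    function(r) r@numReactants, 0L) == 2L)
  expect_equal(nbi, 79L)
  expect_false(anyDuplicated(vapply(reactions(allRxn),
                                    function(r) r@name, "")) > 0L)
})

test_that("library loading validates entries and fails fast", {
  f <- tempfile(fileext = ".json")
  good <- list(list(name = "oxidation",
                    smirks = "[C;H2:1][OX2H:2]>>[C;H1:1]=[O:2]",
                    num_reactants = 1L,
                    slot_queries = list("[C;H2][OX2H]"),
                    source_set = "RobustRxn",
                    example_reactants = list("OCC")))
  jsonlite::write_json(good, f, auto_unbox = TRUE)
  lib <- suppressMessages(loadReactionLibrary(f, "custom"))
  expect_length(lib, 1L)

  bad <- good
  bad[[1]]$smirks <- "[C:1][OX2H:2].[NX3;H2:3]>>[C:1][N:3]"  # 2 templates
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(suppressMessages(loadReactionLibrary(f)), "declared")

  bad2 <- good
  bad2[[1]]$smirks <- "not a reaction"
  jsonlite::write_json(bad2, f, auto_unbox = TRUE)
  expect_error(suppressMessages(loadReactionLibrary(f)), "oxidation")
})

test_that("every bundled reaction passes its example self-test", {
  st <- selfTestReactionLibrary(allRxn)
  expect_true(all(st$ok), info = paste(st$name[!st$ok], collapse = ", "))
})

test_that("functional-group matching routes molecules to reactions", {
  acid <- matchingReactions("CC(=O)O", allRxn)
  expect_gt(length(acid), 0L)
  names <- vapply(acid, function(x) x$reaction@name, "")
  expect_true("acid_alcohol_esterification" %in% names)
  expect_length(matchingReactions("C", allRxn), 0L)
  empty <- new("ReactionLibrary", setName = "empty", reactions = list())
  expect_length(matchingReactions("CC(=O)O", empty), 0L)
})

test_that("complementary libraries group eligible reactants by slot", {
  lib <- new("ReactionLibrary", setName = "esterOnly",
             reactions = list(getReaction("acid_alcohol_esterification")))
  comp <- buildComplementaryLibrary(
    canonicalizeSmiles(c("CCO", "CC(=O)O", "c1ccccc1")), lib)
  expect_true("CC(=O)O" %in%
                comp@groups[["acid_alcohol_esterification#1"]])
  expect_true("CCO" %in% comp@groups[["acid_alcohol_esterification#2"]])
  expect_false(any(vapply(comp@groups,
                          function(g) "c1ccccc1" %in% g, TRUE)))
})

test_that("per-group caps keep the lightest molecules", {
  lib <- new("ReactionLibrary", setName = "esterOnly2",
             reactions = list(getReaction("acid_alcohol_esterification")))
  comp <- buildComplementaryLibrary(
    canonicalizeSmiles(c("CCO", "CCCO", "CC(=O)O")), lib, perGroupCap = 1)
  expect_identical(comp@groups[["acid_alcohol_esterification#2"]], "CCO")
})

test_that("heavy candidates are discarded regardless of groups", {
  lib <- new("ReactionLibrary", setName = "esterOnly3",
             reactions = list(getReaction("acid_alcohol_esterification")))
  heavyAlcohol <- canonicalizeSmiles("OCCCCCCCCCCCCCCCCCCCCCC")  # > 250 Da
  comp <- buildComplementaryLibrary(c(heavyAlcohol, "CCO"), lib)
  expect_false(any(vapply(comp@groups,
                          function(g) heavyAlcohol %in% g, TRUE)))
})

test_that("the transesterification worked example shrinks the product", {
  prods <- applyReaction("transesterification",
                         c("O=C(Oc1ccccc1)c1ccccc1", "CO"),
                         robustRxn)
  expect_true(canonicalizeSmiles("COC(=O)c1ccccc1") %in% prods)
  mwOf <- function(s) computeDescriptors(s)$mw
  expect_lt(mwOf(canonicalizeSmiles("COC(=O)c1ccccc1")),
            mwOf(canonicalizeSmiles("O=C(Oc1ccccc1)c1ccccc1")))
})

test_that("the click cycloaddition forms a triazole", {
  prods <- applyReaction("azide_alkyne_cycloaddition_14",
                         c("CCCN=[N+]=[N-]", "C#CCO"), clickRxn)
  expect_gt(length(prods), 0L)
  expect_true(any(vapply(prods, function(p) {
    evoligand:::.smartsHit("c1cn(nn1)", p)
  }, TRUE)))
})

test_that("mutation produces valid children with full provenance", {
  parent <- moleculeRecord("CC(=O)O", id = "p0")
  set.seed(99)
  nOk <- 0L
  for (k in 1:20) {
    child <- mutateMolecule(parent, allRxn, compLib,
                            id = paste0("m", k), generation = 1L)
    if (is.null(child)) next
    nOk <- nOk + 1L
    expect_identical(origin(child), "mutation")
    expect_identical(parentIds(child), "p0")
    expect_identical(smiles(child), canonicalizeSmiles(smiles(child)))
    # provenance: the recorded reaction on the recorded reactants
    # reproduces the child among the enumerated products
    parts <- strsplit(child@reactionName, ":", fixed = TRUE)[[1]]
    spec <- getReaction(parts[1])
    reactants <- if (spec@numReactants == 2L) {
      m <- matchingReactions(smiles(parent), allRxn)
      slot <- Filter(function(x) x$reaction@name == parts[1], m)[[1]]$slot
      if (slot == 1L) c(smiles(parent), parts[2])
      else c(parts[2], smiles(parent))
    } else smiles(parent)
    expect_true(smiles(child) %in% applyReaction(spec, reactants))
  }
  expect_gt(nOk, 10L)
})

test_that("mutation fails cleanly when no functional group matches", {
  inert <- moleculeRecord("C", id = "methane")
  expect_null(mutateMolecule(inert, allRxn, compLib))
})

test_that("mutation is deterministic under a fixed seed", {
  parent <- moleculeRecord("NCCc1ccccc1", id = "p1")
  set.seed(123)
  a <- mutateMolecule(parent, allRxn, compLib, id = "c1")
  set.seed(123)
  b <- mutateMolecule(parent, allRxn, compLib, id = "c1")
  expect_identical(smiles(a), smiles(b))
  expect_identical(a@reactionName, b@reactionName)
})

test_that("mutate outputs canonicalize cleanly at scale", {
  set.seed(7)
  parents <- lapply(seq_along(fixtureSeeds), function(i) {
    moleculeRecord(fixtureSeeds[i], id = paste0("p", i),
                   canonicalize = FALSE)
  })
  nOk <- 0L; nTried <- 0L
  while (nTried < 1000L) {
    p <- parents[[sample.int(length(parents), 1L)]]
    nTried <- nTried + 1L
    ch <- mutateMolecule(p, allRxn, compLib, id = "x")
    if (is.null(ch)) next
    expect_identical(smiles(ch), canonicalizeSmiles(smiles(ch)))
    nOk <- nOk + 1L
  }
  expect_gt(nOk, 800L)
})

test_that("mutation weight drift goes both ways", {
  set.seed(31)
  parents <- lapply(seq_along(fixtureSeeds), function(i) {
    moleculeRecord(fixtureSeeds[i], id = paste0("p", i),
                   canonicalize = FALSE)
  })
  deltas <- numeric()
  for (k in 1:150) {
    p <- parents[[sample.int(length(parents), 1L)]]
    ch <- mutateMolecule(p, allRxn, compLib, id = "x")
    if (is.null(ch)) next
    deltas <- c(deltas, computeDescriptors(smiles(ch))$mw -
                  computeDescriptors(smiles(p))$mw)
  }
  expect_true(any(deltas > 0))
  expect_true(any(deltas < 0))
})
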