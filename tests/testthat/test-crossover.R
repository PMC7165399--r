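# Crossover: common-core search, decomposition, recombination.

test_that("the core of identical parents is the whole molecule", {
  core <- largestCommonSubstructure("Cc1ccccc1", "Cc1ccccc1")
  expect_equal(core@heavyAtomCount, 7L)
})

test_that("toluene and chlorobenzene share the benzene ring", {
  core <- largestCommonSubstructure("Cc1ccccc1", "Clc1ccccc1")
  expect_equal(core@heavyAtomCount, 6L)
  expect_true(all(core@coreGraph$arom))
})

test_that("tiny molecules yield no qualifying core", {
  expect_null(largestCommonSubstructure("C", "CC", minCoreAtoms = 4L))
})

test_that("ring atoms refuse to match chain atoms by default", {
  # cyclohexane vs hexane: rings only match rings, so no 4-atom core
  expect_null(largestCommonSubstructure("C1CCCCC1", "CCCCCC"))
  relaxed <- largestCommonSubstructure("C1CCCCC1", "CCCCCC",
                                       ringMatchesRingOnly = FALSE)
  expect_gte(relaxed@heavyAtomCount, 4L)
})

test_that("decomposition yields one moiety per cut bond", {
  core <- largestCommonSubstructure("Cc1ccccc1", "Clc1ccccc1")
  decTol <- decomposeOnCore(core@smilesA, core, "A")
  expect_length(decTol$moieties, 1L)
  # benzene against its own ring: nothing to strip
  coreBz <- largestCommonSubstructure("c1ccccc1", "c1ccccc1")
  decBz <- decomposeOnCore("c1ccccc1", coreBz, "A")
  expect_length(decBz$moieties, 0L)
  # para-xylene on a benzene core: two methyls at distinct positions
  coreX <- largestCommonSubstructure("Cc1ccc(C)cc1", "c1ccccc1")
  decX <- decomposeOnCore(canonicalizeSmiles("Cc1ccc(C)cc1"), coreX, "A")
  expect_length(decX$moieties, 2L)
  expect_length(unique(vapply(decX$moieties,
                              function(m) m$position, 0L)), 2L)
})

test_that("reassembly with one parent's moieties reproduces that parent", {
  pairs <- list(c("Cc1ccccc1", "Clc1ccccc1"),
                c("Cc1ccc(C)cc1", "Oc1ccccc1"),
                c("CC(=O)Nc1ccccc1", "CCC(=O)Nc1ccc(O)cc1"),
                c("OCCc1ccccc1", "NCCc1ccccc1"))
  for (p in pairs) {
    a <- canonicalizeSmiles(p[1]); b <- canonicalizeSmiles(p[2])
    core <- largestCommonSubstructure(a, b)
    expect_false(is.null(core), info = paste(p, collapse = " x "))
    for (side in c("A", "B")) {
      s <- if (side == "A") a else b
      dec <- decomposeOnCore(s, core, side)
      rebuilt <- evoligand:::.reassemble(core, dec$moieties)
      expect_identical(
        canonicalizeSmiles(evoligand:::.writeSmiles(rebuilt)), s,
        info = paste(s, side))
    }
  }
})

test_that("children always contain the common core", {
  set.seed(17)
  seeds <- fixtureSeeds
  nChecked <- 0L
  for (k in 1:60) {
    ij <- sample.int(length(seeds), 2L)
    a <- moleculeRecord(seeds[ij[1]], id = "a", canonicalize = FALSE)
    b <- moleculeRecord(seeds[ij[2]], id = "b", canonicalize = FALSE)
    core <- largestCommonSubstructure(smiles(a), smiles(b))
    if (is.null(core)) next
    child <- crossoverMolecules(a, b, id = "c", core = core)
    if (is.null(child)) next
    nChecked <- nChecked + 1L
    expect_true(evoligand:::.containsCore(smiles(child), core),
                info = paste(smiles(a), smiles(b), "->", smiles(child)))
    # the child can never weigh less than its core
    expect_gte(computeDescriptors(smiles(child))$mw,
               evoligand:::.molWeight(core@coreGraph) - 1e-6)
  }
  expect_gt(nChecked, 10L)
})

test_that("identical parents breed themselves", {
  a <- moleculeRecord("Cc1ccccc1", id = "a")
  b <- moleculeRecord("Cc1ccccc1", id = "b")
  set.seed(5)
  child <- crossoverMolecules(a, b, id = "c")
  expect_identical(smiles(child), smiles(a))
  expect_identical(origin(child), "crossover")
  expect_identical(parentIds(child), c("a", "b"))
})

test_that("crossover fails cleanly without a qualifying core", {
  a <- moleculeRecord("C", id = "a")
  b <- moleculeRecord("CC", id = "b")
  expect_null(crossoverMolecules(a, b, id = "c"))
})

test_that("argument order does not change the child distribution", {
  a <- moleculeRecord("Cc1ccccc1", id = "a")
  b <- moleculeRecord("Clc1ccccc1", id = "b")
  draw <- function(x, y) {
    out <- character()
    for (k in 1:500) {
      ch <- crossoverMolecules(x, y, id = "c")
      if (!is.null(ch)) out <- c(out, smiles(ch))
    }
    sort(unique(out))
  }
  set.seed(41); ab <- draw(a, b)
  set.seed(41); ba <- draw(b, a)
  expect_identical(ab, ba)
})
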