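# The generation loop, BRICS preparation, and the fixture generator.

smallConfig <- function(seedPath, ...) {
  runConfig(seedPath, generations = 2L, nElitism = 4L, nMutation = 8L,
            nCrossover = 8L, filterChain = "Lipinski",
            seedsByScore = c(elitism = 6, mutation = 10, crossover = 10),
            rngSeed = 7L, ...)
}

test_that("a run advances, improves, and keeps its books balanced", {
  path <- writeFixtureSmi()
  cfg <- smallConfig(path)
  res <- suppressMessages(runEvolution(cfg))
  expect_equal(nrow(res$summaries), 2L)
  for (i in seq_len(nrow(res$summaries))) {
    s <- res$summaries[i, ]
    expect_equal(s$n_created - s$n_filtered - s$n_duplicates -
                   s$n_score_failures, s$n_population)
    expect_lte(s$best, s$mean)
  }
  # every record's lineage resolves down to seeds
  ids <- vapply(res$ledger, molId, "")
  lastGen <- res$records[[1]]
  tree <- traceLineage(molId(lastGen), res$ledger)
  leaves <- function(node) {
    if (length(node$parents) == 0L) return(list(node))
    do.call(c, lapply(node$parents, leaves))
  }
  expect_true(all(vapply(leaves(tree), function(l)
    l$origin == "seed" && l$generation == 0L, TRUE)))
})

test_that("elitism carries best-so-far forward monotonically", {
  path <- writeFixtureSmi()
  cfg <- smallConfig(path)
  res <- suppressMessages(runEvolution(cfg))
  g0best <- min(vapply(Filter(function(r) generation(r) == 0L,
                              res$ledger),
                       function(r) scores(r)[["primary"]], 0))
  bests <- c(g0best, res$summaries$best)
  expect_true(all(diff(bests) <= 1e-12))
})

test_that("elite scores are carried over bit-identically", {
  path <- writeFixtureSmi()
  cfg <- smallConfig(path)
  res <- suppressMessages(runEvolution(cfg))
  byId <- stats::setNames(res$ledger, vapply(res$ledger, molId, ""))
  elites <- Filter(function(r) origin(r) == "elitism", res$ledger)
  expect_gt(length(elites), 0L)
  for (e in elites) {
    parent <- byId[[parentIds(e)]]
    expect_identical(scores(e)[["primary"]],
                     scores(parent)[["primary"]])
    expect_identical(smiles(e), smiles(parent))
  }
})

test_that("runs with the same seed are byte-identical", {
  path <- writeFixtureSmi()
  out1 <- tempfile(); out2 <- tempfile()
  res1 <- suppressMessages(runEvolution(smallConfig(path,
                                                    outputDir = out1)))
  res2 <- suppressMessages(runEvolution(smallConfig(path,
                                                    outputDir = out2)))
  expect_identical(readLines(file.path(out1, "ledger.tsv")),
                   readLines(file.path(out2, "ledger.tsv")))
})

test_that("pure-elitism single generations return the top seeds", {
  path <- writeFixtureSmi()
  cfg <- runConfig(path, generations = 1L, nElitism = 5L, nMutation = 0L,
                   nCrossover = 0L, rngSeed = 3L)
  res <- suppressMessages(runEvolution(cfg))
  g0 <- Filter(function(r) generation(r) == 0L, res$ledger)
  top5 <- sort(vapply(g0, function(r) scores(r)[["primary"]], 0))[1:5]
  got <- sort(vapply(res$records, function(r) scores(r)[["primary"]], 0))
  expect_equal(got, top5)
  expect_true(all(vapply(res$records,
                         function(r) origin(r) == "elitism", TRUE)))
})

test_that("an impossible filter chain stops the run with a diagnosis", {
  path <- writeFixtureSmi()
  # a filter that admits the seeds but rejects every new compound: the
  # refill loop must give up and name the bottleneck
  registerFilter("seedsOnly",
                 function(desc, smiles) smiles %in% fixtureSeeds)
  on.exit(rm("seedsOnly", envir = evoligand:::.filterRegistry))
  cfg <- runConfig(path, generations = 1L, nElitism = 2L, nMutation = 4L,
                   nCrossover = 0L, filterChain = "seedsOnly",
                   rngSeed = 5L, maxRefillAttempts = 2L)
  expect_error(suppressMessages(runEvolution(cfg)),
               "refill exhausted.*mutation")
})

test_that("every surviving molecule still passes the filter chain", {
  path <- writeFixtureSmi()
  cfg <- smallConfig(path)
  res <- suppressMessages(runEvolution(cfg))
  recheck <- applyFilterChain(res$records, cfg$filterChain)
  expect_length(recheck$survivors, length(res$records))
})

test_that("generation outputs and the ledger are written to disk", {
  path <- writeFixtureSmi()
  out <- tempfile()
  cfg <- smallConfig(path, outputDir = out)
  res <- suppressMessages(runEvolution(cfg))
  expect_true(file.exists(file.path(out, "generation_0", "ranked.smi")))
  expect_true(file.exists(file.path(out, "generation_2", "ranked.smi")))
  expect_true(file.exists(file.path(out, "ledger.tsv")))
  expect_true(file.exists(file.path(out, "summaries.tsv")))
  back <- readLedger(file.path(out, "ledger.tsv"))
  expect_length(back, length(res$ledger))
})

test_that("variant enumeration reduces to the best variant score", {
  path <- writeFixtureSmi()
  # an enumerator returning the molecule plus benzene: every compound's
  # score becomes at most benzene's -1.6
  cfg <- runConfig(path, generations = 1L, nElitism = 2L, nMutation = 0L,
                   nCrossover = 0L, rngSeed = 2L,
                   maxVariantsPerMolecule = 2L,
                   variantEnumerator = function(s) c(s, "c1ccccc1"))
  res <- suppressMessages(runEvolution(cfg))
  expect_true(all(vapply(res$records, function(r)
    scores(r)[["primary"]], 0) <= -1.6))
})

test_that("configuration errors surface before any work happens", {
  expect_error(runConfig("x.smi", generations = 0L))
  expect_error(runConfig("x.smi", filterChain = "NoSuch"), "unknown")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seedSmiPath = "x.smi", badKey = 1), f,
                       auto_unbox = TRUE)
  expect_error(readRunConfig(f), "badKey")
})

test_that("the weight-drift utility reports per-event changes", {
  path <- writeFixtureSmi()
  cfg <- smallConfig(path)
  res <- suppressMessages(runEvolution(cfg))
  drift <- operatorMwDrift(res$ledger)
  expect_true(all(drift$operator %in% c("mutation", "crossover")))
  expect_equal(drift$delta_mw, drift$child_mw - drift$parent_mw)
  expect_gt(nrow(drift), 0L)
})

# --- BRICS ----------------------------------------------------------------

test_that("BRICS leaves uncleavable molecules alone", {
  expect_length(bricsFragment("c1ccccc1"), 0L)
  expect_identical(bricsFragment("c1ccccc1", keepUncleaved = TRUE),
                   "c1ccccc1")
})

test_that("BRICS splits amide-linked systems into sensible pieces", {
  frags <- bricsFragment("CC(=O)Nc1ccccc1")
  expect_gte(length(frags), 2L)
  expect_true("c1ccccc1" %in% frags)
  # duplicated input adds nothing
  expect_identical(bricsFragment(rep("CC(=O)Nc1ccccc1", 2L)), frags)
})

test_that("BRICS fragments match a reference decomposition", {
  # ethyl benzoate: the published rules cut the acyl-O, O-alkyl and
  # aryl-acyl bonds, leaving ethane, the ester oxygen, the carbonyl
  # fragment and benzene (heavy-atom counts frozen from an independent
  # implementation of the same rules)
  frags <- bricsFragment("CCOC(=O)c1ccccc1")
  heavy <- sort(vapply(frags, function(s)
    computeDescriptors(s)$heavy_atoms, 0))
  expect_equal(unname(heavy), c(1, 2, 2, 6))
  expect_true("c1ccccc1" %in% frags)
})

# --- fixtures -------------------------------------------------------------

test_that("fixture libraries honour class, size and drug-likeness", {
  set.seed(1)
  fx <- generateFixtureLibrary(list(alcohol = 3))
  expect_length(fx, 3L)
  expect_false(anyDuplicated(fx) > 0L)
  for (s in fx) {
    expect_true(evoligand:::.smartsHit("[OX2H][C;X4]", s))
    d <- computeDescriptors(s)
    expect_lte(d$heavy_atoms, 20L)
    expect_true(evaluatePropertyFilter(d[1, ],
                                       propertyFilterSpec("Lipinski*"))$pass)
  }
  set.seed(9)
  az <- generateFixtureLibrary(list(azide = 2, `terminal alkyne` = 2))
  expect_length(az, 4L)
  expect_error(generateFixtureLibrary(list(plutonium = 1)), "unknown")
})

test_that("fixture generation is deterministic under a seed", {
  set.seed(5); a <- generateFixtureLibrary(list(alcohol = 4))
  set.seed(5); b <- generateFixtureLibrary(list(alcohol = 4))
  expect_identical(a, b)
})
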