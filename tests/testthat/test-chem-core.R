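# Molecule records: canonicalization, SMI I/O, descriptors, lineage.

test_that("canonicalization maps spellings of one graph to one string", {
  expect_identical(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  expect_identical(canonicalizeSmiles("CCO"),
                   canonicalizeSmiles(canonicalizeSmiles("CCO")))
  expect_identical(canonicalizeSmiles("c1ccccc1"),
                   canonicalizeSmiles("C1=CC=CC=C1"))
  expect_error(canonicalizeSmiles("C1CC"), "ring")
  expect_error(canonicalizeSmiles("C(C)(C)(C)(C)C"), "valence")
  expect_error(canonicalizeSmiles(""), "empty")
})

test_that("canonicalization is a fixed point on generated molecules", {
  set.seed(11)
  smi <- generateFixtureLibrary(list(alcohol = 6, `carboxylic acid` = 6,
                                     `primary amine` = 6, azide = 6,
                                     `terminal alkyne` = 6,
                                     `aryl halide` = 6))
  can <- canonicalizeSmiles(smi)
  expect_identical(canonicalizeSmiles(can), can)
})

test_that("readSmi parses names, skips or fails on bad lines", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "# a comment", "", "c1ccccc1 benzene"), f)
  recs <- readSmi(f)
  expect_length(recs, 2L)
  expect_identical(molId(recs[[1]]), "ethanol")
  expect_identical(smiles(recs[[1]]), "CCO")
  expect_identical(origin(recs[[1]]), "seed")
  expect_identical(generation(recs[[1]]), 0L)

  writeLines(character(), f)
  expect_length(readSmi(f), 0L)

  writeLines(c("CCO", "C1CC"), f)
  expect_error(readSmi(f, onBadLine = "fail"), "line 2")
  expect_length(suppressMessages(readSmi(f, onBadLine = "skip")), 1L)
})

test_that("salts keep their largest fragment on input", {
  f <- tempfile(fileext = ".smi")
  writeLines("[Na+].CC(=O)[O-] sodium_acetate", f)
  recs <- readSmi(f)
  expect_length(recs, 1L)
  expect_false(grepl("Na", smiles(recs[[1]])))
})

test_that("descriptors match hand-derived values", {
  d <- computeDescriptors(c("C", "CCO", "c1ccccc1"))
  # methane
  expect_equal(d$heavy_atoms[1], 1)
  expect_equal(d$rings[1], 0)
  expect_equal(d$rotb[1], 0)
  expect_equal(d$hbd[1], 0)
  expect_equal(d$hba[1], 0)
  # ethanol: 2*12.011 + 6*1.008 + 15.999
  expect_equal(d$mw[2], 46.07, tolerance = 0.01)
  expect_equal(d$hbd[2], 1)
  expect_equal(d$hba[2], 1)
  expect_equal(d$o_count[2], 1)
  expect_equal(d$x_count[2], 0)
  # benzene: no polar atoms, one ring
  expect_equal(d$rings[3], 1)
  expect_equal(d$heavy_atoms[3], 6)
  expect_equal(d$n_count[3], 0)
  expect_equal(d$psa[3], 0)
})

test_that("molecular weight is additive over standard atomic masses", {
  masses <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
              F = 18.998, P = 30.974, S = 32.065, Cl = 35.453,
              Br = 79.904, I = 126.904)
  # independent oracle: parse the Hill formula reported by the backend
  formulaMass <- function(smiles) {
    p <- ChemmineOB::forEachMol("SMILES", paste(smiles, "x"),
                                function(m) ChemmineOB::prop_OB(m))[[1]]
    f <- p$formula
    tot <- 0
    for (m in gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE)[[1]] |>
         (\(ix) regmatches(f, list(ix))[[1]])()) {
      sym <- gsub("[0-9]", "", m)
      cnt <- gsub("[^0-9]", "", m)
      tot <- tot + masses[[sym]] * (if (nzchar(cnt)) as.integer(cnt) else 1L)
    }
    tot
  }
  for (s in c("CCO", "CC(=O)Nc1ccc(O)cc1", "O=[N+]([O-])c1ccccc1",
              "FC(F)(F)c1ccccc1", "CCS")) {
    expect_equal(computeDescriptors(s)$mw, formulaMass(s),
                 tolerance = 0.01)
  }
})

test_that("descriptors are deterministic", {
  a <- computeDescriptors("CC(=O)Nc1ccc(O)cc1")
  b <- computeDescriptors("CC(=O)Nc1ccc(O)cc1")
  expect_identical(a, b)
})

test_that("record validity enforces the provenance contract", {
  expect_error(moleculeRecord("CCO", id = "x", origin = "mutation",
                              parentIds = "p"),
               "reactionName")
  expect_error(moleculeRecord("CCO", id = "x", origin = "crossover",
                              parentIds = "p"),
               "2 parent")
  expect_error(moleculeRecord("CCO", id = "x", origin = "seed",
                              parentIds = "p"),
               "0 parent")
  rec <- moleculeRecord("CCO", id = "x", origin = "mutation",
                        parentIds = "p", reactionName = "esterification")
  expect_s4_class(rec, "MoleculeRecord")
})

test_that("lineage tracing reaches generation-0 seeds and flags gaps", {
  s1 <- moleculeRecord("CCO", id = "s1")
  s2 <- moleculeRecord("CCN", id = "s2")
  x <- moleculeRecord("CCOCC", id = "x1", generation = 1L,
                      origin = "crossover", parentIds = c("s1", "s2"))
  ledger <- list(s1, s2, x)
  tree <- traceLineage("x1", ledger)
  expect_identical(tree$id, "x1")
  expect_length(tree$parents, 2L)
  expect_true(all(vapply(tree$parents,
                         function(p) p$origin == "seed", TRUE)))
  single <- traceLineage("s1", ledger)
  expect_length(single$parents, 0L)
  expect_error(traceLineage("nope", ledger), "not found")
  dangling <- moleculeRecord("CCC", id = "d", generation = 1L,
                             origin = "elitism", parentIds = "ghost")
  expect_error(traceLineage("d", c(ledger, dangling)), "ghost")
})

test_that("the ledger round-trips through its tab-separated form", {
  recs <- list(
    moleculeRecord("CCO", id = "a", scores = c(primary = -1.3)),
    moleculeRecord("CCOC(=O)C", id = "b", generation = 1L,
                   origin = "mutation", parentIds = "a",
                   reactionName = "ester_fischer:CCO",
                   scores = c(primary = -2, diversity = 0.5)))
  f <- tempfile(fileext = ".tsv")
  writeLedger(recs, f)
  back <- readLedger(f)
  expect_length(back, 2L)
  expect_identical(smiles(back[[2]]), smiles(recs[[2]]))
  expect_identical(parentIds(back[[2]]), "a")
  expect_equal(scores(back[[2]])[["primary"]], -2)
  expect_identical(back[[2]]@reactionName, "ester_fischer:CCO")
})
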