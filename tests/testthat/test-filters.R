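# Drug-likeness filters: Table of nine default rules, alert catalogs,
# and filter chains.

test_that("exactly the nine default filters are registered", {
  expect_setequal(registeredFilters(),
                  c("Lipinski", "Lipinski*", "Ghose", "Ghose*",
                    "VandeWaterbeemd", "Mozziconacci",
                    "BRENK", "NIH", "PAINS"))
})

test_that("Lipinski allows one violation, Lipinski* none", {
  d <- list(mw = 501, logp = 1.0, hbd = 1, hba = 2)
  lip <- evaluatePropertyFilter(d, propertyFilterSpec("Lipinski"))
  expect_true(lip$pass)
  expect_identical(lip$violations, "mw")
  lipStar <- evaluatePropertyFilter(d, propertyFilterSpec("Lipinski*"))
  expect_false(lipStar$pass)
})

test_that("violations are counted per bound", {
  d <- list(mw = 501, logp = 6, hbd = 1, hba = 2)
  res <- evaluatePropertyFilter(d, propertyFilterSpec("Lipinski"))
  expect_false(res$pass)  # two violations, only one allowed
  expect_setequal(res$violations, c("mw", "logp"))
})

test_that("Ghose* relaxes only the weight ceiling to 500", {
  d <- list(mw = 490, logp = 2, mr = 80, n_atoms = 40)
  expect_false(evaluatePropertyFilter(d, propertyFilterSpec("Ghose"))$pass)
  expect_true(evaluatePropertyFilter(d, propertyFilterSpec("Ghose*"))$pass)
  g <- propertyFilterSpec("Ghose*")
  expect_equal(g@bounds$upper[g@bounds$descriptor == "mw"], 500)
})

test_that("boundary values pass non-strict bounds and fail strict ones", {
  at500 <- list(mw = 500, logp = 2, hbd = 1, hba = 2)
  expect_true(evaluatePropertyFilter(at500,
                                     propertyFilterSpec("Lipinski*"))$pass)
  # Van de Waterbeemd prints "< 450", "< 90": the boundary itself fails
  at450 <- list(mw = 450, psa = 20)
  expect_false(evaluatePropertyFilter(
    at450, propertyFilterSpec("VandeWaterbeemd"))$pass)
  ethanol <- computeDescriptors("CCO")[1, ]
  expect_true(evaluatePropertyFilter(
    ethanol, propertyFilterSpec("VandeWaterbeemd"))$pass)
})

test_that("a missing descriptor is a configuration error", {
  expect_error(evaluatePropertyFilter(list(mw = 100),
                                      propertyFilterSpec("Lipinski")),
               "missing")
})

test_that("rule hierarchies are monotone over random descriptor sets", {
  set.seed(404)
  d <- randomDescriptors(10000)
  lip <- propertyFilterSpec("Lipinski")
  lipStar <- propertyFilterSpec("Lipinski*")
  gh <- propertyFilterSpec("Ghose")
  ghStar <- propertyFilterSpec("Ghose*")
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    if (evaluatePropertyFilter(row, lipStar)$pass) {
      expect_true(evaluatePropertyFilter(row, lip)$pass)
    }
    if (evaluatePropertyFilter(row, gh)$pass) {
      expect_true(evaluatePropertyFilter(row, ghStar)$pass)
    }
  }
})

test_that("alert catalogs flag known bad actors and clear ethanol", {
  brenk <- loadAlertCatalog("BRENK")
  expect_length(brenk@patterns, 105L)
  clean <- evaluateSubstructureFilter("CCO", brenk)
  expect_true(clean$pass)
  expect_length(clean$matched, 0L)
  azo <- evaluateSubstructureFilter("CC/N=N/CC", brenk)
  expect_false(azo$pass)
  expect_true(any(grepl("azo|diazo", azo$matched, ignore.case = TRUE)))
})

test_that("NIH and PAINS catalogs load with their published sizes", {
  expect_length(loadAlertCatalog("NIH")@patterns, 180L)
  expect_length(loadAlertCatalog("PAINS")@patterns, 480L)
})

test_that("an empty catalog passes everything", {
  cat0 <- new("SubstructureFilter", name = "custom",
              patterns = character(), labels = character())
  expect_true(evaluateSubstructureFilter("CC/N=N/CC", cat0)$pass)
})

test_that("disconnected alert patterns respect multiplicity", {
  diester <- new("SubstructureFilter", name = "custom",
                 patterns = "C(=O)O[C,H1].C(=O)O[C,H1].C(=O)O[C,H1]",
                 labels = "three_esters")
  expect_true(evaluateSubstructureFilter("CC(=O)OC", diester)$pass)
  triacetin <- "CC(=O)OCC(OC(C)=O)COC(C)=O"
  expect_false(evaluateSubstructureFilter(triacetin, diester)$pass)
})

test_that("filter chains are AND-semantics with first-rejector counts", {
  recs <- list(moleculeRecord("CCO", id = "ethanol"),
               moleculeRecord(paste0("C", strrep("(F)(F)C", 20), "F"),
                              id = "heavy"))
  none <- applyFilterChain(recs, character())
  expect_length(none$survivors, 2L)
  out <- applyFilterChain(recs, "Lipinski*")
  expect_length(out$survivors, 1L)
  expect_identical(molId(out$survivors[[1]]), "ethanol")
  expect_equal(sum(out$rejections), 1L)
  expect_error(applyFilterChain(recs, "NoSuchFilter"), "unknown filter")
})

test_that("the survivor set does not depend on chain order", {
  recs <- lapply(seq_along(fixtureSeeds), function(i) {
    moleculeRecord(fixtureSeeds[i], id = paste0("m", i),
                   canonicalize = FALSE)
  })
  ab <- applyFilterChain(recs, c("Ghose", "Lipinski*"))
  ba <- applyFilterChain(recs, c("Lipinski*", "Ghose"))
  expect_identical(vapply(ab$survivors, molId, ""),
                   vapply(ba$survivors, molId, ""))
})

test_that("rejection counts account for every non-survivor", {
  recs <- lapply(seq_along(fixtureSeeds), function(i) {
    moleculeRecord(fixtureSeeds[i], id = paste0("m", i),
                   canonicalize = FALSE)
  })
  out <- applyFilterChain(recs, c("Ghose", "Lipinski*", "PAINS"))
  expect_equal(sum(out$rejections),
               length(recs) - length(out$survivors))
})

test_that("custom predicate filters join the registry", {
  registerFilter("tiny", function(desc, smiles) desc[["heavy_atoms"]] <= 3)
  on.exit(rm("tiny", envir = evoligand:::.filterRegistry))
  recs <- list(moleculeRecord("CCO", id = "a"),
               moleculeRecord("CCCCCC", id = "b"))
  out <- applyFilterChain(recs, "tiny")
  expect_identical(vapply(out$survivors, molId, ""), "a")
})
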