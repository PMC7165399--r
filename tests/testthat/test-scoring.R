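# Fitness: fingerprints, Dice similarity, diversity, ligand efficiency,
# the surrogate scorer, and population scoring.

test_that("fingerprints are deterministic and structure-sensitive", {
  expect_identical(morganFingerprint("CCO")@bits,
                   morganFingerprint("CCO")@bits)
  expect_identical(morganFingerprint(canonicalizeSmiles("OCC"))@bits,
                   morganFingerprint(canonicalizeSmiles("CCO"))@bits)
  expect_false(identical(morganFingerprint("CCO")@bits,
                         morganFingerprint("c1ccccc1")@bits))
})

test_that("Dice similarity reproduces its defining arithmetic", {
  fp <- function(bits) new("Fingerprint", bits = as.integer(bits),
                           nbits = 256L, radius = 2L)
  expect_equal(diceSimilarity(fp(0:16), fp(0:16)), 1)
  expect_equal(diceSimilarity(fp(0:3), fp(10:15)), 0)
  expect_equal(diceSimilarity(fp(c(1, 2, 3, 4)), fp(c(3, 4, 5, 6, 7, 8))),
               0.4)
  selfFp <- morganFingerprint("CCO")
  expect_equal(diceSimilarity(selfFp, selfFp), 1)
  expect_warning(res <- diceSimilarity(fp(integer()), fp(integer())),
                 "empty")
  expect_equal(res, 0)
})

test_that("Dice matches a set-arithmetic oracle on random bit sets", {
  set.seed(202)
  for (k in 1:1000) {
    fa <- randomFingerprint(); fb <- randomFingerprint()
    oracle <- 2 * sum(fa@bits %in% fb@bits) /
      (length(fa@bits) + length(fb@bits))
    expect_identical(diceSimilarity(fa, fb), oracle)
    expect_gte(oracle, 0); expect_lte(oracle, 1)
  }
})

test_that("diversity scores equal the pairwise-sum definition", {
  fpA <- morganFingerprint("CCO")
  fpB <- morganFingerprint("c1ccccc1")
  expect_equal(diversityScores(list(fpA, fpA, fpA)), c(2, 2, 2))
  expect_equal(diversityScores(list(fpA, fpB)), c(0, 0))
  expect_equal(diversityScores(list(fpA)), 0)
  s <- diceSimilarity(fpA, fpB)
  expect_equal(diversityScores(list(fpA, fpA, fpB)),
               c(1 + s, 1 + s, 2 * s))
})

test_that("diversity matches a matrix oracle on random populations", {
  set.seed(303)
  for (rep in 1:5) {
    n <- sample(2:50, 1)
    fps <- replicate(n, randomFingerprint(), simplify = FALSE)
    # independent oracle: full similarity matrix, row sums minus diagonal
    m <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      a <- fps[[i]]@bits; b <- fps[[j]]@bits
      m[i, j] <- 2 * length(intersect(a, b)) / (length(a) + length(b))
    }
    oracle <- rowSums(m) - diag(m)
    d <- diversityScores(fps)
    expect_equal(d, oracle, tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= n - 1 + 1e-12))
  }
})

test_that("diversity is permutation-equivariant", {
  set.seed(7)
  fps <- replicate(12, randomFingerprint(), simplify = FALSE)
  d <- diversityScores(fps)
  perm <- sample(12)
  expect_equal(diversityScores(fps[perm]), d[perm])
})

test_that("ligand efficiency divides by heavy atoms, sign preserved", {
  expect_equal(ligandEfficiency(-10, 20), -0.5)
  expect_equal(ligandEfficiency(-10, 1), -10)
  expect_equal(ligandEfficiency(0, 35), 0)
  expect_error(ligandEfficiency(-10, 0), "heavyAtoms")
})

test_that("the surrogate scorer follows its defining formula", {
  d <- computeDescriptors(c("C", "c1ccccc1", "CCO"))
  expect_equal(surrogateScore(d[1, ]), -0.1)
  expect_equal(surrogateScore(d[2, ]), -1.6)
  expect_equal(surrogateScore(d[3, ]), -1.3)
})

test_that("population scoring attaches every fitness component", {
  recs <- lapply(c("C", "c1ccccc1", "CCO"),
                 function(s) moleculeRecord(s, id = s))
  out <- scorePopulation(recs)
  primaries <- vapply(out, function(r) scores(r)[["primary"]], 0)
  expect_equal(primaries, c(-0.1, -1.6, -1.3))
  expect_equal(which.min(primaries), 2L)  # benzene is fittest
  expect_equal(scores(out[[2]])[["ligand_efficiency"]], -1.6 / 6)
  expect_true(all(vapply(out, function(r)
    "diversity" %in% names(scores(r)), TRUE)))
  expect_length(scorePopulation(list()), 0L)
})

test_that("per-molecule scorer failures get a sentinel and are flagged", {
  recs <- lapply(c("C", "CC", "CCC"), function(s) moleculeRecord(s, id = s))
  patchy <- function(smiles) ifelse(smiles == "CC", NA_real_,
                                    -nchar(smiles))
  out <- suppressMessages(scorePopulation(recs, patchy))
  p <- vapply(out, function(r) scores(r)[["primary"]], 0)
  expect_true(is.infinite(p[2]))
  expect_true(all(is.finite(p[c(1, 3)])))
  broken <- function(smiles) "not a number"
  expect_error(scorePopulation(recs, broken), "contract")
})

test_that("unimplemented rescoring contracts refuse loudly", {
  expect_error(fitnessFunction("nnscore1"), "not.*implemented")
  expect_error(fitnessFunction("nnscore2"), "not.*implemented")
  expect_error(fitnessFunction("mystery"), "unknown")
})
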