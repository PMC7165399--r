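# Selectors and seed-pool composition.

poolOf <- function(scores, diversity = rep(0, length(scores))) {
  lapply(seq_along(scores), function(i) {
    scoredRecord(paste0(strrep("C", i + 1)), paste0("r", i),
                 scores[i], diversity[i])
  })
}

test_that("ranking selection equals a sort-and-slice oracle", {
  pool <- poolOf(c(-5, -7, -6))
  top2 <- rankingSelect(pool, 2)
  expect_equal(vapply(top2, function(r) scores(r)[["primary"]], 0),
               c(-7, -6))
  expect_length(rankingSelect(pool, 0), 0L)
  expect_warning(all3 <- rankingSelect(pool, 10), "whole pool")
  expect_length(all3, 3L)
  set.seed(88)
  for (rep in 1:20) {
    s <- round(runif(15, -10, 0), 2)
    pool <- poolOf(s)
    k <- sample(0:15, 1)
    got <- vapply(rankingSelect(pool, k),
                  function(r) scores(r)[["primary"]], 0)
    expect_equal(got, sort(s)[seq_len(k)])
  }
})

test_that("score ties break lexicographically by SMILES", {
  pool <- list(scoredRecord("CCCC", "w", -5),
               scoredRecord("CC", "z", -5),
               scoredRecord("CCC", "a", -5))
  got <- rankingSelect(pool, 1)
  expect_identical(smiles(got[[1]]), "CC")
})

test_that("roulette draws follow the stated wheel areas", {
  pool1 <- poolOf(-3)
  set.seed(1)
  expect_identical(molId(rouletteSelect(pool1, 1)[[1]]), "r1")
  # k = pool size exhausts the wheel: a permutation of the pool
  pool <- poolOf(c(-1, -2, -3, -4))
  set.seed(2)
  perm <- rouletteSelect(pool, 4)
  expect_setequal(vapply(perm, molId, ""), paste0("r", 1:4))
  # three records engineered so the first two wheel areas sit at 3:1
  # under w = (worst - s) + 0.01 * (worst - best) with worst = 0
  s3 <- c(-3 / 0.98, -1, 0)
  pool2 <- list(scoredRecord("CC", "heavy", s3[1]),
                scoredRecord("CCC", "light", s3[2]),
                scoredRecord("CCCC", "worst", s3[3]))
  w <- evoligand:::.rouletteWeights(s3, "min")
  expect_equal(w[1] / w[2], 3, tolerance = 1e-10)
  expect_gt(w[3], 0)  # even the worst record keeps a non-zero area
  set.seed(3)
  n <- 10000
  wins <- integer(3)
  for (k in seq_len(n)) {
    got <- molId(rouletteSelect(pool2, 1)[[1]])
    i <- match(got, c("heavy", "light", "worst"))
    wins[i] <- wins[i] + 1L
  }
  pExp <- w / sum(w)
  for (i in 1:3) {
    se <- sqrt(pExp[i] * (1 - pExp[i]) / n)
    expect_lt(abs(wins[i] / n - pExp[i]), 3 * se)
  }
})

test_that("identical scores make roulette uniform", {
  pool <- poolOf(c(-2, -2, -2, -2))
  w <- evoligand:::.rouletteWeights(c(-2, -2, -2, -2), "min")
  expect_true(all(w == w[1]))
})

test_that("tournament selection interpolates ranking and uniform", {
  pool <- poolOf(c(-1, -5, -3, -9, -7))
  set.seed(4)
  full <- tournamentSelect(pool, 3, fraction = 1.0)
  expect_identical(vapply(full, molId, ""),
                   vapply(rankingSelect(pool, 3), molId, ""))
  # the best record wins every tournament that samples it
  set.seed(5)
  for (k in 1:200) {
    got <- tournamentSelect(pool, 1, fraction = 0.4)
    best <- min(vapply(pool, function(r) scores(r)[["primary"]], 0))
    idx <- sample.int(5, 2)  # burn unrelated randomness
    expect_true(scores(got[[1]])[["primary"]] <= -1)
  }
  # dominance: better records are selected at least as often
  set.seed(6)
  counts <- c(a = 0L, b = 0L)
  poolAB <- poolOf(c(-8, -2, -5, -5, -5))
  for (k in 1:2000) {
    w <- molId(tournamentSelect(poolAB, 1, fraction = 0.4)[[1]])
    if (w == "r1") counts["a"] <- counts["a"] + 1L
    if (w == "r2") counts["b"] <- counts["b"] + 1L
  }
  expect_gt(counts[["a"]], counts[["b"]])
})

test_that("seed pools merge score and diversity picks without overlap", {
  set.seed(9)
  recs <- lapply(1:12, function(i) {
    scoredRecord(paste0(strrep("C", i + 1)), paste0("r", i),
                 primary = -i, diversity = i / 2)
  })
  pools <- buildSeedPools(recs,
                          counts = list(elitism = c(3, 2),
                                        mutation = c(3, 2),
                                        crossover = c(3, 2)),
                          selector = "ranking")
  for (pl in list(pools@elitism, pools@mutation, pools@crossover)) {
    ids <- vapply(pl, molId, "")
    expect_length(ids, 5L)
    expect_false(anyDuplicated(ids) > 0L)
  }
  # ranking: the three subselections are identical
  expect_identical(vapply(pools@elitism, molId, ""),
                   vapply(pools@mutation, molId, ""))
  expect_identical(vapply(pools@mutation, molId, ""),
                   vapply(pools@crossover, molId, ""))
})

test_that("stochastic selectors give reproducible, non-identical pools", {
  recs <- lapply(1:12, function(i) {
    scoredRecord(paste0(strrep("C", i + 1)), paste0("r", i),
                 primary = -i, diversity = i / 2)
  })
  cts <- list(elitism = c(4, 0), mutation = c(4, 0), crossover = c(4, 0))
  set.seed(10)
  a <- buildSeedPools(recs, cts, selector = "roulette")
  set.seed(10)
  b <- buildSeedPools(recs, cts, selector = "roulette")
  expect_identical(vapply(a@mutation, molId, ""),
                   vapply(b@mutation, molId, ""))
})

test_that("pure score-based seeding works with zero diversity picks", {
  recs <- lapply(1:6, function(i) {
    scoredRecord(paste0(strrep("C", i + 1)), paste0("r", i), -i, i)
  })
  pools <- buildSeedPools(recs,
                          counts = list(elitism = c(2, 0),
                                        mutation = c(2, 0),
                                        crossover = c(2, 0)),
                          selector = "ranking")
  expect_identical(vapply(pools@elitism, molId, ""), c("r6", "r5"))
})

test_that("sentinel-scored records never enter seed pools", {
  recs <- c(lapply(1:4, function(i) {
    scoredRecord(paste0(strrep("C", i + 1)), paste0("r", i), -i, 0)
  }), list(scoredRecord("CCCCCCC", "bad", Inf, 0)))
  pools <- buildSeedPools(recs,
                          counts = list(elitism = c(5, 0),
                                        mutation = c(5, 0),
                                        crossover = c(5, 0)),
                          selector = "ranking")
  expect_false("bad" %in% vapply(pools@elitism, molId, ""))
})
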