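# Seed selection: Ranking, Roulette and Tournament selectors, and the
# three per-generation seed pools they feed.

# safe score lookup on the named score vector (NA when absent)
.getScore <- function(r, key) {
  v <- unname(r@scores[key])
  if (length(v) == 0L) NA_real_ else v
}

.scoreVec <- function(pool, key) {
  vapply(pool, function(r) {
    v <- .getScore(r, key)
    if (is.na(v)) stop("record '", r@id, "' carries no '", key,
                       "' score", call. = FALSE)
    v
  }, 0)
}

# deterministic tie-break order: score (direction-aware), then canonical
# SMILES lexicographically (C locale), then id
.rankOrder <- function(pool, key, direction) {
  s <- .scoreVec(pool, key)
  if (direction == "max") s <- -s
  smi <- vapply(pool, function(r) r@smiles, "")
  ids <- vapply(pool, function(r) r@id, "")
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  order(s, smi, ids)
}

#' Ranking selection
#'
#' Deterministically picks the k best records by a score. Ties at the cut
#' are broken by canonical SMILES (lexicographic) and then id, so the
#' selection is reproducible.
#'
#' @param pool list of scored \linkS4class{MoleculeRecord}.
#' @param k number of records to select.
#' @param key score name (\code{"primary"} or \code{"diversity"}).
#' @param direction \code{"min"} (docking convention) or \code{"max"}.
#' @return list of selected records, best first.
#' @export
rankingSelect <- function(pool, k, key = "primary",
                          direction = c("min", "max")) {
  direction <- match.arg(direction)
  stopifnot(k >= 0)
  if (k > length(pool)) {
    warning("requested ", k, " records from a pool of ", length(pool),
            "; returning the whole pool")
    k <- length(pool)
  }
  if (k == 0L) return(list())
  pool[.rankOrder(pool, key, direction)[seq_len(k)]]
}

# roulette weights: shifted-linear transform guaranteeing a non-zero
# chance for the worst record
.rouletteWeights <- function(s, direction, eps = 0.01) {
  if (direction == "max") s <- -s
  worst <- max(s); best <- min(s)
  if (worst == best) return(rep(1, length(s)))
  (worst - s) + eps * (worst - best)
}

#' Roulette-wheel selection
#'
#' Draws k records without replacement with probability proportional to a
#' fitness-derived wheel area: \code{(worst - score) + 0.01 * (worst -
#' best)} for direction \code{"min"} (mirrored for \code{"max"}),
#' renormalized after each draw. Every record -- even the least fit --
#' keeps a non-zero chance of advancing. Identical scores reduce to
#' uniform sampling.
#'
#' @inheritParams rankingSelect
#' @return list of selected records.
#' @export
rouletteSelect <- function(pool, k, key = "primary",
                           direction = c("min", "max")) {
  direction <- match.arg(direction)
  stopifnot(k >= 0)
  if (k > length(pool)) {
    warning("requested ", k, " records from a pool of ", length(pool),
            "; returning the whole pool")
    k <- length(pool)
  }
  if (k == 0L) return(list())
  w <- .rouletteWeights(.scoreVec(pool, key), direction)
  pool[sample.int(length(pool), k, replace = FALSE, prob = w)]
}

#' Tournament selection
#'
#' Repeats k rounds: sample \code{ceiling(fraction * poolsize)} records
#' uniformly (at least 1) from the remaining pool and advance the best by
#' the score; winners leave the pool between rounds. With
#' \code{fraction = 1} every tournament sees the whole pool and the result
#' equals ranking selection; as the tournament shrinks to one record the
#' selection becomes uniform.
#'
#' @inheritParams rankingSelect
#' @param fraction tournament size as a fraction of the pool, in (0, 1].
#' @return list of selected records.
#' @export
tournamentSelect <- function(pool, k, fraction = 0.1, key = "primary",
                             direction = c("min", "max")) {
  direction <- match.arg(direction)
  stopifnot(k >= 0, fraction > 0, fraction <= 1)
  winners <- list()
  remaining <- pool
  while (length(winners) < k && length(remaining) > 0L) {
    m <- max(1L, ceiling(fraction * length(remaining)))
    idx <- sample.int(length(remaining), m, replace = FALSE)
    sub <- remaining[idx]
    bestLocal <- .rankOrder(sub, key, direction)[1]
    winners[[length(winners) + 1L]] <- sub[[bestLocal]]
    remaining <- remaining[-idx[bestLocal]]
  }
  if (length(winners) < k) {
    warning("pool exhausted after ", length(winners), " of ", k, " rounds")
  }
  winners
}

#' Build the three per-generation seed pools
#'
#' Performs the three subselections that seed the elitism, mutation and
#' crossover operators. Each subselection takes \code{nByScore} records on
#' the primary score and \code{nByDiversity} on the diversity score (both
#' direction \code{"min"}: the smallest diversity sum is the most
#' structurally unique), merged without duplicates -- a diversity pick that
#' duplicates a score pick is redrawn from the rest. With the Ranking
#' selector the three subselections are identical; with Roulette or
#' Tournament they are independent draws that may overlap.
#'
#' Records whose primary score is the failure sentinel are excluded before
#' selection.
#'
#' @param population scored list of \linkS4class{MoleculeRecord}.
#' @param counts named list with entries \code{elitism}, \code{mutation},
#'   \code{crossover}, each \code{c(nByScore, nByDiversity)}.
#' @param selector \code{"ranking"}, \code{"roulette"} or
#'   \code{"tournament"}.
#' @param tournamentFraction tournament size fraction.
#' @return a \linkS4class{SeedPools}.
#' @export
buildSeedPools <- function(population,
                           counts = list(elitism = c(10L, 0L),
                                         mutation = c(10L, 0L),
                                         crossover = c(10L, 0L)),
                           selector = c("ranking", "roulette", "tournament"),
                           tournamentFraction = 0.1) {
  selector <- match.arg(selector)
  eligible <- Filter(function(r) {
    v <- .getScore(r, "primary")
    !is.na(v) && is.finite(v)
  }, population)
  if (length(eligible) == 0L) {
    stop("no scored records available for seed selection", call. = FALSE)
  }
  sel <- function(pool, k, key) {
    switch(selector,
           ranking = rankingSelect(pool, k, key, "min"),
           roulette = rouletteSelect(pool, k, key, "min"),
           tournament = tournamentSelect(pool, k, tournamentFraction, key,
                                         "min"))
  }
  onePool <- function(nScore, nDiv) {
    byScore <- sel(eligible, min(nScore, length(eligible)), "primary")
    ids <- vapply(byScore, function(r) r@id, "")
    rest <- Filter(function(r) !(r@id %in% ids), eligible)
    byDiv <- sel(rest, min(nDiv, length(rest)), "diversity")
    c(byScore, byDiv)
  }
  new("SeedPools",
      elitism = onePool(counts$elitism[1], counts$elitism[2]),
      mutation = onePool(counts$mutation[1], counts$mutation[2]),
      crossover = onePool(counts$crossover[1], counts$crossover[2]))
}
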