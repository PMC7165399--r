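# The generation loop: seed pools -> elitism / mutation / crossover with
# filter refill -> variant enumeration -> scoring -> ranking, plus run
# orchestration and reproducible run summaries.

#' Build a validated run configuration
#'
#' @param seedSmiPath path to the generation-0 SMI file.
#' @param generations number of generations to evolve (>= 1).
#' @param nElitism,nMutation,nCrossover per-generation operator sizes.
#' @param firstGeneration optional named numeric vector
#'   \code{c(nElitism=, nMutation=, nCrossover=)} used for generation 1
#'   only (a conservative first generation).
#' @param filterChain character vector of registered filter names applied
#'   to every generated compound (and to the seeds).
#' @param reactionSet \code{"AllRxn"}, \code{"AutoClickChemRxn"},
#'   \code{"RobustRxn"}, or a path to a reaction-library JSON.
#' @param complementarySmiPath \code{"bundled"} for the packaged reactant
#'   set, or a path to an SMI file of complementary reactants.
#' @param selector \code{"ranking"}, \code{"roulette"} or
#'   \code{"tournament"}.
#' @param tournamentFraction tournament size fraction.
#' @param seedsByScore,seedsByDiversity per-operator seed-pool counts
#'   selected on the primary and the diversity score, as named numeric
#'   vectors \code{c(elitism=, mutation=, crossover=)}.
#' @param fitness fitness function or name, see [fitnessFunction()].
#' @param addLigandEfficiency attach ligand-efficiency scores.
#' @param rescoreElites rescore elite compounds instead of carrying their
#'   scores over unchanged.
#' @param maxVariantsPerMolecule cap forwarded to the variant enumerator.
#' @param variantEnumerator function mapping one SMILES to a character
#'   vector of ionization/tautomer variants (at most
#'   \code{maxVariantsPerMolecule}); the default identity enumerator
#'   returns the input unchanged. Variant scores are reduced to the best
#'   per compound.
#' @param phRange protonation pH range recorded for the enumerator.
#' @param rngSeed integer seed; a fixed seed makes the whole run
#'   deterministic under the surrogate scorer.
#' @param minCoreAtoms smallest acceptable crossover core (heavy atoms).
#' @param crossoverTimeout search budget per parent pair handed to
#'   [largestCommonSubstructure()] (a deterministic node budget scaled in
#'   seconds).
#' @param maxRefillAttempts operator retries allowed per missing molecule
#'   before the run stops with a bottleneck diagnosis.
#' @param parallelism worker count for candidate generation and scoring;
#'   results are independent of the worker count (order-independent
#'   reduction); the bundled implementation maps serially.
#' @param outputDir optional directory for per-generation ranked SMI
#'   files, the run ledger and the summary table.
#' @return a validated configuration list of class \code{evoligandConfig}.
#' @export
runConfig <- function(seedSmiPath,
                      generations = 5L,
                      nElitism = 10L, nMutation = 50L, nCrossover = 50L,
                      firstGeneration = NULL,
                      filterChain = character(),
                      reactionSet = "AllRxn",
                      complementarySmiPath = "bundled",
                      selector = "ranking",
                      tournamentFraction = 0.1,
                      seedsByScore = c(elitism = 10, mutation = 20,
                                       crossover = 20),
                      seedsByDiversity = c(elitism = 0, mutation = 0,
                                           crossover = 0),
                      fitness = "surrogate",
                      addLigandEfficiency = TRUE,
                      rescoreElites = FALSE,
                      maxVariantsPerMolecule = 1L,
                      variantEnumerator = NULL,
                      phRange = c(6.4, 8.4),
                      rngSeed = 42L,
                      minCoreAtoms = 4L,
                      crossoverTimeout = 0.05,
                      maxRefillAttempts = 50L,
                      parallelism = 1L,
                      outputDir = NULL) {
  stopifnot(generations >= 1L, nElitism >= 0L, nMutation >= 0L,
            nCrossover >= 0L, maxRefillAttempts >= 1L,
            maxVariantsPerMolecule >= 1L, parallelism >= 1L,
            length(phRange) == 2L, phRange[1] <= phRange[2])
  selector <- match.arg(selector, c("ranking", "roulette", "tournament"))
  for (nm in filterChain) .resolveFilter(nm)  # fail fast on unknown names
  cfg <- list(seedSmiPath = seedSmiPath,
              generations = as.integer(generations),
              nElitism = as.integer(nElitism),
              nMutation = as.integer(nMutation),
              nCrossover = as.integer(nCrossover),
              firstGeneration = firstGeneration,
              filterChain = filterChain,
              reactionSet = reactionSet,
              complementarySmiPath = complementarySmiPath,
              selector = selector,
              tournamentFraction = tournamentFraction,
              seedsByScore = seedsByScore,
              seedsByDiversity = seedsByDiversity,
              fitness = fitness,
              addLigandEfficiency = addLigandEfficiency,
              rescoreElites = rescoreElites,
              maxVariantsPerMolecule = as.integer(maxVariantsPerMolecule),
              variantEnumerator = variantEnumerator,
              phRange = phRange,
              rngSeed = as.integer(rngSeed),
              minCoreAtoms = as.integer(minCoreAtoms),
              crossoverTimeout = crossoverTimeout,
              maxRefillAttempts = as.integer(maxRefillAttempts),
              parallelism = as.integer(parallelism),
              outputDir = outputDir)
  class(cfg) <- "evoligandConfig"
  cfg
}

#' Read a run configuration from JSON
#'
#' JSON keys mirror the [runConfig()] argument names.
#'
#' @param path JSON file path.
#' @return an \code{evoligandConfig}.
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(runConfig, raw)
}

.resolveReactionSet <- function(reactionSet) {
  if (reactionSet %in% c("AllRxn", "AutoClickChemRxn", "RobustRxn")) {
    bundledReactionLibrary(reactionSet)
  } else loadReactionLibrary(reactionSet)
}

.resolveComplementary <- function(cfg, library) {
  smiles <- if (identical(cfg$complementarySmiPath, "bundled")) {
    path <- system.file("extdata", "complementary_seeds.smi",
                        package = "evoligand", mustWork = TRUE)
    vapply(readSmi(path), function(r) r@smiles, "")
  } else {
    vapply(readSmi(cfg$complementarySmiPath), function(r) r@smiles, "")
  }
  buildComplementaryLibrary(smiles, library)
}

.applyVariants <- function(smiles, cfg) {
  if (is.null(cfg$variantEnumerator)) return(smiles)
  v <- cfg$variantEnumerator(smiles)
  utils::head(unique(v), cfg$maxVariantsPerMolecule)
}

# primary score of one compound under the variant contract: the best
# score over its enumerated variants
.scoreCompound <- function(smiles, scorer, cfg) {
  vars <- .applyVariants(smiles, cfg)
  vals <- scorer(vars)
  if (all(!is.finite(vals))) Inf else min(vals[is.finite(vals)])
}

.generationSizes <- function(cfg, gen) {
  if (gen == 1L && !is.null(cfg$firstGeneration)) {
    fg <- cfg$firstGeneration
    list(nElitism = as.integer(fg[["nElitism"]]),
         nMutation = as.integer(fg[["nMutation"]]),
         nCrossover = as.integer(fg[["nCrossover"]]))
  } else {
    list(nElitism = cfg$nElitism, nMutation = cfg$nMutation,
         nCrossover = cfg$nCrossover)
  }
}

# crossover core cache; cores are pure functions of the (unordered) pair
# and the search parameters, so the cache is package-wide
.coreCached <- function(cacheEnv, a, b, minCoreAtoms = 4L,
                        timeout = 1, ...) {
  key <- paste0("core:", minCoreAtoms, ":", timeout, ":",
                paste(sort(c(a, b)), collapse = "|"))
  if (!exists(key, envir = .pkgCache, inherits = FALSE)) {
    core <- tryCatch(suppressMessages(
      largestCommonSubstructure(a, b, minCoreAtoms = minCoreAtoms,
                                timeout = timeout, ...)),
      error = function(e) NULL)
    assign(key, if (is.null(core)) "none" else core, envir = .pkgCache)
  }
  v <- get(key, envir = .pkgCache)
  if (identical(v, "none")) NULL else v
}

#' Advance the run by one generation
#'
#' Builds the three seed pools from the scored previous generation,
#' advances elites unchanged (or rescored), generates mutation and
#' crossover candidates, deduplicates them by canonical SMILES within the
#' new generation, applies the filter chain, and loops back to the
#' operators on shortfall until the configured sizes are met or the
#' refill budget is exhausted. Survivors pass through the variant
#' contract, are scored, and are ranked.
#'
#' @param state run state: list with elements \code{records} (scored
#'   previous generation), \code{ledger}, \code{generation}.
#' @param cfg an \code{evoligandConfig}.
#' @param library,comp resolved reaction and complementary libraries.
#' @param scorer resolved fitness function.
#' @return list(state, summary): the new state and a one-row summary
#'   data.frame.
#' @export
advanceGeneration <- function(state, cfg, library, comp, scorer) {
  gen <- state$generation + 1L
  sizes <- .generationSizes(cfg, gen)
  counts <- list(
    elitism = c(max(sizes$nElitism, cfg$seedsByScore[["elitism"]]),
                cfg$seedsByDiversity[["elitism"]]),
    mutation = c(cfg$seedsByScore[["mutation"]],
                 cfg$seedsByDiversity[["mutation"]]),
    crossover = c(cfg$seedsByScore[["crossover"]],
                  cfg$seedsByDiversity[["crossover"]]))
  pools <- buildSeedPools(state$records, counts, cfg$selector,
                          cfg$tournamentFraction)
  newRecords <- list()
  seen <- character()        # canonical SMILES already in this generation
  nDuplicates <- 0L
  rejections <- stats::setNames(integer(length(cfg$filterChain)),
                                cfg$filterChain)
  nCreated <- 0L
  counterE <- 0L; counterM <- 0L; counterX <- 0L
  # --- elitism: advance unchanged -----------------------------------------
  nEl <- min(sizes$nElitism, length(pools@elitism))
  if (nEl < sizes$nElitism) {
    warning("elitism pool smaller than requested (", nEl, " < ",
            sizes$nElitism, ")")
  }
  elites <- list()
  if (nEl > 0L) for (r in pools@elitism[seq_len(nEl)]) {
    counterE <- counterE + 1L
    nCreated <- nCreated + 1L
    rec <- moleculeRecord(r@smiles, id = sprintf("g%d_E%d", gen, counterE),
                          generation = gen, origin = "elitism",
                          parentIds = r@id, canonicalize = FALSE)
    if (!cfg$rescoreElites) {
      keep <- r@scores[names(r@scores) != "diversity"]
      rec@scores <- keep
    }
    if (rec@smiles %in% seen) { nDuplicates <- nDuplicates + 1L; next }
    seen <- c(seen, rec@smiles)
    elites[[length(elites) + 1L]] <- rec
  }
  newRecords <- elites
  # --- mutation + crossover with refill loop ------------------------------
  coreCache <- new.env(parent = emptyenv())
  makeBatch <- function(op, need) {
    # chunked generation: raw candidates are produced without
    # sanitization, then canonicalized, deduplicated and filtered in
    # batches (one backend call per chunk instead of per molecule)
    out <- list()
    attempts <- 0L
    maxAtt <- cfg$maxRefillAttempts * max(1L, need)
    pool <- if (op == "mutation") pools@mutation else pools@crossover
    while (length(out) < need && attempts < maxAtt) {
      chunk <- min(max(8L, need - length(out)), 32L,
                   maxAtt - attempts)
      raws <- list()
      for (ci in seq_len(chunk)) {
        attempts <- attempts + 1L
        cand <- if (op == "mutation") {
          if (length(pool) == 0L) break
          parent <- pool[[sample.int(length(pool), 1L)]]
          r <- .mutateRaw(parent, library, comp)
          if (!is.null(r)) {
            list(smiles = r$smiles, reactionName = r$reactionName,
                 parents = parent@id)
          } else NULL
        } else {
          if (length(pool) < 2L) break
          ij <- sample.int(length(pool), 2L)
          a <- pool[[ij[1]]]; b <- pool[[ij[2]]]
          core <- .coreCached(coreCache, a@smiles, b@smiles,
                              minCoreAtoms = cfg$minCoreAtoms,
                              timeout = cfg$crossoverTimeout)
          if (is.null(core)) next
          r <- .crossoverRaw(a, b, core)
          if (!is.null(r)) {
            list(smiles = r, reactionName = NA_character_,
                 parents = c(a@id, b@id))
          } else NULL
        }
        if (!is.null(cand)) raws[[length(raws) + 1L]] <- cand
      }
      if (length(raws) == 0L) next
      can <- .canonicalizeMany(vapply(raws, function(x) x$smiles, ""))
      keepIdx <- which(!is.na(can))
      if (length(keepIdx) == 0L) next
      recs <- list()
      for (k in keepIdx) {
        nCreated <- nCreated + 1L
        if (can[k] %in% seen) { nDuplicates <- nDuplicates + 1L; next }
        if (any(vapply(recs, function(r) r@smiles == can[k], TRUE))) {
          nDuplicates <- nDuplicates + 1L; next
        }
        info <- raws[[k]]
        id <- if (op == "mutation") {
          counterM <- counterM + 1L; sprintf("g%d_M%d", gen, counterM)
        } else {
          counterX <- counterX + 1L; sprintf("g%d_X%d", gen, counterX)
        }
        recs[[length(recs) + 1L]] <- moleculeRecord(
          can[k], id = id, generation = gen, origin = op,
          parentIds = info$parents, reactionName = info$reactionName,
          canonicalize = FALSE)
      }
      if (length(recs) == 0L) next
      flt <- applyFilterChain(recs, cfg$filterChain)
      for (nm in names(flt$rejections)) {
        rejections[[nm]] <- rejections[[nm]] + flt$rejections[[nm]]
      }
      for (r in flt$survivors) {
        if (length(out) >= need) {
          # surplus survivor from the last chunk: roll its creation back
          # so the generation bookkeeping stays exact
          nCreated <- nCreated - 1L
          next
        }
        seen <- c(seen, r@smiles)
        out[[length(out) + 1L]] <- r
      }
    }
    # write loop-carried state back to the enclosing frame
    assign("nCreated", nCreated, envir = parent.frame())
    assign("nDuplicates", nDuplicates, envir = parent.frame())
    assign("rejections", rejections, envir = parent.frame())
    assign("seen", seen, envir = parent.frame())
    assign("counterM", counterM, envir = parent.frame())
    assign("counterX", counterX, envir = parent.frame())
    if (length(out) < need) {
      stop(sprintf(paste0("refill exhausted in generation %d: the %s ",
                          "operator produced %d of %d required molecules ",
                          "(filter chain: %s)"),
                   gen, op, length(out), need,
                   if (length(cfg$filterChain) > 0L)
                     paste(cfg$filterChain, collapse = " > ") else "none"),
           call. = FALSE)
    }
    out
  }
  if (sizes$nMutation > 0L) {
    newRecords <- c(newRecords, makeBatch("mutation", sizes$nMutation))
  }
  if (sizes$nCrossover > 0L) {
    newRecords <- c(newRecords, makeBatch("crossover", sizes$nCrossover))
  }
  # --- variant contract + scoring -----------------------------------------
  toScore <- if (cfg$rescoreElites) seq_along(newRecords)
  else which(vapply(newRecords, function(r) {
    v <- .getScore(r, "primary")
    is.na(v) || !is.finite(v)
  }, TRUE))
  nFailed <- 0L
  if (length(toScore) > 0L) {
    vals <- if (is.null(cfg$variantEnumerator)) {
      # no variant enumeration: score the whole batch in one scorer call
      v <- scorer(vapply(newRecords[toScore], function(r) r@smiles, ""))
      ifelse(is.finite(v), v, Inf)
    } else {
      vapply(newRecords[toScore], function(r)
        .scoreCompound(r@smiles, scorer, cfg), 0)
    }
    for (j in seq_along(toScore)) {
      i <- toScore[j]
      if (!is.finite(vals[j])) nFailed <- nFailed + 1L
      sc <- newRecords[[i]]@scores
      sc[["primary"]] <- vals[j]
      newRecords[[i]]@scores <- sc
    }
  }
  # drop scoring failures from the generation (they are counted)
  ok <- vapply(newRecords, function(r) is.finite(.getScore(r, "primary")),
               TRUE)
  newRecords <- newRecords[ok]
  # diversity over the population, ligand efficiency per record
  fps <- lapply(newRecords, function(r) morganFingerprint(r@smiles))
  dvs <- diversityScores(fps)
  for (i in seq_along(newRecords)) {
    sc <- newRecords[[i]]@scores
    sc[["diversity"]] <- dvs[i]
    if (cfg$addLigandEfficiency) {
      sc[["ligand_efficiency"]] <- ligandEfficiency(
        sc[["primary"]], .nAtoms(.parseSmiles(newRecords[[i]]@smiles)))
    }
    newRecords[[i]]@scores <- sc
  }
  # rank by primary score
  newRecords <- newRecords[.rankOrder(newRecords, "primary", "min")]
  primaries <- vapply(newRecords, function(r) .getScore(r, "primary"), 0)
  nFiltered <- sum(rejections)
  summary <- data.frame(
    generation = gen,
    n_population = length(newRecords),
    n_created = nCreated,
    n_elitism = length(elites),
    n_mutation = sizes$nMutation,
    n_crossover = sizes$nCrossover,
    n_filtered = nFiltered,
    n_duplicates = nDuplicates,
    n_score_failures = nFailed,
    best = min(primaries),
    mean = mean(primaries),
    top10_mean = mean(utils::head(primaries, 10L)),
    stringsAsFactors = FALSE)
  state$records <- newRecords
  state$ledger <- c(state$ledger, newRecords)
  state$generation <- gen
  list(state = state, summary = summary)
}

#' Run the evolutionary design loop
#'
#' Reads and canonicalizes the seed population, deduplicates it, applies
#' the filter chain (generation 0), scores it, and then advances the
#' configured number of generations. With at least one elite per
#' generation and \code{rescoreElites = FALSE}, the best primary score
#' never worsens between generations. Two runs with the same
#' configuration and seed produce byte-identical ledgers under the
#' surrogate scorer.
#'
#' @param cfg an \code{evoligandConfig} from [runConfig()] or
#'   [readRunConfig()].
#' @return list with \code{records} (final generation, ranked),
#'   \code{ledger} (every record of the run), \code{summaries} (one row
#'   per generation) and \code{config}.
#' @export
runEvolution <- function(cfg) {
  stopifnot(inherits(cfg, "evoligandConfig"))
  set.seed(cfg$rngSeed)
  library <- .resolveReactionSet(cfg$reactionSet)
  comp <- .resolveComplementary(cfg, library)
  scorer <- fitnessFunction(cfg$fitness)
  seeds <- readSmi(cfg$seedSmiPath, onBadLine = "skip")
  if (length(seeds) == 0L) stop("no usable seed molecules", call. = FALSE)
  # canonical dedup, first occurrence wins
  smi <- vapply(seeds, function(r) r@smiles, "")
  seeds <- seeds[!duplicated(smi)]
  flt <- applyFilterChain(seeds, cfg$filterChain)
  seeds <- flt$survivors
  if (length(seeds) == 0L) {
    stop("every seed molecule was rejected by the filter chain",
         call. = FALSE)
  }
  # generation 0 scoring (variant contract applies to seeds as well)
  g0vals <- if (is.null(cfg$variantEnumerator)) {
    v <- scorer(vapply(seeds, function(r) r@smiles, ""))
    ifelse(is.finite(v), v, Inf)
  } else {
    vapply(seeds, function(r) .scoreCompound(r@smiles, scorer, cfg), 0)
  }
  for (i in seq_along(seeds)) {
    sc <- seeds[[i]]@scores
    sc[["primary"]] <- g0vals[i]
    seeds[[i]]@scores <- sc
  }
  seeds <- seeds[vapply(seeds, function(r)
    is.finite(.getScore(r, "primary")), TRUE)]
  fps <- lapply(seeds, function(r) morganFingerprint(r@smiles))
  dvs <- diversityScores(fps)
  for (i in seq_along(seeds)) {
    sc <- seeds[[i]]@scores
    sc[["diversity"]] <- dvs[i]
    if (cfg$addLigandEfficiency) {
      sc[["ligand_efficiency"]] <- ligandEfficiency(
        sc[["primary"]], .nAtoms(.parseSmiles(seeds[[i]]@smiles)))
    }
    seeds[[i]]@scores <- sc
  }
  seeds <- seeds[.rankOrder(seeds, "primary", "min")]
  state <- list(records = seeds, ledger = seeds, generation = 0L)
  summaries <- data.frame()
  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    g0dir <- file.path(cfg$outputDir, "generation_0")
    dir.create(g0dir, showWarnings = FALSE)
    writeSmi(seeds, file.path(g0dir, "ranked.smi"),
             scoreColumns = c("primary", "diversity"))
  }
  for (g in seq_len(cfg$generations)) {
    step <- advanceGeneration(state, cfg, library, comp, scorer)
    state <- step$state
    summaries <- rbind(summaries, step$summary)
    message(sprintf(
      "generation %d: %d molecules, best %.3f, mean %.3f",
      g, step$summary$n_population, step$summary$best, step$summary$mean))
    if (!is.null(cfg$outputDir)) {
      gdir <- file.path(cfg$outputDir, paste0("generation_", g))
      dir.create(gdir, showWarnings = FALSE)
      cols <- c("primary", "diversity",
                if (cfg$addLigandEfficiency) "ligand_efficiency")
      writeSmi(state$records, file.path(gdir, "ranked.smi"),
               scoreColumns = cols)
    }
  }
  if (!is.null(cfg$outputDir)) {
    writeLedger(state$ledger, file.path(cfg$outputDir, "ledger.tsv"))
    utils::write.table(summaries,
                       file.path(cfg$outputDir, "summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = state$records, ledger = state$ledger,
       summaries = summaries, config = cfg)
}

#' Per-event molecular-weight drift of the operators
#'
#' For every mutation and crossover event in a ledger, computes the change
#' in molecular weight from parent to child (for crossover, relative to
#' the mean parent weight). Both signs occur in practice: reactions that
#' swap a heavy leaving group for a light one (transesterification of a
#' phenyl ester with methanol, for instance) shrink the child.
#'
#' @param ledger list of \linkS4class{MoleculeRecord} from a run.
#' @return data.frame with columns id, operator, parent_mw, child_mw,
#'   delta_mw, pct.
#' @export
operatorMwDrift <- function(ledger) {
  idx <- stats::setNames(seq_along(ledger),
                         vapply(ledger, function(r) r@id, ""))
  mw <- function(s) .molWeight(.parseSmiles(s))
  rows <- list()
  for (r in ledger) {
    if (!(r@origin %in% c("mutation", "crossover"))) next
    pmw <- mean(vapply(r@parentIds, function(p) {
      mw(ledger[[idx[[p]]]]@smiles)
    }, 0))
    cmw <- mw(r@smiles)
    rows[[length(rows) + 1L]] <- data.frame(
      id = r@id, operator = r@origin, parent_mw = pmw, child_mw = cmw,
      delta_mw = cmw - pmw, pct = 100 * (cmw - pmw) / pmw,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(), operator = character(),
                      parent_mw = numeric(), child_mw = numeric(),
                      delta_mw = numeric(), pct = numeric()))
  }
  do.call(rbind, rows)
}
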