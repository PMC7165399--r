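# The mutation operator: apply an in silico reaction to a parent molecule
# (plus, for bimolecular reactions, a complementary reactant).

# package-level cache of parsed SMARTS / SMIRKS
.pkgCache <- new.env(parent = emptyenv())

.cachedSmarts <- function(pattern) {
  key <- paste0("smarts:", pattern)
  if (!exists(key, envir = .pkgCache, inherits = FALSE)) {
    assign(key, .parseSmarts(pattern), envir = .pkgCache)
  }
  get(key, envir = .pkgCache)
}

.cachedSmirks <- function(smirks) {
  key <- paste0("smirks:", smirks)
  if (!exists(key, envir = .pkgCache, inherits = FALSE)) {
    assign(key, .parseSmirks(smirks), envir = .pkgCache)
  }
  get(key, envir = .pkgCache)
}

# mild neutralization before reaction matching: protonated amines lose a
# proton, deprotonated O/S acids gain one; quaternary and exotic charges
# are left alone
.neutralizeMol <- function(mol) {
  for (i in seq_along(mol$elem)) {
    if (mol$charge[i] > 0L && mol$elem[i] %in% c("N", "P") &&
        mol$hcount[i] > 0L) {
      mol$charge[i] <- 0L
      mol$hcount[i] <- mol$hcount[i] - 1L
    } else if (mol$charge[i] < 0L && mol$elem[i] %in% c("O", "S")) {
      mol$charge[i] <- 0L
      mol$hcount[i] <- mol$hcount[i] + 1L
    }
  }
  mol
}

.neutralSmiles <- function(smiles) {
  mol <- .parseSmiles(smiles)
  # skip molecules that take part in charge-separated groups (azides,
  # nitro): only neutralize when the net charge is nonzero
  if (sum(mol$charge) == 0L) return(canonicalizeSmiles(smiles))
  canonicalizeSmiles(.writeSmiles(.neutralizeMol(mol)))
}

#' Reactions whose slot queries match a molecule
#'
#' Scans a reaction library and returns every (reaction, slot) pair whose
#' per-slot substructure query matches the molecule: the functional-group
#' test that decides which in silico reactions a parent can undergo.
#'
#' @param smiles a single canonical SMILES string.
#' @param library a \linkS4class{ReactionLibrary}.
#' @return list of \code{list(reaction = ReactionSpec, slot = integer)};
#'   empty when no functional group matches.
#' @examples
#' lib <- bundledReactionLibrary("AutoClickChemRxn")
#' length(matchingReactions("CC(=O)O", lib)) > 0  # carboxylic acid reacts
#' @export
matchingReactions <- function(smiles, library) {
  hits <- .slotQueryHits(smiles, library)
  out <- list()
  k <- 0L
  for (r in reactions(library)) {
    for (s in seq_len(r@numReactants)) {
      k <- k + 1L
      if (hits[k]) out[[length(out) + 1L]] <- list(reaction = r, slot = s)
    }
  }
  out
}

# Boolean slot-query screening for one molecule over a whole library,
# through Open Babel's compiled matcher; queries it cannot parse fall
# back to the package matcher.
.slotQueryHits <- function(smiles, library) {
  queries <- unlist(lapply(reactions(library),
                           function(r) r@slotQueries))
  clean <- gsub("[/\\\\@]", "", smiles)
  res <- ChemmineOB::forEachMol("SMILES", paste(clean, "m"), function(m) {
    vapply(queries, function(q) {
      cnt <- tryCatch(
        suppressWarnings(ChemmineOB::smartsSearch_OB(list(m), q)),
        error = function(e) NA_integer_)
      if (is.na(cnt)) NA else cnt > 0L
    }, NA)
  })[[1]]
  if (anyNA(res)) {
    ctx <- .molContext(.parseSmiles(smiles))
    for (k in which(is.na(res))) {
      res[k] <- length(.matchSmarts(.cachedSmarts(queries[k]), ctx,
                                    maxMatches = 1L)) > 0L
    }
  }
  unname(res)
}

#' Build a complementary reactant library
#'
#' Filters candidate molecules the way the default complementary libraries
#' are curated -- molecular weight below \code{mwCap} (250 Da by default),
#' logP below \code{logpCap}, the strict Lipinski* rule with no violations
#' -- discards candidates that match no reaction slot, groups the rest by
#' (reaction, slot), and keeps at most \code{perGroupCap} molecules per
#' group, preferring the lowest molecular weight (ties broken
#' lexicographically by canonical SMILES).
#'
#' @param candidates character vector of canonical SMILES.
#' @param library a \linkS4class{ReactionLibrary}.
#' @param mwCap maximum molecular weight (Da), exclusive.
#' @param logpCap maximum logP, exclusive.
#' @param perGroupCap maximum molecules kept per slot group.
#' @return a \linkS4class{ComplementaryLibrary}.
#' @export
buildComplementaryLibrary <- function(candidates, library, mwCap = 250,
                                      logpCap = 5, perGroupCap = 5000) {
  stopifnot(mwCap > 0, perGroupCap > 0)
  memoKey <- paste0("complib:", library@setName, ":", length(library), ":",
                    mwCap, ":", logpCap, ":", perGroupCap, ":",
                    paste(candidates, collapse = "."))
  if (exists(memoKey, envir = .pkgCache, inherits = FALSE)) {
    return(get(memoKey, envir = .pkgCache))
  }
  if (length(candidates) == 0L) {
    warning("empty candidate list; returning an empty complementary library")
    return(new("ComplementaryLibrary", groups = list()))
  }
  desc <- computeDescriptors(candidates)
  lip <- vapply(seq_len(nrow(desc)), function(i) {
    evaluatePropertyFilter(desc[i, ], propertyFilterSpec("Lipinski*"))$pass
  }, TRUE)
  ok <- desc$mw < mwCap & desc$logp < logpCap & lip
  kept <- candidates[ok]
  keptMw <- desc$mw[ok]
  groups <- list()
  if (length(kept) > 0L) {
    hitTab <- vapply(kept, function(s) .slotQueryHits(s, library),
                     logical(sum(vapply(reactions(library),
                                        function(r) r@numReactants, 0L))))
    k <- 0L
    for (r in reactions(library)) {
      for (s in seq_len(r@numReactants)) {
        k <- k + 1L
        hit <- hitTab[k, ]
        if (any(hit)) {
          smi <- kept[hit]; mws <- keptMw[hit]
          ord <- order(mws, smi)
          groups[[paste0(r@name, "#", s)]] <-
            smi[ord][seq_len(min(perGroupCap, length(smi)))]
        }
      }
    }
  }
  out <- new("ComplementaryLibrary", groups = groups)
  assign(memoKey, out, envir = .pkgCache)
  out
}

# enumerate up to maxProducts distinct products of one reaction applied to
# concrete reactant SMILES (used by provenance checks and self-tests)
.enumerateProducts <- function(spec, reactantSmiles, maxProducts = 32L) {
  rx <- .cachedSmirks(spec@smirks)
  if (length(reactantSmiles) != length(rx$reactants)) {
    stop("reaction '", spec@name, "' needs ", length(rx$reactants),
         " reactant(s)", call. = FALSE)
  }
  mols <- lapply(reactantSmiles,
                 function(s) .parseSmiles(.neutralSmiles(s)))
  ctxs <- lapply(mols, .molContext)
  embs <- lapply(seq_along(mols), function(s) {
    .matchSmarts(rx$reactants[[s]], ctxs[[s]], maxMatches = 16L)
  })
  if (any(vapply(embs, length, 0L) == 0L)) return(character())
  out <- character()
  grid <- expand.grid(lapply(embs, seq_along))
  for (g in seq_len(nrow(grid))) {
    emb <- lapply(seq_along(embs), function(s) embs[[s]][[grid[g, s]]])
    prod <- .applySmirks(rx, mols, emb)
    if (is.null(prod) || .nAtoms(prod) == 0L) next
    smi <- tryCatch(canonicalizeSmiles(.writeSmiles(.largestFragment(prod))),
                    error = function(e) NULL)
    if (!is.null(smi)) out <- c(out, smi)
    if (length(unique(out)) >= maxProducts) break
  }
  unique(out)
}

#' Apply one reaction to concrete reactants
#'
#' Enumerates the distinct products of a reaction over all template match
#' sites (multi-site reactants can give several products).
#'
#' @param spec a \linkS4class{ReactionSpec} (or a reaction name resolved in
#'   \code{library}).
#' @param reactantSmiles character vector of reactant SMILES, one per slot.
#' @param library optional \linkS4class{ReactionLibrary} for name lookup.
#' @return character vector of canonical product SMILES (possibly empty).
#' @examples
#' lib <- bundledReactionLibrary("RobustRxn")
#' applyReaction("transesterification",
#'               c("O=C(Oc1ccccc1)c1ccccc1", "CO"), lib)
#' @export
applyReaction <- function(spec, reactantSmiles, library = NULL) {
  if (is.character(spec)) {
    if (is.null(library)) stop("need a library to resolve a reaction name")
    hit <- Filter(function(r) r@name == spec, reactions(library))
    if (length(hit) == 0L) stop("unknown reaction: ", spec, call. = FALSE)
    spec <- hit[[1]]
  }
  .enumerateProducts(spec, reactantSmiles)
}

# One raw mutation attempt for the engine's batch pipeline: samples a
# reaction, complementary reactant and match site exactly as
# mutateMolecule does, but skips sanitization (the engine canonicalizes
# candidates in batches). Returns list(smiles, reactionName) or NULL.
.mutateRaw <- function(parent, library, comp) {
  memoKey <- paste0("mutctx:", library@setName, ":", length(library), ":",
                    parent@smiles)
  if (exists(memoKey, envir = .pkgCache, inherits = FALSE)) {
    memo <- get(memoKey, envir = .pkgCache)
  } else {
    parentSmiles <- .neutralSmiles(parent@smiles)
    memo <- list(smiles = parentSmiles,
                 cands = matchingReactions(parentSmiles, library),
                 mol = .parseSmiles(parentSmiles))
    assign(memoKey, memo, envir = .pkgCache)
  }
  if (length(memo$cands) == 0L) return(NULL)
  pickIdx <- if (length(memo$cands) == 1L) 1L
  else sample.int(length(memo$cands), 1L)
  cand <- memo$cands[[pickIdx]]
  r <- cand$reaction; slot <- cand$slot
  rxp <- .cachedSmirks(r@smirks)
  compSmiles <- NA_character_
  if (r@numReactants == 2L) {
    other <- if (slot == 1L) 2L else 1L
    pool <- comp@groups[[paste0(r@name, "#", other)]]
    if (is.null(pool) || length(pool) == 0L) return(NULL)
    compSmiles <- pool[if (length(pool) == 1L) 1L
                       else sample.int(length(pool), 1L)]
    mols <- vector("list", 2L)
    mols[[slot]] <- memo$mol
    mols[[other]] <- .parseSmiles(compSmiles)
  } else {
    mols <- list(memo$mol)
  }
  raw <- tryCatch(
    .runReaction(rxp, mols, sanitize = FALSE, pick = function(sizes) {
      lapply(sizes, function(n) if (n == 1L) 1L else sample.int(n, 1L))
    }),
    error = function(e) NULL)
  if (is.null(raw)) return(NULL)
  rn <- if (is.na(compSmiles)) r@name else paste0(r@name, ":", compSmiles)
  list(smiles = raw, reactionName = rn)
}

#' Mutate a parent molecule through an in silico reaction
#'
#' The mutation operator: (1) list the (reaction, slot) pairs whose
#' functional-group query matches the parent; (2) sample one uniformly;
#' (3) for bimolecular reactions, sample a complementary reactant
#' uniformly from the other slot's group; (4) apply the SMIRKS, sampling
#' one match site uniformly when several exist; (5) keep the largest
#' product fragment, sanitize and canonicalize; (6) on failure retry from
#' (2) up to \code{maxAttempts} times.
#'
#' Uses R's RNG: identical inputs under the same seed give the same child.
#'
#' @param parent a \linkS4class{MoleculeRecord}.
#' @param library a \linkS4class{ReactionLibrary}.
#' @param comp a \linkS4class{ComplementaryLibrary}.
#' @param id id for the child record.
#' @param generation generation index for the child record.
#' @param maxAttempts maximum sampling attempts.
#' @return a \linkS4class{MoleculeRecord} with \code{origin="mutation"}, or
#'   \code{NULL} when no reaction applies (the engine then refills from
#'   other parents). The reaction name and, for bimolecular reactions, the
#'   complementary reactant are recorded in the child's
#'   \code{reactionName} as \code{"<name>:<smiles>"}.
#' @export
mutateMolecule <- function(parent, library, comp, id = "mutant",
                           generation = parent@generation + 1L,
                           maxAttempts = 10L) {
  stopifnot(is(parent, "MoleculeRecord"), is(library, "ReactionLibrary"))
  # memoize per (library, parent): parents recur many times per generation
  memoKey <- paste0("mutctx:", library@setName, ":", length(library), ":",
                    parent@smiles)
  if (exists(memoKey, envir = .pkgCache, inherits = FALSE)) {
    memo <- get(memoKey, envir = .pkgCache)
  } else {
    parentSmiles <- .neutralSmiles(parent@smiles)
    memo <- list(smiles = parentSmiles,
                 cands = matchingReactions(parentSmiles, library),
                 mol = .parseSmiles(parentSmiles))
    assign(memoKey, memo, envir = .pkgCache)
  }
  cands <- memo$cands
  if (length(cands) == 0L) return(NULL)
  parentMol <- memo$mol
  for (attempt in seq_len(maxAttempts)) {
    pickIdx <- if (length(cands) == 1L) 1L else sample.int(length(cands), 1L)
    cand <- cands[[pickIdx]]
    r <- cand$reaction; slot <- cand$slot
    rxp <- .cachedSmirks(r@smirks)
    compSmiles <- NA_character_
    if (r@numReactants == 2L) {
      other <- if (slot == 1L) 2L else 1L
      pool <- comp@groups[[paste0(r@name, "#", other)]]
      if (is.null(pool) || length(pool) == 0L) next
      compSmiles <- pool[if (length(pool) == 1L) 1L
                         else sample.int(length(pool), 1L)]
      mols <- vector("list", 2L)
      mols[[slot]] <- parentMol
      mols[[other]] <- .parseSmiles(compSmiles)
    } else {
      mols <- list(parentMol)
    }
    smi <- tryCatch(
      .runReaction(rxp, mols, pick = function(sizes) {
        lapply(sizes, function(n) if (n == 1L) 1L else sample.int(n, 1L))
      }),
      error = function(e) NULL)
    if (!is.null(smi) && .fullValenceOK(.parseSmiles(smi))) {
      rn <- if (is.na(compSmiles)) r@name
      else paste0(r@name, ":", compSmiles)
      return(moleculeRecord(smi, id = id, generation = generation,
                            origin = "mutation", parentIds = parent@id,
                            reactionName = rn, canonicalize = FALSE))
    }
  }
  NULL
}
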