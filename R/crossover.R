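# The crossover operator: merge two parents over their largest common
# substructure, recombining the decorating moieties at random.

#' CorePattern: the shared substructure of two parents
#'
#' The maximum common connected substructure found under element, aromatic
#' and bond-order matching, stored as a small molecular graph together with
#' its embedding in both parents (position i of both maps is the same core
#' atom).
#'
#' @slot coreGraph internal molecular graph of the core.
#' @slot heavyAtomCount number of heavy atoms in the core.
#' @slot mapA,mapB integer atom indices of the core in each parent.
#' @slot smilesA,smilesB the parent SMILES the maps refer to.
#' @exportClass CorePattern
setClass("CorePattern",
         representation(coreGraph = "ANY", heavyAtomCount = "integer",
                        mapA = "integer", mapB = "integer",
                        smilesA = "character", smilesB = "character"))

setMethod("show", "CorePattern", function(object) {
  cat(sprintf("CorePattern: %d heavy atoms (%s)\n", object@heavyAtomCount,
              .writeSmiles(object@coreGraph)))
})

# exact-graph pattern from a molgraph: element + aromatic + charge atoms,
# order + aromatic bonds; reuses the SMARTS matching machinery
.graphAsPattern <- function(mol) {
  atoms <- lapply(seq_along(mol$elem), function(i) {
    list(op = "and", xs = list(
      list(t = "prim", kind = "elem", elem = mol$elem[i],
           arom = mol$arom[i]),
      list(t = "prim", kind = "charge", val = mol$charge[i])))
  })
  bexpr <- lapply(seq_len(nrow(mol$bond)), function(k) {
    if (mol$baro[k]) list(t = "prim", kind = "aromatic")
    else list(t = "prim",
              kind = c("single", "double", "triple")[mol$bond[k, "order"]])
  })
  structure(list(atoms = atoms, amap = rep(0L, length(atoms)),
                 bracket = rep(TRUE, length(atoms)),
                 bond = mol$bond[, c("a", "b"), drop = FALSE],
                 bexpr = bexpr, pattern = "<graph>"),
            class = "smartsPattern")
}

# Maximum common connected subgraph by branch-and-bound extension
# (McGregor-style): grow a mapped connected core one frontier atom at a
# time, branching over compatible images and over permanently excluding
# the frontier atom; prune when the mapped size plus the remaining
# potential cannot beat the incumbent. The search budget is a fixed
# number of node expansions (deterministic across runs and machines,
# roughly proportional to wall time); when it runs out the best core
# found so far is returned (anytime search), which keeps the crossover
# operator productive on larger molecules.
.mcsSearch <- function(molA, molB, ringMatchesRingOnly = TRUE,
                       timeout = 1) {
  ctxA <- .molContext(molA); ctxB <- .molContext(molB)
  nA <- .nAtoms(molA); nB <- .nAtoms(molB)
  atomOK <- function(i, j) {
    molA$elem[i] == molB$elem[j] && molA$arom[i] == molB$arom[j] &&
      molA$charge[i] == molB$charge[j] &&
      (!ringMatchesRingOnly || ctxA$ringAtom[i] == ctxB$ringAtom[j])
  }
  bondCode <- function(mol, ctx) {
    n <- .nAtoms(mol)
    m <- matrix(0L, n, n)
    if (nrow(mol$bond) > 0L) for (k in seq_len(nrow(mol$bond))) {
      code <- 1L + mol$bond[k, "order"] + 10L * as.integer(mol$baro[k]) +
        (if (ringMatchesRingOnly) 100L * as.integer(ctx$ringBond[k]) else 0L)
      a <- mol$bond[k, "a"]; b <- mol$bond[k, "b"]
      m[a, b] <- code; m[b, a] <- code
    }
    m
  }
  cA <- bondCode(molA, ctxA); cB <- bondCode(molB, ctxB)
  compat <- outer(seq_len(nA), seq_len(nB), Vectorize(atomOK))
  if (!any(compat)) return(list(a = integer(), b = integer()))
  # budget in C++ node expansions (deterministic, ~proportional to time)
  res <- .mcsSearchCpp(cA, cB, compat, ceiling(timeout * 3e6), 64L)
  if (res$budgetExhausted && length(res$a) == 0L) return(NULL)
  list(a = res$a, b = res$b)
}

#' Largest common substructure of two molecules
#'
#' Finds a maximum common connected substructure under element, aromatic
#' flag and bond-order matching. With \code{ringMatchesRingOnly} (default),
#' ring atoms and bonds only match ring atoms and bonds, which keeps cores
#' chemically meaningful. The branch-and-bound search is exact within a
#' deterministic node budget scaled by \code{timeout}; if the budget runs
#' out, the best core found so far is returned (anytime behaviour), or no
#' core when none was found at all.
#'
#' @param a,b SMILES of the two molecules.
#' @param minCoreAtoms smallest acceptable core (heavy atoms).
#' @param timeout search budget, scaled in seconds.
#' @param ringMatchesRingOnly restrict ring/chain matching.
#' @return a \linkS4class{CorePattern}, or \code{NULL} when the best core
#'   is smaller than \code{minCoreAtoms} or the exhausted search found
#'   none.
#' @examples
#' core <- largestCommonSubstructure("Cc1ccccc1", "Clc1ccccc1")
#' core@heavyAtomCount  # the shared benzene ring, 6 atoms
#' @export
largestCommonSubstructure <- function(a, b, minCoreAtoms = 4L, timeout = 1,
                                      ringMatchesRingOnly = TRUE) {
  a <- canonicalizeSmiles(a); b <- canonicalizeSmiles(b)
  molA <- .parseSmiles(a); molB <- .parseSmiles(b)
  res <- .mcsSearch(molA, molB, ringMatchesRingOnly, timeout)
  if (is.null(res)) {
    message("common-substructure search timed out; no core")
    return(NULL)
  }
  mapA <- res$a; mapB <- res$b
  if (length(mapA) < minCoreAtoms) return(NULL)
  core <- .subMol(molA, mapA)
  ordA <- sort(mapA)
  new("CorePattern", coreGraph = core,
      heavyAtomCount = length(mapA),
      mapA = ordA, mapB = mapB[order(mapA)],
      smilesA = a, smilesB = b)
}

#' Decompose a molecule around a core into decorating moieties
#'
#' Cuts every bond between a core atom and a non-core atom. Each resulting
#' non-core fragment becomes one moiety with a single attachment point
#' (recorded as the core position it hangs from). Reattaching every moiety
#' reconstructs the molecule exactly.
#'
#' @param smiles molecule SMILES (one of the two the core was built from).
#' @param core a \linkS4class{CorePattern}.
#' @param side \code{"A"} or \code{"B"}: which stored embedding to use.
#' @return list with \code{core} (the \linkS4class{CorePattern}),
#'   \code{moieties}: list of \code{list(position, frag, attachAtom,
#'   order, baro)}, or an error when a fragment touches the core through
#'   more than one bond.
#' @export
decomposeOnCore <- function(smiles, core, side = c("A", "B")) {
  side <- match.arg(side)
  smiles <- canonicalizeSmiles(smiles)
  want <- if (side == "A") core@smilesA else core@smilesB
  if (smiles != want) {
    stop("molecule does not match the stored side-", side, " parent",
         call. = FALSE)
  }
  mol <- .parseSmiles(smiles)
  mapv <- if (side == "A") core@mapA else core@mapB
  coreSet <- mapv
  pos <- match(seq_len(.nAtoms(mol)), mapv)  # mol atom -> core position
  # cut bonds core <-> non-core
  cut <- list()
  keepB <- rep(TRUE, nrow(mol$bond))
  for (k in seq_len(nrow(mol$bond))) {
    ia <- mol$bond[k, "a"]; ib <- mol$bond[k, "b"]
    inA <- ia %in% coreSet; inB <- ib %in% coreSet
    if (xor(inA, inB)) {
      keepB[k] <- FALSE
      cut[[length(cut) + 1L]] <- list(
        corePos = pos[if (inA) ia else ib],
        outAtom = if (inA) ib else ia,
        order = mol$bond[k, "order"], baro = mol$baro[k])
    }
  }
  # fragments of the molecule with the cut bonds removed, minus the core
  cutMol <- mol
  cutMol$bond <- mol$bond[keepB, , drop = FALSE]
  cutMol$baro <- mol$baro[keepB]
  frags <- .fragments(cutMol)
  moieties <- list()
  for (fr in frags) {
    if (any(fr %in% coreSet)) next
    touches <- Filter(function(ct) ct$outAtom %in% fr, cut)
    if (length(touches) == 0L) next
    if (length(touches) > 1L) {
      stop("decomposition error: a fragment touches the core through ",
           length(touches), " bonds", call. = FALSE)
    }
    ct <- touches[[1]]
    frAtoms <- sort(fr)
    moieties[[length(moieties) + 1L]] <- list(
      position = ct$corePos,
      frag = .subMol(mol, frAtoms),
      attachAtom = match(ct$outAtom, frAtoms),
      order = ct$order, baro = ct$baro)
  }
  list(core = core, side = side, moieties = moieties)
}

# reassemble core + chosen moieties into a molgraph
.reassemble <- function(core, moieties) {
  out <- core@coreGraph
  # core hydrogens are recomputed unless bracket-fixed in the parents
  for (m in moieties) {
    off <- .nAtoms(out)
    u <- .unionMol(out, m$frag)
    out <- u$mol
    out$bond <- rbind(out$bond,
                      matrix(c(m$position, m$attachAtom + off, m$order),
                             ncol = 3,
                             dimnames = list(NULL, c("a", "b", "order"))))
    out$baro <- c(out$baro, m$baro)
  }
  bs <- .bondOrderSum(out)
  for (i in seq_len(.nAtoms(out))) {
    if (!out$hfixed[i]) {
      out$hcount[i] <- .defaultHcount(out$elem[i], out$arom[i], bs[i])
    }
  }
  out
}

#' Cross two parent molecules over their largest common substructure
#'
#' Finds the core shared by the two parents, strips each parent down to
#' core plus decorating moieties, and assembles a child by choosing, at
#' every decorated core position, the moiety set of one parent or the
#' other with equal probability (positions decorated in only one parent
#' choose between that moiety set and nothing). Invalid assemblies
#' (valence overflow at an attachment point) are re-sampled up to
#' \code{maxAttempts} times. The child always contains the core.
#'
#' @param a,b parent \linkS4class{MoleculeRecord}s.
#' @param id child record id.
#' @param generation child generation index.
#' @param minCoreAtoms,timeout,ringMatchesRingOnly core-search parameters,
#'   see [largestCommonSubstructure()].
#' @param maxAttempts assembly retry budget.
#' @param core optional precomputed \linkS4class{CorePattern} for the pair.
#' @return a \linkS4class{MoleculeRecord} with \code{origin="crossover"},
#'   or \code{NULL} when no qualifying core exists or all assemblies were
#'   invalid.
#' @export
crossoverMolecules <- function(a, b, id = "child",
                               generation = max(a@generation,
                                                b@generation) + 1L,
                               minCoreAtoms = 4L, timeout = 1,
                               ringMatchesRingOnly = TRUE,
                               maxAttempts = 10L, core = NULL) {
  stopifnot(is(a, "MoleculeRecord"), is(b, "MoleculeRecord"))
  if (is.null(core)) {
    core <- largestCommonSubstructure(a@smiles, b@smiles,
                                      minCoreAtoms = minCoreAtoms,
                                      timeout = timeout,
                                      ringMatchesRingOnly =
                                        ringMatchesRingOnly)
  }
  if (is.null(core)) return(NULL)
  # a precomputed core may store the pair in either orientation
  sideA <- if (identical(core@smilesA, a@smiles)) "A"
  else if (identical(core@smilesB, a@smiles)) "B"
  else return(NULL)
  sideB <- if (sideA == "A") "B" else "A"
  decA <- tryCatch(decomposeOnCore(a@smiles, core, sideA),
                   error = function(e) NULL)
  decB <- tryCatch(decomposeOnCore(b@smiles, core, sideB),
                   error = function(e) NULL)
  if (is.null(decA) || is.null(decB)) return(NULL)
  posA <- vapply(decA$moieties, function(m) m$position, 0L)
  posB <- vapply(decB$moieties, function(m) m$position, 0L)
  allPos <- sort(unique(c(posA, posB)))
  for (attempt in seq_len(maxAttempts)) {
    chosen <- list()
    for (p in allPos) {
      fromA <- decA$moieties[posA == p]
      fromB <- decB$moieties[posB == p]
      pickA <- stats::runif(1) < 0.5
      set <- if (length(fromA) > 0L && length(fromB) > 0L) {
        if (pickA) fromA else fromB
      } else if (length(fromA) > 0L) {
        if (pickA) fromA else list()
      } else {
        if (pickA) fromB else list()
      }
      chosen <- c(chosen, set)
    }
    child <- .reassemble(core, chosen)
    smi <- tryCatch(canonicalizeSmiles(.writeSmiles(child)),
                    error = function(e) NULL)
    if (!is.null(smi) && .fullValenceOK(.parseSmiles(smi))) {
      return(moleculeRecord(smi, id = id, generation = generation,
                            origin = "crossover",
                            parentIds = c(a@id, b@id),
                            canonicalize = FALSE))
    }
  }
  NULL
}

# One raw crossover attempt for the engine's batch pipeline: identical
# sampling to crossoverMolecules, without sanitization. Returns the raw
# written SMILES or NULL.
.crossoverRaw <- function(a, b, core) {
  sideA <- if (identical(core@smilesA, a@smiles)) "A"
  else if (identical(core@smilesB, a@smiles)) "B"
  else return(NULL)
  sideB <- if (sideA == "A") "B" else "A"
  coreId <- paste(core@smilesA, core@smilesB,
                  paste(core@mapA, collapse = ","), sep = "|")
  memoDec <- function(smiles, side) {
    key <- paste0("dec:", coreId, "|", side)
    if (!exists(key, envir = .pkgCache, inherits = FALSE)) {
      v <- tryCatch(decomposeOnCore(smiles, core, side),
                    error = function(e) "fail")
      assign(key, v, envir = .pkgCache)
    }
    v <- get(key, envir = .pkgCache)
    if (identical(v, "fail")) NULL else v
  }
  decA <- memoDec(a@smiles, sideA)
  decB <- memoDec(b@smiles, sideB)
  if (is.null(decA) || is.null(decB)) return(NULL)
  posA <- vapply(decA$moieties, function(m) m$position, 0L)
  posB <- vapply(decB$moieties, function(m) m$position, 0L)
  allPos <- sort(unique(c(posA, posB)))
  chosen <- list()
  for (p in allPos) {
    fromA <- decA$moieties[posA == p]
    fromB <- decB$moieties[posB == p]
    pickA <- stats::runif(1) < 0.5
    set <- if (length(fromA) > 0L && length(fromB) > 0L) {
      if (pickA) fromA else fromB
    } else if (length(fromA) > 0L) {
      if (pickA) fromA else list()
    } else {
      if (pickA) fromB else list()
    }
    chosen <- c(chosen, set)
  }
  .writeSmiles(.reassemble(core, chosen))
}

# does the molecule contain the core as a substructure? (validation)
.containsCore <- function(smiles, core) {
  pat <- .graphAsPattern(core@coreGraph)
  ctx <- .molContext(.parseSmiles(canonicalizeSmiles(smiles)))
  length(.matchSmarts(pat, ctx, maxMatches = 1L)) > 0L
}
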