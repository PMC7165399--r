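# SMIRKS reaction engine and reaction-library management.
#
# The library dialect is JSON: a list of objects
#   {name, smirks, num_reactants, slot_queries[], source_set,
#    example_reactants[]}
# SMIRKS are written in the package's documented SMARTS subset with full
# atom mapping on every reactant-template atom; the product template reuses
# those maps, may omit mapped atoms (they are deleted, co-product fragments
# fall away with them) and may introduce unmapped concrete atoms (created).

# split a SMIRKS/SMARTS string on top-level dots
.splitTopLevel <- function(s, sep = ".") {
  depth <- 0L; out <- character(); cur <- ""
  for (ch in strsplit(s, "")[[1]]) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (ch == sep && depth == 0L) { out <- c(out, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

# Concretize a product-template atom expression: a conjunction of element /
# charge / H-count primitives. Returns elem, arom, charge, hcount (NA =
# recompute), or errors for anything non-concrete.
.concretizeAtom <- function(expr, smirks) {
  spec <- list(elem = NA_character_, arom = FALSE, charge = 0L,
               hcount = NA_integer_)
  walk <- function(e) {
    if (!is.null(e$op) && e$op == "and") {
      for (x in e$xs) walk(x)
      return()
    }
    if (!is.null(e$op) && e$op %in% c("or", "not")) {
      stop(sprintf("product template of '%s' is not concrete", smirks),
           call. = FALSE)
    }
    if (e$kind == "elem") {
      spec$elem <<- e$elem
      spec$arom <<- isTRUE(e$arom)
    } else if (e$kind == "anum") {
      nm <- names(.ATOMIC_NUMBER)[match(e$val, .ATOMIC_NUMBER)]
      spec$elem <<- nm
    } else if (e$kind == "charge") {
      spec$charge <<- as.integer(e$val)
    } else if (e$kind == "H") {
      spec$hcount <<- as.integer(e$val)
    } else {
      stop(sprintf("product template of '%s' uses primitive '%s'",
                   smirks, e$kind), call. = FALSE)
    }
  }
  walk(expr)
  spec
}

# parse a SMIRKS into reactant pattern list + product spec
.parseSmirks <- function(smirks) {
  halves <- strsplit(smirks, ">>", fixed = TRUE)[[1]]
  if (length(halves) != 2L) {
    stop("SMIRKS must contain one '>>': ", smirks, call. = FALSE)
  }
  rparts <- .splitTopLevel(trimws(halves[1]))
  if (!(length(rparts) %in% c(1L, 2L))) {
    stop("SMIRKS must have 1 or 2 reactant templates: ", smirks,
         call. = FALSE)
  }
  rpats <- lapply(rparts, .parseSmarts)
  for (p in rpats) {
    if (any(p$amap == 0L)) {
      stop("every reactant-template atom must carry an atom map: ", smirks,
           call. = FALSE)
    }
  }
  allMaps <- unlist(lapply(rpats, function(p) p$amap))
  if (anyDuplicated(allMaps) > 0L) {
    stop("duplicate atom maps across reactant templates: ", smirks,
         call. = FALSE)
  }
  pparts <- .splitTopLevel(trimws(halves[2]))
  if (length(pparts) != 1L) {
    stop("the product side must be a single connected template ",
         "(co-products are implicit): ", smirks, call. = FALSE)
  }
  ppat <- .parseSmarts(pparts[1])
  if (any(!(ppat$amap[ppat$amap > 0L] %in% allMaps))) {
    stop("product template uses unknown atom maps: ", smirks, call. = FALSE)
  }
  pspec <- lapply(seq_along(ppat$atoms), function(i) {
    .concretizeAtom(ppat$atoms[[i]], smirks)
  })
  # concrete product bond orders: default/-/=/#/: only
  bord <- integer(nrow(ppat$bond)); barom <- logical(nrow(ppat$bond))
  if (nrow(ppat$bond) > 0L) for (k in seq_len(nrow(ppat$bond))) {
    e <- ppat$bexpr[[k]]
    if (identical(e$op, "default")) {
      a <- ppat$bond[k, 1]; b <- ppat$bond[k, 2]
      if (pspec[[a]]$arom && pspec[[b]]$arom) { bord[k] <- 1L; barom[k] <- TRUE }
      else bord[k] <- 1L
    } else if (is.null(e$op) && e$kind %in% c("single", "double", "triple",
                                              "aromatic")) {
      bord[k] <- switch(e$kind, single = 1L, double = 2L, triple = 3L,
                        aromatic = 1L)
      barom[k] <- e$kind == "aromatic"
    } else {
      stop("product template bonds must be concrete (-, =, #, :): ",
           smirks, call. = FALSE)
    }
  }
  list(reactants = rpats, product = ppat, productSpec = pspec,
       productBondOrder = bord, productBondArom = barom)
}

# union of two molgraphs; returns combined graph and the index offset of b
.unionMol <- function(a, b) {
  off <- .nAtoms(a)
  out <- .emptyMol()
  out$elem <- c(a$elem, b$elem); out$arom <- c(a$arom, b$arom)
  out$charge <- c(a$charge, b$charge); out$hcount <- c(a$hcount, b$hcount)
  out$hfixed <- c(a$hfixed, b$hfixed); out$amap <- c(a$amap, b$amap)
  bb <- b$bond
  if (nrow(bb) > 0L) { bb[, "a"] <- bb[, "a"] + off; bb[, "b"] <- bb[, "b"] + off }
  out$bond <- rbind(a$bond, bb)
  out$baro <- c(a$baro, b$baro)
  list(mol = out, offset = off)
}

# Apply a parsed SMIRKS to concrete reactant molgraphs with chosen template
# embeddings. Returns the edited molgraph (all fragments) or NULL on an
# inconsistent edit.
.applySmirks <- function(rx, mols, embeddings) {
  stopifnot(length(mols) == length(rx$reactants),
            length(embeddings) == length(rx$reactants))
  if (length(mols) == 2L) {
    u <- .unionMol(mols[[1]], mols[[2]])
    combined <- u$mol
    embeddings[[2]] <- embeddings[[2]] + u$offset
  } else combined <- mols[[1]]
  # map number -> combined atom index
  mapTo <- integer(0)
  for (s in seq_along(rx$reactants)) {
    p <- rx$reactants[[s]]
    mapTo[as.character(p$amap)] <- embeddings[[s]]
  }
  # 1. drop reactant-template bonds between mapped atoms
  drop <- logical(nrow(combined$bond))
  for (s in seq_along(rx$reactants)) {
    p <- rx$reactants[[s]]
    if (nrow(p$bond) > 0L) for (k in seq_len(nrow(p$bond))) {
      ia <- embeddings[[s]][p$bond[k, 1]]
      ib <- embeddings[[s]][p$bond[k, 2]]
      hit <- (combined$bond[, "a"] == ia & combined$bond[, "b"] == ib) |
        (combined$bond[, "a"] == ib & combined$bond[, "b"] == ia)
      drop <- drop | hit
    }
  }
  combined$bond <- combined$bond[!drop, , drop = FALSE]
  combined$baro <- combined$baro[!drop]
  # 2. create new product atoms, remember product-template -> combined index
  ppat <- rx$product
  pIdx <- integer(length(ppat$atoms))
  touched <- integer(0)
  for (i in seq_along(ppat$atoms)) {
    m <- ppat$amap[i]
    spec <- rx$productSpec[[i]]
    if (m > 0L) {
      idx <- mapTo[[as.character(m)]]
      if (is.null(idx) || is.na(idx)) return(NULL)
      pIdx[i] <- idx
      # product template may flip aromaticity/charge of mapped atoms
      if (!is.na(spec$elem)) {
        combined$elem[idx] <- spec$elem
        combined$arom[idx] <- spec$arom
      }
      combined$charge[idx] <- spec$charge
      if (!is.na(spec$hcount)) {
        combined$hcount[idx] <- spec$hcount; combined$hfixed[idx] <- TRUE
      } else combined$hfixed[idx] <- FALSE
    } else {
      if (is.na(spec$elem)) return(NULL)
      # a freshly created bracket atom without an H spec gets 0 hydrogens
      # (SMILES bracket convention); unbracketed new atoms are recomputed
      hfix <- !is.na(spec$hcount) || isTRUE(ppat$bracket[i])
      combined$elem <- c(combined$elem, spec$elem)
      combined$arom <- c(combined$arom, spec$arom)
      combined$charge <- c(combined$charge, spec$charge)
      combined$hcount <- c(combined$hcount,
                           if (is.na(spec$hcount)) 0L else spec$hcount)
      combined$hfixed <- c(combined$hfixed, hfix)
      combined$amap <- c(combined$amap, 0L)
      pIdx[i] <- length(combined$elem)
    }
    touched <- c(touched, pIdx[i])
  }
  # 3. add product-template bonds
  if (nrow(ppat$bond) > 0L) for (k in seq_len(nrow(ppat$bond))) {
    ia <- pIdx[ppat$bond[k, 1]]; ib <- pIdx[ppat$bond[k, 2]]
    if (ia == ib) return(NULL)
    hit <- which((combined$bond[, "a"] == ia & combined$bond[, "b"] == ib) |
                   (combined$bond[, "a"] == ib & combined$bond[, "b"] == ia))
    if (length(hit) > 0L) {
      combined$bond[hit[1], "order"] <- rx$productBondOrder[k]
      combined$baro[hit[1]] <- rx$productBondArom[k]
    } else {
      combined$bond <- rbind(combined$bond,
                             matrix(c(ia, ib, rx$productBondOrder[k]),
                                    ncol = 3,
                                    dimnames = list(NULL,
                                                    c("a", "b", "order"))))
      combined$baro <- c(combined$baro, rx$productBondArom[k])
    }
  }
  # 4. delete mapped reactant atoms absent from the product
  keptMaps <- ppat$amap[ppat$amap > 0L]
  gone <- vapply(names(mapTo), function(m) !(as.integer(m) %in% keptMaps),
                 TRUE)
  if (any(gone)) {
    goneIdx <- unlist(mapTo[gone])
    keepAtoms <- setdiff(seq_len(length(combined$elem)), goneIdx)
    old2new <- match(seq_len(length(combined$elem)), keepAtoms)
    keepB <- !(combined$bond[, "a"] %in% goneIdx |
                 combined$bond[, "b"] %in% goneIdx)
    combined$bond <- combined$bond[keepB, , drop = FALSE]
    combined$baro <- combined$baro[keepB]
    if (nrow(combined$bond) > 0L) {
      combined$bond[, "a"] <- old2new[combined$bond[, "a"]]
      combined$bond[, "b"] <- old2new[combined$bond[, "b"]]
    }
    touched <- stats::na.omit(old2new[touched])
    combined$elem <- combined$elem[keepAtoms]
    combined$arom <- combined$arom[keepAtoms]
    combined$charge <- combined$charge[keepAtoms]
    combined$hcount <- combined$hcount[keepAtoms]
    combined$hfixed <- combined$hfixed[keepAtoms]
    combined$amap <- combined$amap[keepAtoms]
  }
  # 5. recompute hydrogens on touched atoms without explicit H
  bs <- .bondOrderSum(combined)
  for (i in touched) {
    if (!combined$hfixed[i]) {
      combined$hcount[i] <- .defaultHcount(combined$elem[i],
                                           combined$arom[i], bs[i])
    }
  }
  combined
}

# full pipeline for one reaction on concrete reactants: enumerate template
# embeddings, optionally sample one site, keep the largest fragment,
# canonicalize (or, with sanitize = FALSE, return the raw written SMILES
# for deferred batch canonicalization). Returns SMILES or NULL.
.runReaction <- function(rx, mols, pick = NULL, sanitize = TRUE) {
  ctxs <- lapply(mols, .molContext)
  embs <- vector("list", length(mols))
  for (s in seq_along(mols)) {
    found <- .matchSmarts(rx$reactants[[s]], ctxs[[s]], maxMatches = 64L)
    if (length(found) == 0L) return(NULL)
    embs[[s]] <- found
  }
  # enumerate (or sample) one embedding combination
  idx <- if (is.null(pick)) lapply(embs, function(e) 1L)
  else pick(vapply(embs, length, 0L))
  emb <- lapply(seq_along(embs), function(s) embs[[s]][[idx[[s]]]])
  out <- .applySmirks(rx, mols, emb)
  if (is.null(out) || .nAtoms(out) == 0L) return(NULL)
  out <- .largestFragment(out)
  raw <- .writeSmiles(out)
  if (!sanitize) return(raw)
  tryCatch(canonicalizeSmiles(raw), error = function(e) NULL)
}

#' Load a reaction library from its JSON description
#'
#' Validates every entry: the SMIRKS parses in the package's documented
#' SMARTS subset, the number of reactant templates matches
#' \code{num_reactants} and the per-slot substructure queries, and the
#' product template is concrete. Sizes and the bimolecular count are
#' reported in a message.
#'
#' @param path path to a reaction-library JSON file.
#' @param setName library name recorded on the returned object.
#' @return a \linkS4class{ReactionLibrary}.
#' @export
loadReactionLibrary <- function(path, setName = NULL) {
  if (!file.exists(path)) stop("reaction library not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(e) {
    need <- c("name", "smirks", "num_reactants", "slot_queries",
              "source_set")
    if (!all(need %in% names(e))) {
      stop("reaction entry missing fields: ",
           paste(setdiff(need, names(e)), collapse = ", "), call. = FALSE)
    }
    rx <- tryCatch(.parseSmirks(e$smirks), error = function(err) {
      stop(sprintf("reaction '%s': %s", e$name, conditionMessage(err)),
           call. = FALSE)
    })
    if (length(rx$reactants) != e$num_reactants) {
      stop(sprintf("reaction '%s': SMIRKS has %d reactant template(s), %d declared",
                   e$name, length(rx$reactants), e$num_reactants),
           call. = FALSE)
    }
    if (length(e$slot_queries) != e$num_reactants) {
      stop(sprintf("reaction '%s': %d slot queries for %d reactants",
                   e$name, length(e$slot_queries), e$num_reactants),
           call. = FALSE)
    }
    for (q in e$slot_queries) .parseSmarts(q)  # fail fast on bad queries
    new("ReactionSpec", name = e$name, smirks = e$smirks,
        numReactants = as.integer(e$num_reactants),
        slotQueries = as.character(unlist(e$slot_queries)),
        sourceSet = e$source_set,
        exampleReactants = as.character(unlist(e$example_reactants)))
  })
  lib <- new("ReactionLibrary",
             setName = if (is.null(setName)) "custom" else setName,
             reactions = specs)
  nbi <- sum(vapply(specs, function(r) r@numReactants, 0L) == 2L)
  message(sprintf("loaded reaction library '%s': %d reactions, %d bimolecular",
                  lib@setName, length(specs), nbi))
  lib
}

#' Load one of the bundled reaction sets
#'
#' Three sets ship with the package: \code{AutoClickChemRxn} (36
#' click-chemistry-style reactions), \code{RobustRxn} (58 robust
#' medicinal-chemistry coupling and ring-forming reactions) and
#' \code{AllRxn}, their 94-reaction union, 79 of which take two reactants.
#'
#' @param setName \code{"AutoClickChemRxn"}, \code{"RobustRxn"} or
#'   \code{"AllRxn"}.
#' @return a \linkS4class{ReactionLibrary}.
#' @examples
#' length(bundledReactionLibrary("AutoClickChemRxn"))
#' @export
bundledReactionLibrary <- function(setName = c("AllRxn", "AutoClickChemRxn",
                                               "RobustRxn")) {
  setName <- match.arg(setName)
  f <- function(x) system.file("extdata", x, package = "evoligand",
                               mustWork = TRUE)
  lib <- switch(setName,
                AutoClickChemRxn = loadReactionLibrary(
                  f("reactions_autoclickchem.json"), "AutoClickChemRxn"),
                RobustRxn = loadReactionLibrary(
                  f("reactions_robust.json"), "RobustRxn"),
                AllRxn = {
                  a <- loadReactionLibrary(f("reactions_autoclickchem.json"),
                                           "AutoClickChemRxn")
                  b <- loadReactionLibrary(f("reactions_robust.json"),
                                           "RobustRxn")
                  new("ReactionLibrary", setName = "AllRxn",
                      reactions = c(a@reactions, b@reactions))
                })
  lib
}

#' Self-test a reaction library on its example reactants
#'
#' Applies every reaction to its recorded \code{example_reactants} and
#' checks that a valid, canonicalizable product forms.
#'
#' @param library a \linkS4class{ReactionLibrary}.
#' @return data.frame with columns \code{name} and \code{ok}.
#' @export
selfTestReactionLibrary <- function(library) {
  res <- lapply(reactions(library), function(r) {
    ok <- tryCatch({
      if (length(r@exampleReactants) != r@numReactants) stop("no examples")
      rx <- .parseSmirks(r@smirks)
      mols <- lapply(r@exampleReactants,
                     function(s) .parseSmiles(canonicalizeSmiles(s)))
      !is.null(.runReaction(rx, mols))
    }, error = function(e) FALSE)
    data.frame(name = r@name, ok = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
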