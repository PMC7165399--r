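# Internal molecular-graph engine.
#
# Molecules are held as plain lists (class "molgraph"):
#   elem   character element symbols ("C", "Cl", ...)
#   arom   logical aromatic flags
#   charge integer formal charges
#   hcount integer attached hydrogen count (implicit H made explicit here)
#   hfixed logical whether hcount was written in brackets in the source
#   amap   integer atom-map class (0 = unmapped; used by reaction templates)
#   bond   integer matrix, columns (a, b, order); order 1/2/3, aromatic bonds
#          are stored with order 1 and baro TRUE
#   baro   logical aromatic-bond flags, one per bond row
#
# Stereochemistry is dropped on parse (a hadStereo attribute records the fact);
# canonical forms come from Open Babel downstream, never from this writer.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s", "se", "as")

# smallest "normal" valences used when inferring implicit hydrogens
.NORMAL_VALENCE <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5),
                        S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

.STANDARD_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.086,
                    P = 30.974, S = 32.065, Cl = 35.453, K = 39.098,
                    Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
                    Se = 78.971, As = 74.922, Br = 79.904, I = 126.904)

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                    Mg = 12, Si = 14, P = 15, S = 16, Cl = 17, K = 19,
                    Ca = 20, Fe = 26, Cu = 29, Zn = 30, As = 33, Se = 34,
                    Br = 35, I = 53)

.emptyMol <- function() {
  structure(list(elem = character(), arom = logical(), charge = integer(),
                 hcount = integer(), hfixed = logical(), amap = integer(),
                 bond = matrix(integer(), ncol = 3,
                               dimnames = list(NULL, c("a", "b", "order"))),
                 baro = logical()),
            class = "molgraph")
}

.molError <- function(smiles, why) {
  stop(sprintf("cannot parse SMILES '%s': %s", smiles, why), call. = FALSE)
}

# Tokenizing bracket atom bodies: [<isotope><sym><@..><H<n>><charge><:map>]
.parseBracket <- function(body, smiles) {
  m <- regmatches(body, regexec(
    "^([0-9]*)(se|as|[A-Z][a-z]?|[bcnops])(@{0,2})(H[0-9]*)?((?:\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+))?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0L) .molError(smiles, sprintf("bad bracket atom [%s]", body))
  sym <- m[3]
  arom <- sym %in% .AROMATIC_ELEMS
  elem <- if (arom) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  h <- m[5]
  hcount <- if (h == "") 0L else if (h == "H") 1L else as.integer(substring(h, 2))
  chg <- m[6]
  charge <- if (chg == "") 0L
  else if (grepl("^[+-][0-9]+$", chg)) as.integer(chg)
  else nchar(chg) * (if (substr(chg, 1, 1) == "+") 1L else -1L)
  amap <- if (m[7] == "") 0L else as.integer(substring(m[7], 2))
  list(elem = elem, arom = arom, hcount = hcount, charge = charge, amap = amap)
}

# Parse one SMILES string (possibly multi-fragment) into a molgraph.
# Stereo markers (/ \ @) are accepted and dropped. Results are memoized:
# parsing is pure and the same strings recur heavily inside a run.
.parseSmiles <- function(smiles) {
  key <- paste0("mol:", smiles)
  if (exists(key, envir = .pkgCache, inherits = FALSE)) {
    return(get(key, envir = .pkgCache))
  }
  mol <- .parseSmilesUncached(smiles)
  assign(key, mol, envir = .pkgCache)
  mol
}

.parseSmilesUncached <- function(smiles) {
  s <- gsub("[/\\\\]", "", trimws(smiles))
  if (nchar(s) == 0L) .molError(smiles, "empty string")
  mol <- .emptyMol()
  elem <- character(); arom <- logical(); charge <- integer()
  hcount <- integer(); hfixed <- logical(); amap <- integer()
  bonds <- list()
  stack <- integer()          # branch stack
  prev <- 0L                  # previous atom index
  pending <- ""               # pending bond symbol
  ring <- list()              # open ring closures: num -> c(atom, bondsym)
  hadStereo <- grepl("[@/\\\\]", smiles)
  i <- 1L; n <- nchar(s)
  newAtom <- function(e, ar, hc, hf, ch, am) {
    elem[length(elem) + 1L] <<- e
    arom[length(arom) + 1L] <<- ar
    hcount[length(hcount) + 1L] <<- hc
    hfixed[length(hfixed) + 1L] <<- hf
    charge[length(charge) + 1L] <<- ch
    amap[length(amap) + 1L] <<- am
    idx <- length(elem)
    if (prev > 0L) {
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, pendingOrder(prev, idx))
    }
    prev <<- idx
    pending <<- ""
    idx
  }
  pendingOrder <- function(a, b) {
    # encode: order in 1..3, aromatic as 4, resolved later
    if (pending == "") {
      if (arom[a] && arom[b]) 4L else 1L
    } else switch(pending, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L,
                  .molError(smiles, paste("bad bond", pending)))
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) .molError(smiles, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) .molError(smiles, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; pending <- ""; i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (prev == 0L) .molError(smiles, "ring closure before any atom")
      if (ch == "%") {
        num <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", num)) .molError(smiles, "bad %nn ring closure")
        i <- i + 3L
      } else { num <- ch; i <- i + 1L }
      key <- as.character(as.integer(num))
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, sym = pending)
      } else {
        op <- ring[[key]]
        sym <- if (pending != "") pending else op$sym
        a <- op$atom; b <- prev
        ord <- if (sym == "") { if (arom[a] && arom[b]) 4L else 1L }
        else switch(sym, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L)
        bonds[[length(bonds) + 1L]] <- c(a, b, ord)
        ring[[key]] <- NULL
      }
      pending <- ""
    } else if (ch == "[") {
      j <- regexpr("]", substring(s, i))[1]
      if (j < 0) .molError(smiles, "unclosed bracket")
      at <- .parseBracket(substr(s, i + 1L, i + j - 2L), smiles)
      newAtom(at$elem, at$arom, at$hcount, TRUE, at$charge, at$amap)
      i <- i + j
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        newAtom(two, FALSE, 0L, FALSE, 0L, 0L); i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        newAtom(ch, FALSE, 0L, FALSE, 0L, 0L); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        newAtom(toupper(ch), TRUE, 0L, FALSE, 0L, 0L); i <- i + 1L
      } else .molError(smiles, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(ring) > 0L) .molError(smiles, "unclosed ring bond")
  if (length(stack) > 0L) .molError(smiles, "unclosed branch")
  if (length(elem) == 0L) .molError(smiles, "no atoms")
  bm <- do.call(rbind, bonds)
  if (is.null(bm)) bm <- matrix(integer(), ncol = 3)
  baro <- bm[, 3] == 4L
  bm[baro, 3] <- 1L
  colnames(bm) <- c("a", "b", "order")
  mol$elem <- elem; mol$arom <- arom; mol$charge <- charge
  mol$hcount <- hcount; mol$hfixed <- hfixed; mol$amap <- amap
  mol$bond <- bm; mol$baro <- baro
  mol <- .assignImplicitH(mol, smiles)
  attr(mol, "hadStereo") <- hadStereo
  mol
}

# Sum of bond orders seen by each atom, counting aromatic bonds as 1.
.bondOrderSum <- function(mol) {
  bs <- integer(length(mol$elem))
  if (nrow(mol$bond) > 0L) {
    for (k in seq_len(nrow(mol$bond))) {
      o <- mol$bond[k, "order"]
      bs[mol$bond[k, "a"]] <- bs[mol$bond[k, "a"]] + o
      bs[mol$bond[k, "b"]] <- bs[mol$bond[k, "b"]] + o
    }
  }
  bs
}

# Extra valence unit consumed by the delocalized system: one for aromatic
# C/B always, one for pyridine-type aromatic N/P (two sigma connections);
# pyrrole-type N (three connections, lone pair in the ring) gets none.
.aromExtra <- function(elem, arom, occupied) {
  if (!arom) return(0L)
  # aromatic C with an exocyclic double bond (c(=O), azulenones, ...) spends
  # its pi electron on that bond and gets no extra unit
  if (elem %in% c("C", "B") && occupied <= 3L) return(1L)
  if (elem %in% c("N", "P") && occupied <= 2L) return(1L)
  0L
}

# Implicit hydrogen count an unbracketed atom would get under SMILES rules:
# smallest normal valence >= bond-order sum, minus that sum, with the
# aromatic adjustment above.
.defaultHcount <- function(elem, arom, bondsum) {
  nv <- .NORMAL_VALENCE[[elem]]
  if (is.null(nv)) return(0L)
  eff <- bondsum + .aromExtra(elem, arom, bondsum)
  v <- nv[nv >= eff]
  if (length(v) == 0L) return(0L)
  as.integer(v[1] - eff)
}

.assignImplicitH <- function(mol, smiles) {
  bs <- .bondOrderSum(mol)
  for (i in seq_along(mol$elem)) {
    if (!mol$hfixed[i]) {
      mol$hcount[i] <- .defaultHcount(mol$elem[i], mol$arom[i], bs[i])
    }
  }
  mol
}

.nAtoms <- function(mol) length(mol$elem)

# adjacency list: per atom, matrix of (neighbor, bond-row)
.adjacency <- function(mol) {
  adj <- vector("list", .nAtoms(mol))
  for (i in seq_along(adj)) adj[[i]] <- matrix(integer(), ncol = 2)
  if (nrow(mol$bond) > 0L) {
    for (k in seq_len(nrow(mol$bond))) {
      a <- mol$bond[k, "a"]; b <- mol$bond[k, "b"]
      adj[[a]] <- rbind(adj[[a]], c(b, k))
      adj[[b]] <- rbind(adj[[b]], c(a, k))
    }
  }
  adj
}

# ring-bond flags via bridge detection (a bond is in a ring iff not a bridge)
.ringBonds <- function(mol) {
  nb <- nrow(mol$bond)
  if (nb == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(mol$bond[, c("a", "b"), drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < .nAtoms(mol)) {
    g <- igraph::add_vertices(g, .nAtoms(mol) - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  inRing <- rep(TRUE, nb)
  inRing[as.integer(br)] <- FALSE
  inRing
}

.ringAtoms <- function(mol, ringBond = .ringBonds(mol)) {
  inRing <- rep(FALSE, .nAtoms(mol))
  if (any(ringBond)) {
    rb <- mol$bond[ringBond, , drop = FALSE]
    inRing[unique(c(rb[, "a"], rb[, "b"]))] <- TRUE
  }
  inRing
}

# number of independent rings (cyclomatic number)
.ringCount <- function(mol) {
  g <- igraph::graph_from_edgelist(mol$bond[, c("a", "b"), drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < .nAtoms(mol)) {
    g <- igraph::add_vertices(g, .nAtoms(mol) - igraph::vcount(g))
  }
  ncomp <- igraph::components(g)$no
  nrow(mol$bond) - .nAtoms(mol) + ncomp
}

# connected fragments as lists of atom indices
.fragments <- function(mol) {
  g <- igraph::graph_from_edgelist(mol$bond[, c("a", "b"), drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < .nAtoms(mol)) {
    g <- igraph::add_vertices(g, .nAtoms(mol) - igraph::vcount(g))
  }
  comp <- igraph::components(g)$membership
  split(seq_along(comp), comp)
}

# restrict a molgraph to an atom subset (bonds within the subset only)
.subMol <- function(mol, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  idx <- match(seq_len(.nAtoms(mol)), atoms)
  keep <- if (nrow(mol$bond) > 0L) {
    mol$bond[, "a"] %in% atoms & mol$bond[, "b"] %in% atoms
  } else logical(0)
  bm <- mol$bond[keep, , drop = FALSE]
  if (nrow(bm) > 0L) {
    bm[, "a"] <- idx[bm[, "a"]]; bm[, "b"] <- idx[bm[, "b"]]
  }
  out <- .emptyMol()
  out$elem <- mol$elem[atoms]; out$arom <- mol$arom[atoms]
  out$charge <- mol$charge[atoms]; out$hcount <- mol$hcount[atoms]
  out$hfixed <- mol$hfixed[atoms]; out$amap <- mol$amap[atoms]
  out$bond <- bm; out$baro <- mol$baro[keep]
  out
}

# largest fragment by heavy-atom count, ties broken by element string
.largestFragment <- function(mol) {
  fr <- .fragments(mol)
  if (length(fr) == 1L) return(mol)
  sizes <- vapply(fr, length, 0L)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    keys <- vapply(best, function(i) paste(sort(mol$elem[fr[[i]]]),
                                           collapse = ""), "")
    best <- best[order(keys)][1]
  } else best <- best[1]
  .subMol(mol, fr[[best]])
}

# Write a (valid, not canonical) SMILES for a molgraph. Hydrogen counts are
# made explicit in brackets whenever the SMILES default would differ, so the
# round trip through a canonicalizer preserves the graph.
.writeSmiles <- function(mol) {
  n <- .nAtoms(mol)
  if (n == 0L) return("")
  adj <- .adjacency(mol)
  bs <- .bondOrderSum(mol)
  atomToken <- function(i) {
    e <- mol$elem[i]
    sym <- if (mol$arom[i]) tolower(e) else e
    needBracket <- mol$charge[i] != 0L ||
      !(e %in% .ORGANIC_SUBSET) ||
      (mol$arom[i] && !(tolower(e) %in% c("b", "c", "n", "o", "p", "s"))) ||
      mol$hcount[i] != .defaultHcount(e, mol$arom[i], bs[i])
    if (!needBracket) return(sym)
    h <- if (mol$hcount[i] == 0L) "" else if (mol$hcount[i] == 1L) "H"
    else paste0("H", mol$hcount[i])
    ch <- mol$charge[i]
    cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
    else sprintf("%+d", ch)
    paste0("[", sym, h, cs, "]")
  }
  bondToken <- function(k, from, to) {
    if (mol$baro[k]) {
      if (mol$arom[from] && mol$arom[to]) return("") else return(":")
    }
    o <- mol$bond[k, "order"]
    if (o == 1L) {
      if (mol$arom[from] && mol$arom[to]) return("-") else return("")
    }
    if (o == 2L) return("=")
    "#"
  }
  visited <- logical(n)
  usedBond <- logical(nrow(mol$bond))
  ringNum <- 0L
  ringLabel <- list()  # bond row -> number
  # pre-pass: find ring-closure bonds via DFS spanning tree
  closure <- rep(FALSE, nrow(mol$bond))
  seen <- logical(n)
  for (root in seq_len(n)) {
    if (seen[root]) next
    stack2 <- root; seen[root] <- TRUE
    while (length(stack2) > 0L) {
      v <- stack2[length(stack2)]; stack2 <- stack2[-length(stack2)]
      nb <- adj[[v]]
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]; k <- nb[r, 2]
        if (usedBond[k]) next
        usedBond[k] <- TRUE
        if (seen[w]) closure[k] <- TRUE
        else { seen[w] <- TRUE; stack2 <- c(stack2, w) }
      }
    }
  }
  for (k in which(closure)) {
    ringNum <- ringNum + 1L
    ringLabel[[as.character(k)]] <- ringNum
  }
  numTok <- function(x) if (x < 10L) as.character(x) else sprintf("%%%02d", x)
  emit <- function(v, fromBond) {
    out <- atomToken(v)
    visited[v] <<- TRUE
    nb <- adj[[v]]
    # ring-closure digits at this atom
    if (nrow(nb) > 0L) for (r in seq_len(nrow(nb))) {
      k <- nb[r, 2]
      if (closure[k]) {
        lbl <- ringLabel[[as.character(k)]]
        out <- paste0(out, bondToken(k, v, nb[r, 1]), numTok(lbl))
      }
    }
    branches <- character()
    if (nrow(nb) > 0L) for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]; k <- nb[r, 2]
      if (closure[k] || visited[w] || (!is.null(fromBond) && k == fromBond))
        next
      branches <- c(branches, paste0(bondToken(k, v, w), emit(w, k)))
    }
    if (length(branches) > 1L) {
      out <- paste0(out,
                    paste0("(", branches[-length(branches)], ")",
                           collapse = ""),
                    branches[length(branches)])
    } else if (length(branches) == 1L) out <- paste0(out, branches)
    out
  }
  pieces <- character()
  for (root in seq_len(n)) {
    if (!visited[root]) pieces <- c(pieces, emit(root, NULL))
  }
  paste(pieces, collapse = ".")
}

# molecular weight from standard atomic masses, including attached hydrogens
.molWeight <- function(mol) {
  m <- .STANDARD_MASS[mol$elem]
  if (anyNA(m)) {
    stop("no standard mass for element(s): ",
         paste(unique(mol$elem[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  sum(m) + sum(mol$hcount) * .STANDARD_MASS[["H"]]
}
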