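# SMARTS subset engine: pattern parsing and subgraph matching with
# atom-level match maps (needed by the reaction and fragmentation
# machinery; boolean-only catalog matching goes through Open Babel).
#
# Supported atom primitives: element symbols (aromatic-aware), #n, *, A, a,
# D<n>, H<n>/h<n>, X<n>, v<n>, R/R0/R<n>, charges, atom maps :n, negation !,
# conjunctions & and ;, disjunction ",", recursive SMARTS $(...).
# Supported bond primitives: - = # : ~ @ and !, with &/;/, combinations;
# the default bond is single-or-aromatic.
# Not supported (never used by the bundled libraries): isotopes, chirality,
# r<n> ring sizes, x<n> ring connectivity, component-level grouping.

.smartsError <- function(pattern, why) {
  stop(sprintf("cannot parse SMARTS '%s': %s", pattern, why), call. = FALSE)
}

# --- parsing ---------------------------------------------------------------

# tokenize the inside of a bracket atom into primitive tokens
.parseAtomExpr <- function(body, pattern) {
  toks <- list(); i <- 1L; n <- nchar(body)
  num <- function(def) {
    j <- i
    while (j <= n && grepl("[0-9]", substr(body, j, j))) j <- j + 1L
    if (j == i) return(list(val = def, nxt = i))
    list(val = as.integer(substr(body, i, j - 1L)), nxt = j)
  }
  amap <- 0L
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch %in% c("!", "&", ";", ",")) {
      toks[[length(toks) + 1L]] <- list(t = ch); i <- i + 1L
    } else if (ch == "$") {
      if (substr(body, i + 1L, i + 1L) != "(")
        .smartsError(pattern, "expected $(...)")
      depth <- 0L; j <- i + 1L
      repeat {
        cj <- substr(body, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1L
        if (j > n) .smartsError(pattern, "unclosed recursive SMARTS")
      }
      sub <- substr(body, i + 2L, j - 1L)
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = "rec",
                                        pat = .parseSmarts(sub))
      i <- j + 1L
    } else if (ch == "#") {
      i <- i + 1L; r <- num(NA); i <- r$nxt
      if (is.na(r$val)) .smartsError(pattern, "#requires a number")
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = "anum",
                                        val = r$val)
    } else if (ch == "*") {
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = "any")
      i <- i + 1L
    } else if (ch %in% c("D", "X", "v")) {
      i <- i + 1L; r <- num(1L); i <- r$nxt
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = ch, val = r$val)
    } else if (ch %in% c("H", "h")) {
      i <- i + 1L; r <- num(1L); i <- r$nxt
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = "H", val = r$val)
    } else if (ch == "R") {
      i <- i + 1L; r <- num(NA); i <- r$nxt
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = "ring",
                                        val = if (is.na(r$val)) TRUE
                                        else r$val > 0L)
    } else if (ch %in% c("+", "-")) {
      sgn <- if (ch == "+") 1L else -1L
      j <- i + 1L; cnt <- 1L
      while (j <= n && substr(body, j, j) == ch) { cnt <- cnt + 1L; j <- j + 1L }
      r <- NULL
      if (j <= n && grepl("[0-9]", substr(body, j, j)) && cnt == 1L) {
        i <- j; r <- num(1L); j <- r$nxt; cnt <- r$val
      }
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = "charge",
                                        val = sgn * cnt)
      i <- j
    } else if (ch == ":") {
      i <- i + 1L; r <- num(NA); i <- r$nxt
      if (is.na(r$val)) .smartsError(pattern, "bad atom map")
      amap <- r$val
    } else if (ch == "a") {
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = "arom",
                                        val = TRUE); i <- i + 1L
    } else if (ch == "A") {
      nxt2 <- substr(body, i, i + 1L)
      if (nxt2 %in% c("Al", "As", "Ag", "Au")) {
        toks[[length(toks) + 1L]] <- list(t = "prim", kind = "elem",
                                          elem = nxt2, arom = NA)
        i <- i + 2L
      } else {
        toks[[length(toks) + 1L]] <- list(t = "prim", kind = "arom",
                                          val = FALSE); i <- i + 1L
      }
    } else {
      two <- substr(body, i, i + 1L)
      lower2 <- two %in% c("se", "as")
      if (lower2 || grepl("^[A-Z][a-z]$", two)) {
        # two-letter element; lowercase pair = aromatic Se/As
        if (lower2) {
          toks[[length(toks) + 1L]] <- list(
            t = "prim", kind = "elem",
            elem = paste0(toupper(substr(two, 1, 1)), substr(two, 2, 2)),
            arom = TRUE)
          i <- i + 2L
        } else if (two %in% c("Cl", "Br") ||
                   two %in% names(.ATOMIC_NUMBER)) {
          toks[[length(toks) + 1L]] <- list(t = "prim", kind = "elem",
                                            elem = two, arom = NA)
          i <- i + 2L
        } else {
          toks[[length(toks) + 1L]] <- list(t = "prim", kind = "elem",
                                            elem = substr(two, 1, 1),
                                            arom = FALSE)
          i <- i + 1L
        }
      } else if (grepl("^[A-Z]$", ch)) {
        if (!(ch %in% names(.ATOMIC_NUMBER))) {
          .smartsError(pattern, sprintf("unknown element '%s'", ch))
        }
        toks[[length(toks) + 1L]] <- list(t = "prim", kind = "elem",
                                          elem = ch, arom = FALSE)
        i <- i + 1L
      } else if (grepl("^[bcnops]$", ch)) {
        toks[[length(toks) + 1L]] <- list(t = "prim", kind = "elem",
                                          elem = toupper(ch), arom = TRUE)
        i <- i + 1L
      } else if (grepl("[0-9]", ch)) {
        # isotope specification: parse and ignore
        r <- num(NA); i <- r$nxt
      } else .smartsError(pattern, sprintf("bad atom primitive '%s'", ch))
    }
  }
  list(expr = .buildAtomTree(toks, pattern), amap = amap)
}

# precedence: ! > & (implicit) > , > ;
.buildAtomTree <- function(toks, pattern) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  parseUnary <- function() {
    t <- peek()
    if (is.null(t)) .smartsError(pattern, "dangling operator")
    if (identical(t$t, "!")) { take(); return(list(op = "not", x = parseUnary())) }
    if (!identical(t$t, "prim")) .smartsError(pattern, "expected primitive")
    take()
  }
  parseAnd <- function() {
    xs <- list(parseUnary())
    repeat {
      t <- peek()
      if (is.null(t)) break
      if (identical(t$t, "&")) { take(); xs[[length(xs) + 1L]] <- parseUnary() }
      else if (identical(t$t, "prim") || identical(t$t, "!")) {
        xs[[length(xs) + 1L]] <- parseUnary()
      } else break
    }
    if (length(xs) == 1L) xs[[1]] else list(op = "and", xs = xs)
  }
  parseOr <- function() {
    xs <- list(parseAnd())
    while (!is.null(peek()) && identical(peek()$t, ",")) {
      take(); xs[[length(xs) + 1L]] <- parseAnd()
    }
    if (length(xs) == 1L) xs[[1]] else list(op = "or", xs = xs)
  }
  parseSemi <- function() {
    xs <- list(parseOr())
    while (!is.null(peek()) && identical(peek()$t, ";")) {
      take(); xs[[length(xs) + 1L]] <- parseOr()
    }
    if (length(xs) == 1L) xs[[1]] else list(op = "and", xs = xs)
  }
  out <- parseSemi()
  if (pos <= length(toks)) .smartsError(pattern, "trailing atom tokens")
  out
}

# bond expression from collected bond symbol string (may be "")
.buildBondExpr <- function(sym, pattern) {
  if (sym == "") return(list(op = "default"))
  toks <- list(); i <- 1L; n <- nchar(sym)
  while (i <= n) {
    ch <- substr(sym, i, i)
    if (ch %in% c("!", "&", ";", ",")) toks[[length(toks) + 1L]] <- list(t = ch)
    else if (ch %in% c("-", "=", "#", ":", "~", "@", "/", "\\")) {
      kind <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                     ":" = "aromatic", "~" = "anybond", "@" = "ringbond",
                     "/" = "single", "\\" = "single")
      toks[[length(toks) + 1L]] <- list(t = "prim", kind = kind)
    } else .smartsError(pattern, sprintf("bad bond symbol '%s'", ch))
    i <- i + 1L
  }
  .buildAtomTree(toks, pattern)  # same precedence machinery
}

# Parse a SMARTS pattern into a pattern graph:
#   atoms: list of atom expression trees; amap: integer atom maps
#   bond: matrix (a, b); bexpr: list of bond expression trees
.parseSmarts <- function(pattern) {
  s <- trimws(pattern)
  if (nchar(s) == 0L) .smartsError(pattern, "empty pattern")
  atoms <- list(); amap <- integer(); bracket <- logical()
  bonds <- list(); bexpr <- list()
  stack <- integer(); prev <- 0L; pend <- ""
  ring <- list()
  i <- 1L; n <- nchar(s)
  pushAtom <- function(expr, map, brk = FALSE) {
    atoms[[length(atoms) + 1L]] <<- expr
    amap[length(amap) + 1L] <<- map
    bracket[length(bracket) + 1L] <<- brk
    idx <- length(atoms)
    if (prev > 0L) {
      bonds[[length(bonds) + 1L]] <<- c(prev, idx)
      bexpr[[length(bexpr) + 1L]] <<- .buildBondExpr(pend, pattern)
    }
    prev <<- idx; pend <<- ""
    idx
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("-", "=", "#", ":", "~", "@", "!", "&", ";", ",", "/", "\\")) {
      pend <- paste0(pend, ch); i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) .smartsError(pattern, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) .smartsError(pattern, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (prev == 0L) .smartsError(pattern, "ring closure before any atom")
      if (ch == "%") { numStr <- substr(s, i + 1L, i + 2L); i <- i + 3L }
      else { numStr <- ch; i <- i + 1L }
      key <- as.character(as.integer(numStr))
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, sym = pend)
      } else {
        op <- ring[[key]]
        sym <- if (pend != "") pend else op$sym
        bonds[[length(bonds) + 1L]] <- c(op$atom, prev)
        bexpr[[length(bexpr) + 1L]] <- .buildBondExpr(sym, pattern)
        ring[[key]] <- NULL
      }
      pend <- ""
    } else if (ch == "[") {
      depth <- 0L; j <- i
      repeat {
        cj <- substr(s, j, j)
        if (cj == "[") depth <- depth + 1L
        if (cj == "]") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1L
        if (j > n) .smartsError(pattern, "unclosed bracket")
      }
      at <- .parseAtomExpr(substr(s, i + 1L, j - 1L), pattern)
      pushAtom(at$expr, at$amap, brk = TRUE)
      i <- j + 1L
    } else if (ch == "*") {
      pushAtom(list(op = "prim", t = "prim", kind = "any"), 0L); i <- i + 1L
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        pushAtom(list(t = "prim", kind = "elem", elem = two, arom = NA),
                 0L)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        pushAtom(list(t = "prim", kind = "elem", elem = ch, arom = FALSE),
                 0L)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        pushAtom(list(t = "prim", kind = "elem", elem = toupper(ch),
                      arom = TRUE), 0L)
        i <- i + 1L
      } else if (ch == "A") {
        pushAtom(list(t = "prim", kind = "arom", val = FALSE), 0L)
        i <- i + 1L
      } else if (ch == "a") {
        pushAtom(list(t = "prim", kind = "arom", val = TRUE), 0L)
        i <- i + 1L
      } else .smartsError(pattern, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(ring) > 0L) .smartsError(pattern, "unclosed ring bond")
  if (length(stack) > 0L) .smartsError(pattern, "unclosed branch")
  if (length(atoms) == 0L) .smartsError(pattern, "no atoms")
  bm <- do.call(rbind, bonds)
  if (is.null(bm)) bm <- matrix(integer(), ncol = 2)
  structure(list(atoms = atoms, amap = amap, bracket = bracket,
                 bond = bm, bexpr = bexpr, pattern = pattern),
            class = "smartsPattern")
}

# --- matching --------------------------------------------------------------

# precomputed per-molecule context reused across patterns
.molContext <- function(mol) {
  adj <- .adjacency(mol)
  ringB <- .ringBonds(mol)
  list(mol = mol, adj = adj,
       deg = vapply(adj, nrow, 0L),
       ringBond = ringB,
       ringAtom = .ringAtoms(mol, ringB),
       bsum = .bondOrderSum(mol))
}

.evalAtomExpr <- function(expr, ctx, i) {
  if (!is.null(expr$op) && expr$op %in% c("and", "or", "not")) {
    if (expr$op == "not") return(!.evalAtomExpr(expr$x, ctx, i))
    vals <- vapply(expr$xs, .evalAtomExpr, TRUE, ctx = ctx, i = i)
    return(if (expr$op == "and") all(vals) else any(vals))
  }
  mol <- ctx$mol
  switch(expr$kind,
         any = TRUE,
         anum = .ATOMIC_NUMBER[mol$elem[i]] == expr$val,
         elem = {
           ok <- mol$elem[i] == expr$elem
           if (ok && !is.na(expr$arom)) ok <- mol$arom[i] == expr$arom
           isTRUE(ok)
         },
         arom = mol$arom[i] == expr$val,
         D = ctx$deg[i] == expr$val,
         H = mol$hcount[i] == expr$val,
         X = (ctx$deg[i] + mol$hcount[i]) == expr$val,
         v = (ctx$bsum[i] + mol$hcount[i]) == expr$val,
         ring = ctx$ringAtom[i] == expr$val,
         charge = mol$charge[i] == expr$val,
         rec = length(.matchSmarts(expr$pat, ctx, anchor = i,
                                   maxMatches = 1L)) > 0L,
         stop("unhandled atom primitive: ", expr$kind))
}

.evalBondExpr <- function(expr, ctx, k) {
  if (!is.null(expr$op) && expr$op %in% c("and", "or", "not")) {
    if (expr$op == "not") return(!.evalBondExpr(expr$x, ctx, k))
    vals <- vapply(expr$xs, .evalBondExpr, TRUE, ctx = ctx, k = k)
    return(if (expr$op == "and") all(vals) else any(vals))
  }
  if (identical(expr$op, "default")) {
    return(ctx$mol$baro[k] || ctx$mol$bond[k, "order"] == 1L)
  }
  switch(expr$kind,
         single = !ctx$mol$baro[k] && ctx$mol$bond[k, "order"] == 1L,
         double = !ctx$mol$baro[k] && ctx$mol$bond[k, "order"] == 2L,
         triple = !ctx$mol$baro[k] && ctx$mol$bond[k, "order"] == 3L,
         aromatic = ctx$mol$baro[k],
         anybond = TRUE,
         ringbond = ctx$ringBond[k],
         stop("unhandled bond primitive: ", expr$kind))
}

# Subgraph matching by backtracking. Returns a list of integer vectors,
# each mapping pattern atom -> molecule atom. anchor (if given) pins
# pattern atom 1 to that molecule atom. Matches are deduplicated by their
# mapped atom tuple; uniqueSets additionally dedupes by unordered atom set.
.matchSmarts <- function(pat, ctx, anchor = NULL, maxMatches = Inf,
                         uniqueSets = FALSE) {
  np <- length(pat$atoms)
  nm <- .nAtoms(ctx$mol)
  if (np > nm) return(list())
  # pattern adjacency
  padj <- vector("list", np)
  for (q in seq_len(np)) padj[[q]] <- matrix(integer(), ncol = 2)
  if (nrow(pat$bond) > 0L) for (k in seq_len(nrow(pat$bond))) {
    a <- pat$bond[k, 1]; b <- pat$bond[k, 2]
    padj[[a]] <- rbind(padj[[a]], c(b, k))
    padj[[b]] <- rbind(padj[[b]], c(a, k))
  }
  # match order: DFS from atom 1 so each new atom touches a mapped one
  order <- integer(0); seen <- logical(np); stack <- 1L
  viaBond <- rep(NA_integer_, np); viaFrom <- rep(NA_integer_, np)
  while (length(stack) > 0L) {
    q <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[q]) next
    seen[q] <- TRUE; order <- c(order, q)
    nb <- padj[[q]]
    if (nrow(nb) > 0L) for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]
      if (!seen[w] && is.na(viaBond[w])) {
        viaBond[w] <- nb[r, 2]; viaFrom[w] <- q
        stack <- c(stack, w)
      }
    }
  }
  if (any(!seen)) {
    .smartsError(pat$pattern, "disconnected pattern (use the catalog layer)")
  }
  # molecule bond lookup: key "a:b" -> bond row
  bondKey <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(ctx$mol$bond) > 0L) for (k in seq_len(nrow(ctx$mol$bond))) {
    a <- ctx$mol$bond[k, "a"]; b <- ctx$mol$bond[k, "b"]
    assign(paste0(min(a, b), ":", max(a, b)), k, envir = bondKey)
  }
  getBond <- function(a, b) {
    key <- paste0(min(a, b), ":", max(a, b))
    if (exists(key, envir = bondKey, inherits = FALSE))
      get(key, envir = bondKey) else NA_integer_
  }
  results <- list()
  seenSets <- character()
  mapv <- rep(NA_integer_, np)
  used <- logical(nm)
  atomOK <- function(q, i) .evalAtomExpr(pat$atoms[[q]], ctx, i)
  recurse <- function(step) {
    if (length(results) >= maxMatches) return()
    if (step > np) {
      key <- paste(mapv, collapse = ",")
      if (uniqueSets) key <- paste(sort(mapv), collapse = ",")
      if (!(key %in% seenSets)) {
        seenSets[length(seenSets) + 1L] <<- key
        results[[length(results) + 1L]] <<- mapv
      }
      return()
    }
    q <- order[step]
    cand <- if (step == 1L) {
      if (!is.null(anchor)) anchor else seq_len(nm)
    } else {
      from <- mapv[viaFrom[q]]
      nb <- ctx$adj[[from]]
      if (nrow(nb) == 0L) integer() else nb[, 1]
    }
    for (i in cand) {
      if (used[i] || !atomOK(q, i)) next
      if (step > 1L) {
        k <- getBond(mapv[viaFrom[q]], i)
        if (is.na(k) || !.evalBondExpr(pat$bexpr[[viaBond[q]]], ctx, k)) next
      }
      # check all other pattern bonds from q into already-mapped atoms
      ok <- TRUE
      nbq <- padj[[q]]
      if (nrow(nbq) > 0L) for (r in seq_len(nrow(nbq))) {
        w <- nbq[r, 1]; pk <- nbq[r, 2]
        isVia <- !is.na(viaFrom[q]) && w == viaFrom[q] && pk == viaBond[q]
        if (!is.na(mapv[w]) && !isVia) {
          mk <- getBond(mapv[w], i)
          if (is.na(mk) || !.evalBondExpr(pat$bexpr[[pk]], ctx, mk)) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      mapv[q] <<- i; used[i] <<- TRUE
      recurse(step + 1L)
      mapv[q] <<- NA_integer_; used[i] <<- FALSE
      if (length(results) >= maxMatches) return()
    }
  }
  recurse(1L)
  results
}

# convenience: does `pattern` (SMARTS string or parsed) occur in `smiles`?
.smartsHit <- function(pattern, smiles) {
  pat <- if (inherits(pattern, "smartsPattern")) pattern
  else .parseSmarts(pattern)
  ctx <- .molContext(.parseSmiles(smiles))
  length(.matchSmarts(pat, ctx, maxMatches = 1L)) > 0L
}
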