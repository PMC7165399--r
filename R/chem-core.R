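# Molecule records: SMI I/O, physicochemical descriptors, lineage tracing.

.DESCRIPTOR_NAMES <- c("mw", "logp", "hbd", "hba", "mr", "n_atoms",
                       "heavy_atoms", "rotb", "rings", "n_count", "o_count",
                       "x_count", "psa")

#' Read an SMI file into seed MoleculeRecords
#'
#' One molecule per line: a SMILES first token and an optional name second
#' token, whitespace-delimited; blank lines and lines starting with
#' \code{#} are ignored. Molecules are canonicalized; multi-fragment
#' entries (salts, counterions) keep their largest fragment.
#'
#' @param path path to the SMI file.
#' @param onBadLine \code{"fail"} to stop with the offending line number,
#'   \code{"skip"} to drop bad lines (counted in a message).
#' @return list of \linkS4class{MoleculeRecord} with \code{origin="seed"},
#'   generation 0, in file order. Ids come from the name token, or are
#'   auto-generated as \code{seed<line>} when absent.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), f)
#' readSmi(f)
#' @export
readSmi <- function(path, onBadLine = c("fail", "skip")) {
  onBadLine <- match.arg(onBadLine)
  if (!file.exists(path)) stop("SMI file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  records <- list()
  nskip <- 0L
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    id <- if (length(tok) >= 2L) tok[2] else paste0("seed", i)
    rec <- tryCatch(
      moleculeRecord(.canonicalLargestFragment(tok[1]), id = id,
                     generation = 0L, origin = "seed", canonicalize = FALSE),
      error = function(e) e)
    if (inherits(rec, "error")) {
      if (onBadLine == "fail") {
        stop(sprintf("bad SMILES at line %d of %s: %s", i, path,
                     conditionMessage(rec)), call. = FALSE)
      }
      nskip <- nskip + 1L
    } else records[[length(records) + 1L]] <- rec
  }
  if (nskip > 0L) message(sprintf("readSmi: skipped %d bad line(s)", nskip))
  records
}

#' Write MoleculeRecords to an SMI file
#'
#' @param records list of \linkS4class{MoleculeRecord}.
#' @param path output file path.
#' @param scoreColumns score names appended as extra columns when present.
#' @return \code{path}, invisibly.
#' @export
writeSmi <- function(records, path, scoreColumns = character()) {
  lines <- vapply(records, function(r) {
    extra <- if (length(scoreColumns) > 0L) {
      vals <- r@scores[scoreColumns]
      paste0("\t", paste(sprintf("%.6g", vals), collapse = "\t"))
    } else ""
    paste0(r@smiles, "\t", r@id, extra)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# graph-derived descriptor pieces ------------------------------------------

.rotatableBonds <- function(mol) {
  if (nrow(mol$bond) == 0L) return(0L)
  ringB <- .ringBonds(mol)
  adj <- .adjacency(mol)
  deg <- vapply(adj, nrow, 0L)
  # is this atom an amide carbonyl carbon?
  isAmideC <- function(i) {
    if (mol$elem[i] != "C") return(FALSE)
    nb <- adj[[i]]
    any(vapply(seq_len(nrow(nb)), function(r) {
      mol$elem[nb[r, 1]] == "O" && mol$bond[nb[r, 2], "order"] == 2L
    }, TRUE))
  }
  n <- 0L
  for (k in seq_len(nrow(mol$bond))) {
    if (ringB[k] || mol$baro[k] || mol$bond[k, "order"] != 1L) next
    a <- mol$bond[k, "a"]; b <- mol$bond[k, "b"]
    if (deg[a] < 2L || deg[b] < 2L) next
    amide <- (mol$elem[b] == "N" && isAmideC(a)) ||
      (mol$elem[a] == "N" && isAmideC(b))
    if (amide) next
    n <- n + 1L
  }
  n
}

#' Physicochemical descriptors for drug-likeness filtering
#'
#' Computes, per molecule: molecular weight (Da, standard atomic masses
#' including hydrogens), an atom-contribution octanol--water logP estimate
#' and molar refractivity (both from Open Babel's contribution tables),
#' hydrogen-bond donors and acceptors in the Lipinski convention (donors =
#' O--H plus N--H bond count; acceptors = N plus O atom count), total and
#' heavy atom counts, rotatable bonds (non-ring single bonds between two
#' non-terminal heavy atoms, excluding amide C--N), ring count, N/O/halogen
#' counts, and topological polar surface area (\eqn{\mathrm{\AA}^2}).
#'
#' @param smiles character vector of SMILES (canonical or not).
#' @return data.frame with one row per molecule and columns
#'   \code{smiles, mw, logp, hbd, hba, mr, n_atoms, heavy_atoms, rotb,
#'   rings, n_count, o_count, x_count, psa}.
#' @examples
#' computeDescriptors(c("CCO", "c1ccccc1"))
#' @export
computeDescriptors <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.DESCRIPTOR_NAMES) + 1)),
      c("smiles", .DESCRIPTOR_NAMES)))
  }
  # descriptor rows are pure functions of the SMILES: serve cached rows
  keys <- paste0("desc:", smiles)
  cachedRows <- lapply(keys, function(k) {
    if (exists(k, envir = .pkgCache, inherits = FALSE)) {
      get(k, envir = .pkgCache)
    } else NULL
  })
  todo <- which(vapply(cachedRows, is.null, TRUE))
  if (length(todo) > 0L) {
    fresh <- .computeDescriptorsUncached(smiles[todo])
    for (k in seq_along(todo)) {
      row <- fresh[k, , drop = FALSE]
      assign(keys[todo[k]], row, envir = .pkgCache)
      cachedRows[[todo[k]]] <- row
    }
  }
  out <- do.call(rbind, cachedRows)
  rownames(out) <- NULL
  out
}

.computeDescriptorsUncached <- function(smiles) {
  mols <- lapply(smiles, function(s) {
    m <- .parseSmiles(s); .checkValence(m, s); m
  })
  # Open Babel contribution estimates (logP, MR, TPSA), batched
  clean <- gsub("[/\\\\@]", "", trimws(smiles))
  inp <- paste0(paste0(clean, " m", seq_along(clean)), collapse = "\n")
  props <- ChemmineOB::forEachMol("SMILES", inp,
                                  function(m) ChemmineOB::prop_OB(m))
  ptab <- do.call(rbind, props)
  if (nrow(ptab) != length(smiles)) {
    stop("descriptor backend returned ", nrow(ptab), " results for ",
         length(smiles), " molecules", call. = FALSE)
  }
  ord <- match(paste0("m", seq_along(clean)), ptab$title)
  if (anyNA(ord)) ord <- seq_along(clean)
  ptab <- ptab[ord, , drop = FALSE]
  one <- function(i) {
    mol <- mols[[i]]
    heavy <- .nAtoms(mol)
    hbdN <- sum(mol$hcount[mol$elem %in% c("N", "O")])
    data.frame(
      smiles = smiles[i],
      mw = .molWeight(mol),
      logp = ptab$logP[i],
      hbd = hbdN,
      hba = sum(mol$elem %in% c("N", "O")),
      mr = ptab$MR[i],
      n_atoms = heavy + sum(mol$hcount),
      heavy_atoms = heavy,
      rotb = .rotatableBonds(mol),
      rings = .ringCount(mol),
      n_count = sum(mol$elem == "N"),
      o_count = sum(mol$elem == "O"),
      x_count = sum(mol$elem %in% c("F", "Cl", "Br", "I")),
      psa = ptab$TPSA[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(smiles), one))
  rownames(out) <- NULL
  out
}

# lineage -------------------------------------------------------------------

#' Trace the ancestry of a compound through the run ledger
#'
#' Follows parent ids recursively down to generation-0 seeds and returns the
#' ancestry as a nested list: each node carries \code{id}, \code{origin},
#' \code{generation}, \code{smiles} and a \code{parents} list of subtrees.
#'
#' @param id the record id to trace.
#' @param ledger list of \linkS4class{MoleculeRecord} covering the run.
#' @return nested list ancestry tree; every leaf is a generation-0 seed.
#' @export
traceLineage <- function(id, ledger) {
  idx <- stats::setNames(seq_along(ledger),
                         vapply(ledger, function(r) r@id, ""))
  build <- function(theId, seen) {
    if (theId %in% seen) {
      stop("lineage cycle detected at id '", theId, "'", call. = FALSE)
    }
    i <- match(theId, names(idx))
    if (is.na(i)) {
      stop("lineage error: id '", theId, "' not found in ledger",
           call. = FALSE)
    }
    rec <- ledger[[i]]
    list(id = rec@id, origin = rec@origin, generation = rec@generation,
         smiles = rec@smiles,
         parents = lapply(rec@parentIds, build, seen = c(seen, theId)))
  }
  build(id, character())
}

# ledger serialization ------------------------------------------------------

#' Write the run ledger as a tab-separated table
#'
#' Columns: id, smiles, generation, origin, parent_ids (comma-joined),
#' reaction_name, then one column per score name present anywhere in the
#' ledger.
#'
#' @param records list of \linkS4class{MoleculeRecord}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeLedger <- function(records, path) {
  scoreNames <- sort(unique(unlist(lapply(records,
                                          function(r) names(r@scores)))))
  rows <- lapply(records, function(r) {
    sc <- stats::setNames(rep(NA_real_, length(scoreNames)), scoreNames)
    sc[names(r@scores)] <- r@scores
    c(id = r@id, smiles = r@smiles, generation = as.character(r@generation),
      origin = r@origin, parent_ids = paste(r@parentIds, collapse = ","),
      reaction_name = ifelse(is.na(r@reactionName), "", r@reactionName),
      vapply(sc, function(v) ifelse(is.na(v), "", sprintf("%.10g", v)), ""))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a run ledger written by [writeLedger()]
#'
#' @param path ledger TSV path.
#' @return list of \linkS4class{MoleculeRecord}.
#' @export
readLedger <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  fixed <- c("id", "smiles", "generation", "origin", "parent_ids",
             "reaction_name")
  scoreNames <- setdiff(colnames(tab), fixed)
  lapply(seq_len(nrow(tab)), function(i) {
    sc <- vapply(scoreNames, function(s) {
      v <- tab[i, s]
      if (nzchar(v)) as.numeric(v) else NA_real_
    }, 0)
    sc <- sc[!is.na(sc)]
    pid <- tab$parent_ids[i]
    moleculeRecord(tab$smiles[i], id = tab$id[i],
                   generation = as.integer(tab$generation[i]),
                   origin = tab$origin[i],
                   parentIds = if (nzchar(pid))
                     strsplit(pid, ",", fixed = TRUE)[[1]] else character(),
                   reactionName = if (nzchar(tab$reaction_name[i]))
                     tab$reaction_name[i] else NA_character_,
                   scores = sc, canonicalize = FALSE)
  })
}
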