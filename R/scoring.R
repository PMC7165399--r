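# Fitness machinery: Morgan fingerprints, Dice similarity, population
# diversity, ligand efficiency, the deterministic surrogate scorer, and
# the fitness-contract registry.

# Deterministic 32-bit mixing hash (FNV-1a variant processing one 32-bit
# word per step), implemented exactly in doubles; platform-independent.
.fnv1a <- function(ints) {
  h <- 2166136261
  p <- 16777619
  for (x in ints) {
    v <- x %% 4294967296
    # h <- h XOR v on 32 bits, via 16-bit halves
    hl <- h %% 65536; hh <- (h - hl) / 65536
    vl <- v %% 65536; vh <- (v - vl) / 65536
    h <- bitwXor(as.integer(hl), as.integer(vl)) +
      65536 * bitwXor(as.integer(hh), as.integer(vh))
    # h <- h * p mod 2^32
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Morgan (circular) fingerprint of a molecule
#'
#' Hashes each atom's initial invariants (atomic number, heavy degree,
#' attached hydrogens, formal charge, aromaticity, ring membership) and
#' iteratively folds in sorted neighbor environments up to \code{radius}
#' bond spheres, collecting every iteration's identifiers into a folded
#' bit set -- the bit string \eqn{F} that the Dice similarity of Eq.~1
#' compares.
#'
#' @param smiles a single SMILES string.
#' @param radius circular-neighborhood radius (default 2).
#' @param nbits fingerprint length, a power of two (default 2048).
#' @return a \linkS4class{Fingerprint}.
#' @examples
#' fp <- morganFingerprint("CCO")
#' @export
morganFingerprint <- function(smiles, radius = 2L, nbits = 2048L) {
  stopifnot(radius >= 0L, nbits >= 2L, bitwAnd(nbits, nbits - 1L) == 0L)
  key <- paste0("fp:", radius, ":", nbits, ":", smiles)
  if (exists(key, envir = .pkgCache, inherits = FALSE)) {
    return(get(key, envir = .pkgCache))
  }
  mol <- .parseSmiles(smiles)
  ctx <- .molContext(mol)
  n <- .nAtoms(mol)
  inv <- vapply(seq_len(n), function(i) {
    .fnv1a(c(.ATOMIC_NUMBER[[mol$elem[i]]], ctx$deg[i], mol$hcount[i],
             mol$charge[i] + 8L, as.integer(mol$arom[i]),
             as.integer(ctx$ringAtom[i])))
  }, 0)
  bits <- inv
  if (radius > 0L) for (r in seq_len(radius)) {
    newInv <- vapply(seq_len(n), function(i) {
      nb <- ctx$adj[[i]]
      env <- if (nrow(nb) == 0L) numeric() else {
        codes <- vapply(seq_len(nrow(nb)), function(rr) {
          k <- nb[rr, 2]
          bcode <- if (mol$baro[k]) 4 else mol$bond[k, "order"]
          bcode * 4294967296 + inv[nb[rr, 1]]
        }, 0)
        codes <- sort(codes)
        as.vector(rbind(codes %/% 4294967296, codes %% 4294967296))
      }
      .fnv1a(c(r, inv[i], env))
    }, 0)
    inv <- newInv
    bits <- c(bits, inv)
  }
  fp <- new("Fingerprint", bits = sort(unique(as.integer(bits %% nbits))),
            nbits = as.integer(nbits), radius = as.integer(radius))
  assign(key, fp, envir = .pkgCache)
  fp
}

#' Dice similarity of two fingerprints
#'
#' Computes \eqn{s(F_A, F_B) = 2|F_A \cap F_B| / (|F_A| + |F_B|)} on the
#' on-bit sets, exactly as written: 0 for completely different bit sets,
#' 1 for a perfect match. Two empty fingerprints are defined as completely
#' different (s = 0, with a warning), the conservative reading of the
#' 0/0 case.
#'
#' @param fa,fb \linkS4class{Fingerprint} objects of equal length.
#' @return similarity in \code{[0, 1]}.
#' @examples
#' fp <- morganFingerprint("CCO")
#' diceSimilarity(fp, fp)  # 1
#' @export
diceSimilarity <- function(fa, fb) {
  stopifnot(is(fa, "Fingerprint"), is(fb, "Fingerprint"))
  if (fa@nbits != fb@nbits) {
    stop("fingerprints have different lengths", call. = FALSE)
  }
  na <- length(fa@bits); nb <- length(fb@bits)
  if (na + nb == 0L) {
    warning("both fingerprints are empty; defining similarity as 0")
    return(0)
  }
  2 * length(intersect(fa@bits, fb@bits)) / (na + nb)
}

#' Diversity scores of a population
#'
#' For each molecule M, \eqn{d(M) = \sum_{N \ne M} s(F_M, F_N)}: the sum
#' of its pairwise Dice similarities to every other population member.
#' Small d means structurally unique; d ranges from 0 to n - 1.
#'
#' @param fps list of \linkS4class{Fingerprint} objects.
#' @return numeric vector of diversity scores, in input order.
#' @examples
#' fps <- lapply(c("CCO", "CCO", "c1ccccc1"), morganFingerprint)
#' diversityScores(fps)
#' @export
diversityScores <- function(fps) {
  n <- length(fps)
  if (n == 0L) return(numeric())
  d <- numeric(n)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- diceSimilarity(fps[[i]], fps[[j]])
      d[i] <- d[i] + s
      d[j] <- d[j] + s
    }
  }
  d
}

#' Ligand efficiency
#'
#' The primary score divided by the number of non-hydrogen atoms; the sign
#' is preserved, so more negative stays better under the docking-score
#' convention.
#'
#' @param primaryScore docking-convention score (lower = better).
#' @param heavyAtoms non-hydrogen atom count, at least 1.
#' @return the normalized score.
#' @export
ligandEfficiency <- function(primaryScore, heavyAtoms) {
  if (any(heavyAtoms < 1L)) {
    stop("heavyAtoms must be >= 1", call. = FALSE)
  }
  primaryScore / heavyAtoms
}

#' Deterministic surrogate fitness score
#'
#' A desk-scale stand-in for a docking score, defined exactly as
#' \code{-(0.1 * heavy_atoms + 1.0 * rings + 0.5 * (hbd + hba))}. It is a
#' test double with docking-score direction (lower = better), not a
#' binding-affinity predictor; it lets the whole evolutionary loop run
#' deterministically without a receptor.
#'
#' @param desc one row of [computeDescriptors()] output (or named
#'   list/vector with \code{heavy_atoms}, \code{rings}, \code{hbd},
#'   \code{hba}).
#' @return the surrogate score.
#' @examples
#' surrogateScore(computeDescriptors("c1ccccc1")[1, ])  # -1.6
#' @export
surrogateScore <- function(desc) {
  -(0.1 * as.numeric(desc[["heavy_atoms"]]) +
      1.0 * as.numeric(desc[["rings"]]) +
      0.5 * (as.numeric(desc[["hbd"]]) + as.numeric(desc[["hba"]])))
}

#' Resolve a fitness function by name
#'
#' The fitness contract: a function taking a character vector of SMILES
#' and returning a numeric vector of primary scores (lower = better),
#' with \code{NA} for per-molecule failures. \code{"surrogate"} resolves
#' to the deterministic surrogate scorer. \code{"nnscore1"} and
#' \code{"nnscore2"} are registered names for neural-network rescoring
#' contracts that this package does not implement; requesting them is an
#' error that says so. Docking through an external program is configured
#' with [dockingAdapter()].
#'
#' @param fitness a name or a function obeying the contract.
#' @return scoring function.
#' @export
fitnessFunction <- function(fitness = "surrogate") {
  if (is.function(fitness)) return(fitness)
  switch(fitness,
         surrogate = function(smiles) {
           desc <- computeDescriptors(smiles)
           vapply(seq_len(nrow(desc)), function(i) surrogateScore(desc[i, ]),
                  0)
         },
         nnscore1 = ,
         nnscore2 = stop("neural-network rescoring ('", fitness,
                         "') is a registered contract but is not ",
                         "implemented in this package", call. = FALSE),
         stop("unknown fitness function: ", fitness, call. = FALSE))
}

#' External docking adapter contract
#'
#' Builds a fitness function that delegates scoring to an external
#' executable. The adapter receives a batch TSV of \code{id<TAB>smiles} on
#' a temporary path, the receptor path, the docking-box center and size
#' (\enc{Å}{Angstrom}) and the exhaustiveness, and must write
#' \code{id<TAB>score} lines (top-pose score, kcal/mol) to the output
#' path. Vina-compatible wrappers (SMILES to PDBQT conversion, docking,
#' top-pose extraction) satisfy this contract; none is bundled.
#'
#' @param command path to the adapter executable.
#' @param receptor receptor file path handed to the adapter.
#' @param center,size numeric length-3 docking-box center and size.
#' @param exhaustiveness search effort forwarded to the adapter.
#' @return a fitness function obeying the [fitnessFunction()] contract.
#' @export
dockingAdapter <- function(command, receptor, center, size,
                           exhaustiveness = 8L) {
  stopifnot(length(center) == 3L, length(size) == 3L)
  force(command); force(receptor)
  function(smiles) {
    inFile <- tempfile(fileext = ".tsv"); outFile <- tempfile(fileext = ".tsv")
    ids <- paste0("m", seq_along(smiles))
    writeLines(paste(ids, smiles, sep = "\t"), inFile)
    status <- system2(command,
                      c(inFile, outFile, receptor,
                        paste(center, collapse = ","),
                        paste(size, collapse = ","),
                        as.character(exhaustiveness)))
    if (status != 0L) stop("docking adapter exited with status ", status,
                           call. = FALSE)
    tab <- utils::read.table(outFile, sep = "\t", header = FALSE,
                             col.names = c("id", "score"))
    tab$score[match(ids, tab$id)]
  }
}

#' Score a population
#'
#' Attaches the primary fitness score to every record (per-molecule scorer
#' failures get an infinite sentinel, are logged, and are excluded from
#' later seeding), computes diversity scores over the successfully scored
#' subset, and adds ligand efficiency when requested.
#'
#' @param records list of \linkS4class{MoleculeRecord}.
#' @param scorer a fitness function from [fitnessFunction()].
#' @param addLigandEfficiency attach \code{ligand_efficiency} scores.
#' @param fpRadius,fpBits Morgan fingerprint parameters for diversity.
#' @return the records, with \code{primary}, \code{diversity} and
#'   optionally \code{ligand_efficiency} entries in their score vectors.
#' @export
scorePopulation <- function(records, scorer = fitnessFunction("surrogate"),
                            addLigandEfficiency = TRUE,
                            fpRadius = 2L, fpBits = 2048L) {
  if (length(records) == 0L) return(records)
  smi <- vapply(records, function(r) r@smiles, "")
  primary <- scorer(smi)
  if (!is.numeric(primary) || length(primary) != length(records)) {
    stop("fitness contract violation: scorer must return one number per ",
         "molecule", call. = FALSE)
  }
  okIdx <- which(is.finite(primary))
  if (length(okIdx) < length(records)) {
    message(sprintf("scoring failed for %d molecule(s); sentinel applied",
                    length(records) - length(okIdx)))
  }
  fps <- lapply(smi[okIdx], morganFingerprint, radius = fpRadius,
                nbits = fpBits)
  dOk <- diversityScores(fps)
  for (i in seq_along(records)) {
    sc <- records[[i]]@scores
    sc[["primary"]] <- if (is.finite(primary[i])) primary[i] else Inf
    j <- match(i, okIdx)
    if (!is.na(j)) sc[["diversity"]] <- dOk[j]
    if (addLigandEfficiency && is.finite(primary[i])) {
      heavy <- .nAtoms(.parseSmiles(records[[i]]@smiles))
      sc[["ligand_efficiency"]] <- ligandEfficiency(primary[i], heavy)
    }
    records[[i]]@scores <- sc
  }
  records
}
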