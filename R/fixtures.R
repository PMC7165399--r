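# Synthetic seed libraries with known functional groups: a desk-scale
# stand-in for vendor-derived seed sets, so the whole evolutionary loop
# can be exercised without downloads.

.FIXTURE_CLASSES <- list(
  alcohol = list(
    query = "[OX2H][C;X4]",
    build = function(stem) paste0(stem, "O")),
  `carboxylic acid` = list(
    query = "[CX3](=O)[OX2H]",
    build = function(stem) paste0(stem, "C(=O)O")),
  `primary amine` = list(
    query = "[NX3;H2;!$(NC=O)]",
    build = function(stem) paste0(stem, "N")),
  azide = list(
    query = "[NX2]=[NX2+]=[NX1-]",
    build = function(stem) paste0(stem, "N=[N+]=[N-]")),
  `terminal alkyne` = list(
    query = "[CX2;H1]#[CX2]",
    build = function(stem) paste0(stem, "C#C")),
  `aryl halide` = list(
    query = "[c][Cl,Br,I]",
    build = function(stem) paste0(stem, "c1ccc(Br)cc1")))

# small aliphatic/aromatic stems; every generated molecule stays under
# 20 heavy atoms and passes the strict Lipinski* rule
.FIXTURE_STEMS <- c("C", "CC", "CCC", "CCCC", "CC(C)", "CCC(C)", "C1CCCCC1",
                    "CC1CCCCC1", "c1ccccc1C", "Cc1ccccc1C", "CCc1ccccc1C",
                    "C1CCCC1", "CC(C)C", "CCCCC", "c1ccccc1CC",
                    "COC", "COCC", "CCOC", "C1CCOC1C")

#' Generate a synthetic seed library with known functional groups
#'
#' Builds small (under 20 heavy atoms), valid, Lipinski*-passing molecules
#' guaranteed to carry the requested functional-group class, by combining
#' random aliphatic/aromatic stems with the class's group. Deterministic
#' under a fixed RNG seed. Supported classes: \code{alcohol},
#' \code{carboxylic acid}, \code{primary amine}, \code{azide},
#' \code{terminal alkyne}, \code{aryl halide} (underscores accepted in
#' place of spaces).
#'
#' @param spec named list/vector of per-class counts, e.g.
#'   \code{list(alcohol = 3, azide = 2)}.
#' @return character vector of distinct canonical SMILES.
#' @examples
#' set.seed(1)
#' generateFixtureLibrary(list(alcohol = 3))
#' @export
generateFixtureLibrary <- function(spec) {
  out <- character()
  for (cls in names(spec)) {
    key <- gsub("_", " ", cls)
    info <- .FIXTURE_CLASSES[[key]]
    if (is.null(info)) {
      stop("unknown functional-group class: '", cls, "'", call. = FALSE)
    }
    n <- as.integer(spec[[cls]])
    stopifnot(n >= 1L)
    made <- character()
    guard <- 0L
    pat <- .cachedSmarts(info$query)
    while (length(made) < n) {
      guard <- guard + 1L
      if (guard > 100L * n) {
        stop("could not generate ", n, " distinct '", key, "' molecules",
             call. = FALSE)
      }
      stem <- .FIXTURE_STEMS[sample.int(length(.FIXTURE_STEMS), 1L)]
      smi <- tryCatch(canonicalizeSmiles(info$build(stem)),
                      error = function(e) NULL)
      if (is.null(smi) || smi %in% made || smi %in% out) next
      ctx <- .molContext(.parseSmiles(smi))
      if (.nAtoms(ctx$mol) > 20L) next
      if (length(.matchSmarts(pat, ctx, maxMatches = 1L)) == 0L) next
      d <- computeDescriptors(smi)
      if (!evaluatePropertyFilter(d[1, ], propertyFilterSpec("Lipinski*"))$pass)
        next
      made <- c(made, smi)
    }
    out <- c(out, made)
  }
  out
}

#' Write a fixture seed library to an SMI file
#'
#' Convenience wrapper: generates a library with [generateFixtureLibrary()]
#' and writes it as an SMI file usable as [runConfig()] seed input.
#'
#' @param path output SMI path.
#' @param spec per-class counts, see [generateFixtureLibrary()].
#' @return \code{path}, invisibly.
#' @export
writeFixtureLibrary <- function(path, spec = list(alcohol = 4,
                                                  `carboxylic acid` = 4,
                                                  `primary amine` = 4,
                                                  azide = 4,
                                                  `terminal alkyne` = 4,
                                                  `aryl halide` = 4)) {
  smi <- generateFixtureLibrary(spec)
  writeLines(paste(smi, paste0("fx", seq_along(smi))), path)
  invisible(path)
}
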