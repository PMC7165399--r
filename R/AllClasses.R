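#' @import methods
NULL

#' MoleculeRecord: one candidate ligand in an evolutionary run
#'
#' A record ties a canonical SMILES to its identity and provenance inside a
#' genetic-algorithm run: the generation it was created in, the operator that
#' created it (\code{seed}, \code{elitism}, \code{mutation} or
#' \code{crossover}), the ids of its parents, the in silico reaction used
#' (mutation children only) and any scores attached so far (primary
#' docking-convention score, diversity score, ligand efficiency).
#'
#' Validity enforces the provenance contract: seeds have no parents,
#' elitism and mutation children exactly one, crossover children exactly two.
#'
#' @slot id unique identifier within a run.
#' @slot smiles canonical SMILES string.
#' @slot generation non-negative integer generation index.
#' @slot origin one of \code{"seed"}, \code{"elitism"}, \code{"mutation"},
#'   \code{"crossover"}.
#' @slot parentIds character vector of 0--2 parent ids.
#' @slot reactionName name of the reaction that produced a mutation child
#'   (with the complementary reactant appended after a colon when one was
#'   used); \code{NA} otherwise.
#' @slot scores named numeric vector of scores.
#' @exportClass MoleculeRecord
setClass("MoleculeRecord",
         representation(id = "character", smiles = "character",
                        generation = "integer", origin = "character",
                        parentIds = "character", reactionName = "character",
                        scores = "numeric"),
         prototype(reactionName = NA_character_, scores = numeric()))

setValidity("MoleculeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(object@smiles) != 1L || !nzchar(object@smiles))
    msg <- c(msg, "smiles must be a single non-empty string")
  if (length(object@generation) != 1L || is.na(object@generation) ||
      object@generation < 0L)
    msg <- c(msg, "generation must be a single non-negative integer")
  if (!(object@origin %in% c("seed", "elitism", "mutation", "crossover")))
    msg <- c(msg, "origin must be seed/elitism/mutation/crossover")
  np <- length(object@parentIds)
  want <- switch(object@origin, seed = 0L, elitism = 1L, mutation = 1L,
                 crossover = 2L, NA_integer_)
  if (!is.na(want) && np != want)
    msg <- c(msg, sprintf("origin '%s' requires %d parent id(s), got %d",
                          object@origin, want, np))
  if (object@origin == "mutation" && is.na(object@reactionName))
    msg <- c(msg, "mutation records must carry a reactionName")
  if (object@origin != "mutation" && !is.na(object@reactionName))
    msg <- c(msg, "reactionName is only set for mutation records")
  if (length(object@scores) > 0L && is.null(names(object@scores)))
    msg <- c(msg, "scores must be a named numeric vector")
  if (length(msg) > 0L) msg else TRUE
})

#' Construct a MoleculeRecord
#'
#' @param smiles SMILES string; canonicalized unless \code{canonicalize =
#'   FALSE} (only when the caller guarantees canonical input).
#' @param id identifier; unique within a run.
#' @param generation generation index, 0 for seeds.
#' @param origin provenance operator.
#' @param parentIds parent record ids (0 for seed, 1 for elitism/mutation,
#'   2 for crossover).
#' @param reactionName reaction label for mutation children.
#' @param scores named numeric vector of scores.
#' @param canonicalize whether to canonicalize \code{smiles}.
#' @return a \linkS4class{MoleculeRecord}.
#' @examples
#' moleculeRecord("OCC", id = "ethanol")
#' @export
moleculeRecord <- function(smiles, id, generation = 0L, origin = "seed",
                           parentIds = character(),
                           reactionName = NA_character_,
                           scores = numeric(), canonicalize = TRUE) {
  if (canonicalize) smiles <- canonicalizeSmiles(smiles)
  new("MoleculeRecord", id = as.character(id), smiles = smiles,
      generation = as.integer(generation), origin = origin,
      parentIds = as.character(parentIds),
      reactionName = as.character(reactionName), scores = scores)
}

setMethod("show", "MoleculeRecord", function(object) {
  cat(sprintf("MoleculeRecord %s [gen %d, %s]\n  %s\n", object@id,
              object@generation, object@origin, object@smiles))
  if (length(object@scores) > 0L) {
    cat("  scores:", paste(sprintf("%s=%.4g", names(object@scores),
                                   object@scores), collapse = ", "), "\n")
  }
})

#' @describeIn MoleculeRecord-accessors record identifier
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))
#' @describeIn MoleculeRecord-accessors canonical SMILES
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))
#' @describeIn MoleculeRecord-accessors generation index
#' @export
setGeneric("generation", function(x) standardGeneric("generation"))
#' @describeIn MoleculeRecord-accessors provenance operator
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @describeIn MoleculeRecord-accessors parent record ids
#' @export
setGeneric("parentIds", function(x) standardGeneric("parentIds"))
#' @describeIn MoleculeRecord-accessors named score vector
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Accessors for MoleculeRecord
#'
#' @param x a \linkS4class{MoleculeRecord}.
#' @name MoleculeRecord-accessors
NULL

#' @rdname MoleculeRecord-accessors
#' @export
setMethod("molId", "MoleculeRecord", function(x) x@id)
#' @rdname MoleculeRecord-accessors
#' @export
setMethod("smiles", "MoleculeRecord", function(x) x@smiles)
#' @rdname MoleculeRecord-accessors
#' @export
setMethod("generation", "MoleculeRecord", function(x) x@generation)
#' @rdname MoleculeRecord-accessors
#' @export
setMethod("origin", "MoleculeRecord", function(x) x@origin)
#' @rdname MoleculeRecord-accessors
#' @export
setMethod("parentIds", "MoleculeRecord", function(x) x@parentIds)
#' @rdname MoleculeRecord-accessors
#' @export
setMethod("scores", "MoleculeRecord", function(x) x@scores)

#' Fingerprint: circular substructure bit set
#'
#' The on-bit set of a folded Morgan (circular) fingerprint, the bit string
#' \eqn{F} used by the Dice similarity and the population diversity score.
#'
#' @slot bits sorted integer vector of on-bit indices in \code{[0, nbits)}.
#' @slot nbits fingerprint length (power of two).
#' @slot radius circular-neighborhood radius.
#' @exportClass Fingerprint
setClass("Fingerprint",
         representation(bits = "integer", nbits = "integer",
                        radius = "integer"))

setValidity("Fingerprint", function(object) {
  msg <- character()
  if (length(object@nbits) != 1L || object@nbits < 1L)
    msg <- c(msg, "nbits must be a positive integer")
  if (any(object@bits < 0L) || any(object@bits >= object@nbits))
    msg <- c(msg, "bit indices must lie in [0, nbits)")
  if (anyDuplicated(object@bits) > 0L)
    msg <- c(msg, "bit indices must be unique")
  if (length(msg) > 0L) msg else TRUE
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d/%d bits on (radius %d)\n",
              length(object@bits), object@nbits, object@radius))
})

#' ReactionSpec: one in silico chemical reaction
#'
#' A SMIRKS transform plus one substructure query per reactant slot that
#' identifies eligible reactants. Unimolecular reactions have one slot; the
#' bimolecular majority have two, one filled by the evolving parent and one
#' by a complementary-library reactant.
#'
#' @slot name unique reaction label.
#' @slot smirks reaction SMARTS (SMIRKS) string with atom maps.
#' @slot numReactants 1 or 2.
#' @slot slotQueries character vector (length \code{numReactants}) of SMARTS.
#' @slot sourceSet "AutoClickChemRxn" or "RobustRxn".
#' @slot exampleReactants optional example reactant SMILES for self-tests.
#' @exportClass ReactionSpec
setClass("ReactionSpec",
         representation(name = "character", smirks = "character",
                        numReactants = "integer", slotQueries = "character",
                        sourceSet = "character",
                        exampleReactants = "character"),
         prototype(exampleReactants = character()))

setValidity("ReactionSpec", function(object) {
  msg <- character()
  if (!(object@numReactants %in% c(1L, 2L)))
    msg <- c(msg, "numReactants must be 1 or 2")
  if (length(object@slotQueries) != object@numReactants)
    msg <- c(msg, "need one slot query per reactant")
  if (!(object@sourceSet %in% c("AutoClickChemRxn", "RobustRxn")))
    msg <- c(msg, "sourceSet must be AutoClickChemRxn or RobustRxn")
  if (length(msg) > 0L) msg else TRUE
})

#' ReactionLibrary: a named set of reactions
#'
#' @slot setName "AutoClickChemRxn", "RobustRxn", "AllRxn", or a custom name.
#' @slot reactions list of \linkS4class{ReactionSpec}.
#' @exportClass ReactionLibrary
setClass("ReactionLibrary",
         representation(setName = "character", reactions = "list"))

setValidity("ReactionLibrary", function(object) {
  msg <- character()
  if (!all(vapply(object@reactions, is, TRUE, "ReactionSpec")))
    msg <- c(msg, "reactions must all be ReactionSpec objects")
  nm <- vapply(object@reactions, function(r) r@name, "")
  if (anyDuplicated(nm) > 0L)
    msg <- c(msg, "reaction names must be unique within a library")
  if (length(msg) > 0L) msg else TRUE
})

setMethod("show", "ReactionLibrary", function(object) {
  nbi <- sum(vapply(object@reactions, function(r) r@numReactants, 0L) == 2L)
  cat(sprintf("ReactionLibrary '%s': %d reactions (%d bimolecular)\n",
              object@setName, length(object@reactions), nbi))
})

#' @describeIn ReactionLibrary-accessors number of reactions
#' @export
setMethod("length", "ReactionLibrary", function(x) length(x@reactions))

#' Accessors for ReactionLibrary
#' @param x a \linkS4class{ReactionLibrary}.
#' @name ReactionLibrary-accessors
NULL

#' @rdname ReactionLibrary-accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname ReactionLibrary-accessors
#' @export
setMethod("reactions", "ReactionLibrary", function(x) x@reactions)

#' ComplementaryLibrary: reactant pools per reaction slot
#'
#' Maps slot keys (\code{"<reaction name>#<slot index>"}) to the canonical
#' SMILES eligible to fill that slot during bimolecular mutation.
#'
#' @slot groups named list of character vectors of canonical SMILES.
#' @exportClass ComplementaryLibrary
setClass("ComplementaryLibrary", representation(groups = "list"))

setMethod("show", "ComplementaryLibrary", function(object) {
  cat(sprintf("ComplementaryLibrary: %d slot groups, %d molecule entries\n",
              length(object@groups),
              sum(vapply(object@groups, length, 0L))))
})

#' SeedPools: the three per-generation seed selections
#'
#' The elitism, mutation and crossover operators each draw from their own
#' pool, selected from the scored previous generation by primary score and
#' by diversity score.
#'
#' @slot elitism,mutation,crossover lists of \linkS4class{MoleculeRecord}.
#' @exportClass SeedPools
setClass("SeedPools",
         representation(elitism = "list", mutation = "list",
                        crossover = "list"))

setMethod("show", "SeedPools", function(object) {
  cat(sprintf("SeedPools: elitism %d, mutation %d, crossover %d\n",
              length(object@elitism), length(object@mutation),
              length(object@crossover)))
})
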