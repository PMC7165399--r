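# Molecular filtration: the nine predefined drug-likeness filters applied
# singly or chained, plus the registry used by the evolution engine.

#' PropertyFilter: descriptor-bound drug-likeness rule
#'
#' Bounds are encoded as data: one row per (descriptor, lower, upper,
#' strict) with an allowed number of violations. Non-strict bounds pass on
#' equality; strict bounds (Van de Waterbeemd's "< 450", "< 90") do not.
#'
#' @slot name filter name.
#' @slot bounds data.frame with columns descriptor, lower, upper, strict.
#' @slot maxViolations violations allowed before the molecule fails.
#' @exportClass PropertyFilter
setClass("PropertyFilter",
         representation(name = "character", bounds = "data.frame",
                        maxViolations = "integer"))

setValidity("PropertyFilter", function(object) {
  b <- object@bounds
  msg <- character()
  if (!all(c("descriptor", "lower", "upper", "strict") %in% colnames(b)))
    msg <- c(msg, "bounds needs descriptor/lower/upper/strict columns")
  else {
    if (!all(b$descriptor %in% .DESCRIPTOR_NAMES))
      msg <- c(msg, "unknown descriptor name in bounds")
    both <- !is.na(b$lower) & !is.na(b$upper)
    if (any(both & b$lower > b$upper))
      msg <- c(msg, "lower bound exceeds upper bound")
  }
  if (object@maxViolations < 0L) msg <- c(msg, "maxViolations must be >= 0")
  if (length(msg) > 0L) msg else TRUE
})

#' SubstructureFilter: a catalog of structural alerts
#'
#' A molecule fails when any catalog SMARTS occurs as a substructure.
#'
#' @slot name catalog name (BRENK, NIH, PAINS, or custom).
#' @slot patterns character vector of SMARTS.
#' @slot labels character vector of per-pattern labels.
#' @exportClass SubstructureFilter
setClass("SubstructureFilter",
         representation(name = "character", patterns = "character",
                        labels = "character"))

setValidity("SubstructureFilter", function(object) {
  if (length(object@patterns) != length(object@labels))
    return("patterns and labels must be parallel vectors")
  TRUE
})

setMethod("show", "PropertyFilter", function(object) {
  cat(sprintf("PropertyFilter '%s' (%d bounds, %d violation(s) allowed)\n",
              object@name, nrow(object@bounds), object@maxViolations))
})

setMethod("show", "SubstructureFilter", function(object) {
  cat(sprintf("SubstructureFilter '%s' (%d alert patterns)\n",
              object@name, length(object@patterns)))
})

.bounds <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(descriptor = r[[1]],
               lower = as.numeric(r[[2]]), upper = as.numeric(r[[3]]),
               strict = length(r) >= 4 && isTRUE(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

#' Construct one of the predefined property-filter rules
#'
#' Available rules: \code{Lipinski} (logP <= 5, HBD <= 5, HBA <= 10,
#' MW <= 500 Da; one violation allowed), \code{Lipinski*} (same bounds, no
#' violations), \code{Ghose} (logP -0.4..5.6, MW 160..480, MR 40..130,
#' 20..70 atoms), \code{Ghose*} (as Ghose with MW up to 500),
#' \code{VandeWaterbeemd} (MW < 450, PSA < 90, strict), and
#' \code{Mozziconacci} (<= 15 rotatable bonds, <= 6 rings, >= 1 N, >= 1 O,
#' <= 7 halogens).
#'
#' @param name one of the rule names above.
#' @return a \linkS4class{PropertyFilter}.
#' @export
propertyFilterSpec <- function(name) {
  lip <- .bounds(list("logp", NA, 5.0), list("hbd", NA, 5),
                 list("hba", NA, 10), list("mw", NA, 500))
  spec <- switch(name,
    "Lipinski" = list(lip, 1L),
    "Lipinski*" = list(lip, 0L),
    "Ghose" = list(.bounds(list("logp", -0.4, 5.6), list("mw", 160, 480),
                           list("mr", 40, 130), list("n_atoms", 20, 70)),
                   0L),
    "Ghose*" = list(.bounds(list("logp", -0.4, 5.6), list("mw", 160, 500),
                            list("mr", 40, 130), list("n_atoms", 20, 70)),
                    0L),
    "VandeWaterbeemd" = list(.bounds(list("mw", NA, 450, TRUE),
                                     list("psa", NA, 90, TRUE)), 0L),
    "Mozziconacci" = list(.bounds(list("rotb", NA, 15), list("rings", NA, 6),
                                  list("n_count", 1, NA),
                                  list("o_count", 1, NA),
                                  list("x_count", NA, 7)), 0L),
    stop("unknown property filter: ", name, call. = FALSE))
  new("PropertyFilter", name = name, bounds = spec[[1]],
      maxViolations = spec[[2]])
}

#' Evaluate a property filter on a descriptor set
#'
#' A bound is violated when the descriptor falls strictly outside
#' \code{[lower, upper]} (boundary values pass); strict bounds exclude the
#' boundary. The molecule passes when the number of violated bounds does
#' not exceed the filter's allowance. Violations are counted per bound:
#' a molecule over the weight and logP limits accrues two.
#'
#' @param desc one row of [computeDescriptors()] output (or any named
#'   list/vector carrying the referenced descriptors).
#' @param spec a \linkS4class{PropertyFilter}.
#' @return \code{list(pass = logical, violations = character)} where
#'   violations names the offending descriptors.
#' @export
evaluatePropertyFilter <- function(desc, spec) {
  stopifnot(is(spec, "PropertyFilter"))
  viol <- character()
  for (i in seq_len(nrow(spec@bounds))) {
    b <- spec@bounds[i, ]
    if (!(b$descriptor %in% names(desc)) ||
        is.na(suppressWarnings(as.numeric(desc[[b$descriptor]])))) {
      stop("descriptor '", b$descriptor, "' missing from input",
           call. = FALSE)
    }
    x <- as.numeric(desc[[b$descriptor]])
    bad <- FALSE
    if (!is.na(b$lower)) bad <- bad || if (b$strict) x <= b$lower else x < b$lower
    if (!is.na(b$upper)) bad <- bad || if (b$strict) x >= b$upper else x > b$upper
    if (bad) viol <- c(viol, b$descriptor)
  }
  list(pass = length(viol) <= spec@maxViolations, violations = viol)
}

#' Load a structural-alert catalog
#'
#' Bundled catalogs: \code{BRENK} (105 alerts for reactive, toxic or
#' pharmacokinetically unfavourable groups), \code{NIH} (180 problematic
#' functional groups from screening-deck curation) and \code{PAINS} (480
#' pan-assay interference patterns). Catalog files are plain text, one
#' \code{SMARTS<TAB>label} per line with provenance in \code{#} headers;
#' a custom file in the same format can be given as a path.
#'
#' Every pattern is syntax-checked at load time; an unparsable pattern
#' fails the load, not individual molecules later.
#'
#' @param name \code{"BRENK"}, \code{"NIH"}, \code{"PAINS"}, or a file path.
#' @return a \linkS4class{SubstructureFilter}.
#' @export
loadAlertCatalog <- function(name) {
  path <- switch(name,
                 BRENK = system.file("extdata", "alerts_brenk.tsv",
                                     package = "evoligand", mustWork = TRUE),
                 NIH = system.file("extdata", "alerts_nih.tsv",
                                   package = "evoligand", mustWork = TRUE),
                 PAINS = system.file("extdata", "alerts_pains.tsv",
                                     package = "evoligand", mustWork = TRUE),
                 name)
  if (!file.exists(path)) stop("catalog not found: ", name, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  pat <- vapply(parts, `[`, "", 1)
  lab <- vapply(parts, function(p) if (length(p) > 1L) p[2] else p[1], "")
  if (length(pat) == 0L) stop("catalog '", name, "' is empty", call. = FALSE)
  # fail fast on unparsable patterns (checked component-wise, since
  # disconnected alerts are matched per component)
  probe <- ChemmineOB::forEachMol("SMILES", "C probe", function(m) {
    for (i in seq_along(pat)) {
      for (comp in .splitTopLevel(pat[i])) {
        ok <- tryCatch({
          suppressWarnings(ChemmineOB::smartsSearch_OB(list(m), comp))
          TRUE
        }, error = function(e) FALSE)
        if (!ok) stop("catalog '", name, "': unparsable SMARTS for alert '",
                      lab[i], "'", call. = FALSE)
      }
    }
    TRUE
  })
  new("SubstructureFilter",
      name = if (name %in% c("BRENK", "NIH", "PAINS")) name else "custom",
      patterns = pat, labels = lab)
}

#' Screen a molecule against a structural-alert catalog
#'
#' The molecule passes when no catalog pattern occurs as a substructure.
#' Disconnected (dot-separated) alert patterns match when every distinct
#' component is present at least as often as its multiplicity.
#'
#' @param smiles a single canonical SMILES.
#' @param catalog a \linkS4class{SubstructureFilter}.
#' @return \code{list(pass = logical, matched = character)} with the labels
#'   of every alert found.
#' @export
evaluateSubstructureFilter <- function(smiles, catalog) {
  stopifnot(is(catalog, "SubstructureFilter"))
  if (length(catalog@patterns) == 0L) {
    return(list(pass = TRUE, matched = character()))
  }
  pats <- catalog@patterns
  hits <- ChemmineOB::forEachMol("SMILES", paste(smiles, "m"), function(m) {
    vapply(pats, function(p) {
      comps <- .splitTopLevel(p)
      tab <- table(comps)
      all(vapply(names(tab), function(cp) {
        cnt <- tryCatch(
          suppressWarnings(ChemmineOB::smartsSearch_OB(list(m), cp)),
          error = function(e) 0L)
        as.integer(cnt) >= tab[[cp]]
      }, TRUE))
    }, TRUE)
  })[[1]]
  list(pass = !any(hits), matched = unname(catalog@labels[hits]))
}

# --- registry and chains ---------------------------------------------------

.filterRegistry <- new.env(parent = emptyenv())

.registryInit <- function() {
  if (length(ls(.filterRegistry)) > 0L) return(invisible())
  for (nm in c("Lipinski", "Lipinski*", "Ghose", "Ghose*",
               "VandeWaterbeemd", "Mozziconacci")) {
    assign(nm, propertyFilterSpec(nm), envir = .filterRegistry)
  }
  for (nm in c("BRENK", "NIH", "PAINS")) {
    # catalogs load lazily: a promise-like closure avoids paying the parse
    # cost unless the catalog is used
    assign(nm, local({
      nm2 <- nm
      function() loadAlertCatalog(nm2)
    }), envir = .filterRegistry)
  }
  invisible()
}

#' Names of the registered molecular filters
#'
#' The nine predefined filters are registered by default; custom filters
#' added through [registerFilter()] appear as well.
#'
#' @return character vector of filter names.
#' @examples
#' registeredFilters()
#' @export
registeredFilters <- function() {
  .registryInit()
  sort(ls(.filterRegistry))
}

#' Register a custom molecular filter
#'
#' A custom filter is either a \linkS4class{PropertyFilter}, a
#' \linkS4class{SubstructureFilter}, or a predicate
#' \code{function(desc, smiles)} returning \code{TRUE} to keep the
#' molecule -- the same pass contract the predefined filters follow.
#'
#' @param name filter name used in chains.
#' @param filter the filter object or predicate function.
#' @return \code{name}, invisibly.
#' @export
registerFilter <- function(name, filter) {
  .registryInit()
  if (!(is(filter, "PropertyFilter") || is(filter, "SubstructureFilter") ||
        is.function(filter))) {
    stop("filter must be a PropertyFilter, SubstructureFilter or function",
         call. = FALSE)
  }
  assign(name, filter, envir = .filterRegistry)
  invisible(name)
}

.resolveFilter <- function(name) {
  .registryInit()
  if (!exists(name, envir = .filterRegistry, inherits = FALSE)) {
    stop("unknown filter name: '", name, "'", call. = FALSE)
  }
  f <- get(name, envir = .filterRegistry)
  if (is.function(f) && !is(f, "PropertyFilter") &&
      name %in% c("BRENK", "NIH", "PAINS")) {
    f <- f()  # materialize lazy catalog
    assign(name, f, envir = .filterRegistry)
  }
  f
}

# evaluate one registered filter for one molecule
.passesFilter <- function(filter, desc, smiles) {
  if (is(filter, "PropertyFilter")) {
    evaluatePropertyFilter(desc, filter)$pass
  } else if (is(filter, "SubstructureFilter")) {
    evaluateSubstructureFilter(smiles, filter)$pass
  } else {
    isTRUE(filter(desc, smiles))
  }
}

#' Apply a chain of filters to a population
#'
#' AND semantics: a molecule survives only if it passes every filter in
#' the chain. Evaluation short-circuits in chain order, and each rejected
#' molecule is attributed to the first filter that rejected it. Unknown
#' filter names raise a configuration error before anything is evaluated.
#'
#' @param records list of \linkS4class{MoleculeRecord}.
#' @param chain character vector of registered filter names (may be empty).
#' @return \code{list(survivors = list, rejections = named integer)} with
#'   input order preserved among survivors.
#' @export
applyFilterChain <- function(records, chain) {
  filters <- lapply(chain, .resolveFilter)
  rejections <- stats::setNames(integer(length(chain)), chain)
  if (length(records) == 0L || length(chain) == 0L) {
    return(list(survivors = records, rejections = rejections))
  }
  needDesc <- any(vapply(filters, function(f) is(f, "PropertyFilter") ||
                           is.function(f), TRUE))
  desc <- if (needDesc) {
    computeDescriptors(vapply(records, function(r) r@smiles, ""))
  } else NULL
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    d <- if (!is.null(desc)) desc[i, ] else NULL
    ok <- TRUE
    for (j in seq_along(filters)) {
      if (!.passesFilter(filters[[j]], d, records[[i]]@smiles)) {
        rejections[[chain[j]]] <- rejections[[chain[j]]] + 1L
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  list(survivors = records[keep], rejections = rejections)
}
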