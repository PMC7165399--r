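# BRICS fragmentation: retrosynthetically motivated bond cleavage used to
# prepare lead-optimization seed libraries from known ligands.

# Link-atom environments (Degen et al. bond classes, expressed in the
# package's SMARTS subset; dummy-atom alternatives are dropped because
# fragments here terminate in hydrogens, not attachment dummies).
.BRICS_ENV <- c(
  L1 = "[C;D3]([#6,#7,#8])(=O)",
  L3 = "[O;D2;$(O-;!@[#6])]",
  L4 = "[C;!D1;!$(C=*);$(C-;!@[#6])]",
  L5 = "[N;!D1;!$(N=*);!$(N-[!#6;!#16])]",
  L6 = "[C;D3;!R](=O)",
  L7 = "[C;D2,D3]",
  L8 = "[C;!R;!D1;!$(C!-*)]",
  L9 = "[n;+0;$(n(:[c,n,o,s]):[c,n,o,s])]",
  L10 = "[N;R;$(N(@C(=O))@[C,N,O,S])]",
  L11 = "[S;D2;$(S-;!@[#6])]",
  L12 = "[S;D4]([#6])(=O)(=O)",
  L13 = "[C;$(C(-;@[C,N,O,S])-;@[N,O,S])]",
  L14 = "[c;$(c(:[c,n,o,s]):[n,o,s])]",
  L15 = "[C;$(C(-;@C)-;@C)]",
  L16 = "[c;$(c(:c):c)]")

# cleavable environment pairs; all are acyclic single bonds except the
# L7-L7 olefin which is an acyclic double bond
.BRICS_PAIRS <- rbind(
  c("L1", "L3", 1L), c("L1", "L5", 1L), c("L1", "L10", 1L),
  c("L3", "L4", 1L), c("L3", "L13", 1L), c("L3", "L14", 1L),
  c("L3", "L15", 1L), c("L3", "L16", 1L),
  c("L4", "L5", 1L), c("L4", "L11", 1L),
  c("L5", "L12", 1L), c("L5", "L14", 1L), c("L5", "L16", 1L),
  c("L5", "L13", 1L), c("L5", "L15", 1L),
  c("L6", "L13", 1L), c("L6", "L14", 1L), c("L6", "L15", 1L),
  c("L6", "L16", 1L),
  c("L7", "L7", 2L),
  c("L8", "L9", 1L), c("L8", "L10", 1L), c("L8", "L13", 1L),
  c("L8", "L14", 1L), c("L8", "L15", 1L), c("L8", "L16", 1L),
  c("L9", "L13", 1L), c("L9", "L14", 1L), c("L9", "L15", 1L),
  c("L9", "L16", 1L),
  c("L10", "L13", 1L), c("L10", "L14", 1L), c("L10", "L15", 1L),
  c("L10", "L16", 1L),
  c("L11", "L13", 1L), c("L11", "L14", 1L), c("L11", "L15", 1L),
  c("L11", "L16", 1L),
  c("L13", "L14", 1L), c("L13", "L15", 1L), c("L13", "L16", 1L),
  c("L14", "L14", 1L), c("L14", "L15", 1L), c("L14", "L16", 1L),
  c("L15", "L16", 1L),
  c("L16", "L16", 1L))

# atoms (per environment class) that match anchored at each position
.bricsEnvHits <- function(ctx) {
  out <- list()
  for (nm in names(.BRICS_ENV)) {
    pat <- .cachedSmarts(.BRICS_ENV[[nm]])
    hit <- vapply(seq_len(.nAtoms(ctx$mol)), function(i) {
      length(.matchSmarts(pat, ctx, anchor = i, maxMatches = 1L)) > 0L
    }, TRUE)
    out[[nm]] <- hit
  }
  out
}

# rows of mol$bond that are BRICS-cleavable
.bricsBonds <- function(mol) {
  ctx <- .molContext(mol)
  if (nrow(mol$bond) == 0L) return(integer())
  hits <- .bricsEnvHits(ctx)
  cleave <- integer()
  for (k in seq_len(nrow(mol$bond))) {
    if (ctx$ringBond[k] || mol$baro[k]) next
    ord <- mol$bond[k, "order"]
    ia <- mol$bond[k, "a"]; ib <- mol$bond[k, "b"]
    for (p in seq_len(nrow(.BRICS_PAIRS))) {
      if (ord != as.integer(.BRICS_PAIRS[p, 3])) next
      ea <- .BRICS_PAIRS[p, 1]; eb <- .BRICS_PAIRS[p, 2]
      if ((hits[[ea]][ia] && hits[[eb]][ib]) ||
          (hits[[ea]][ib] && hits[[eb]][ia])) {
        cleave <- c(cleave, k)
        break
      }
    }
  }
  cleave
}

#' BRICS fragmentation of a molecule set
#'
#' Cleaves every bond whose two ends match a retrosynthetically
#' interesting environment pair (the BRICS bond classes) and returns the
#' resulting fragments, with attachment points capped by hydrogens and
#' duplicates removed by canonical SMILES. Molecules with no cleavable
#' bond contribute nothing by default (or themselves with
#' \code{keepUncleaved}).
#'
#' @param smilesList character vector of SMILES.
#' @param keepUncleaved include molecules that have no cleavable bond.
#' @return character vector of canonical fragment SMILES.
#' @examples
#' bricsFragment("c1ccccc1")                      # no cleavable bond
#' bricsFragment("CC(=O)Nc1ccccc1")               # amide split
#' @export
bricsFragment <- function(smilesList, keepUncleaved = FALSE) {
  out <- character()
  for (s in smilesList) {
    mol <- tryCatch(.parseSmiles(canonicalizeSmiles(s)),
                    error = function(e) NULL)
    if (is.null(mol)) {
      message("bricsFragment: skipping unparsable SMILES '", s, "'")
      next
    }
    cut <- .bricsBonds(mol)
    if (length(cut) == 0L) {
      if (keepUncleaved) out <- c(out, canonicalizeSmiles(s))
      next
    }
    frag <- mol
    keep <- setdiff(seq_len(nrow(mol$bond)), cut)
    frag$bond <- mol$bond[keep, , drop = FALSE]
    frag$baro <- mol$baro[keep]
    # hydrogens re-grow at the cut positions
    bs <- .bondOrderSum(frag)
    for (i in seq_len(.nAtoms(frag))) {
      if (!frag$hfixed[i]) {
        frag$hcount[i] <- .defaultHcount(frag$elem[i], frag$arom[i], bs[i])
      }
    }
    for (fr in .fragments(frag)) {
      sub <- .subMol(frag, fr)
      smi <- tryCatch(canonicalizeSmiles(.writeSmiles(sub)),
                      error = function(e) NULL)
      if (!is.null(smi)) out <- c(out, smi)
    }
  }
  unique(out)
}
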