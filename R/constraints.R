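#' @include AllClasses.R AllGenerics.R structure-io.R gnm.R
NULL

#' Split residues into two lobes along the hinge
#'
#' Each maximal contiguous run of non-hinge residues becomes a segment;
#' segments with positive mean mode-1 component go to lobe A, negative to
#' lobe B, and a segment with mean exactly zero inherits the lobe of the
#' preceding segment (lobe A if it is the first).
#'
#' @param mode1 per-residue mode-1 eigenvector components
#' @param hinges a [HingeSet] (or integer vector of hinge indices)
#' @return a [LobePartition]
#' @export
splitLobes <- function(mode1, hinges) {
  hres <- if (is(hinges, "HingeSet")) hinges@residues else as.integer(hinges)
  n <- length(mode1)
  if (length(hres) == 0L)
    warning("empty hinge set: treating the protein as a single lobe")
  isH <- seq_len(n) %in% hres
  seg <- cumsum(c(TRUE, diff(!isH) != 0 | FALSE))  # run ids over all residues
  lobeA <- integer(0); lobeB <- integer(0)
  lastLobe <- "A"
  for (s in unique(seg)) {
    idx <- which(seg == s)
    if (isH[idx[1]]) next
    m <- mean(mode1[idx])
    lobe <- if (m > 0) "A" else if (m < 0) "B" else lastLobe
    if (lobe == "A") lobeA <- c(lobeA, idx) else lobeB <- c(lobeB, idx)
    lastLobe <- lobe
  }
  new("LobePartition", lobeA = as.integer(lobeA), lobeB = as.integer(lobeB),
      hinge = as.integer(sort(intersect(hres, seq_len(n)))))
}

setMethod("show", "LobePartition", function(object) {
  cat("LobePartition: lobe A", length(object@lobeA), "res; lobe B",
      length(object@lobeB), "res; hinge", length(object@hinge), "res\n")
})

## internal: heavy atoms of the protein residues of one state, annotated with
## the open-state internal index. For the closed state, residues are looked
## up through the pair mapping; unmapped residues are skipped.
.heavyAtomsByOpenIdx <- function(pair, state = c("open", "closed")) {
  state <- match.arg(state)
  s <- if (state == "open") pair@open else pair@closed
  a <- s@atoms[!s@atoms$is_ligand & s@atoms$element != "H", , drop = FALSE]
  if (state == "open") {
    a$open_idx <- a$res_id
  } else {
    m <- pair@mapping
    a$open_idx <- m$open_idx[match(a$res_id, m$closed_idx)]
    a <- a[!is.na(a$open_idx), , drop = FALSE]
  }
  a
}

## internal: minimum-distance based membership: which residues (by open_idx
## group) have any atom within cutoff of any atom of `other`?
.withinCutoff <- function(atoms, other, cutoff) {
  if (nrow(atoms) == 0L || nrow(other) == 0L) return(integer(0))
  A <- as.matrix(atoms[, c("x", "y", "z")])
  B <- as.matrix(other[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  hit <- rowSums(d2 <= cutoff^2 + 1e-12) > 0
  sort(unique(atoms$open_idx[hit]))
}

#' Lobe-interface residues
#'
#' A residue is interfacial if any of its heavy atoms lies within
#' \code{cutoff} of any heavy atom of any residue of the opposite lobe. The
#' conformational state the distances are measured in is selectable; the
#' default takes the union over both states, which conservatively fixes
#' anything interfacial in either conformation.
#'
#' @param pair a [StructurePair]
#' @param partition a [LobePartition] in open-state internal indices
#' @param cutoff distance cutoff in Angstrom (default 6)
#' @param state "open", "closed", or "union" (default)
#' @return sorted integer vector of open-state author residue numbers
#' @export
interfaceResidues <- function(pair, partition, cutoff = 6,
                              state = c("union", "open", "closed")) {
  state <- match.arg(state)
  states <- if (state == "union") c("open", "closed") else state
  idx <- integer(0)
  for (st in states) {
    at <- .heavyAtomsByOpenIdx(pair, st)
    aA <- at[at$open_idx %in% partition@lobeA, , drop = FALSE]
    aB <- at[at$open_idx %in% partition@lobeB, , drop = FALSE]
    idx <- union(idx, c(.withinCutoff(aA, aB, cutoff),
                        .withinCutoff(aB, aA, cutoff)))
  }
  sort(.resnoOfIndex(pair, sort(idx)))
}

#' Binding-pocket residues around the closed-state ligands
#'
#' Residues of the closed structure with any heavy atom within \code{cutoff}
#' of any ligand heavy atom, reported in open-state author numbering via the
#' pair mapping. These positions are held fixed in every design tier so that
#' ligand interactions stay intact.
#'
#' @param pair a [StructurePair] whose closed state carries the ligand(s)
#' @param cutoff distance cutoff in Angstrom (default 6)
#' @return sorted integer vector of open-state author residue numbers;
#'   empty (with a warning) if the closed state has no ligand
#' @export
pocketResidues <- function(pair, cutoff = 6) {
  lig <- pair@closedLigands
  lig <- lig[lig$element != "H", , drop = FALSE]
  if (nrow(lig) == 0L) {
    warning("closed state has no ligand: empty binding pocket")
    return(integer(0))
  }
  if (cutoff <= 0) return(integer(0))
  at <- .heavyAtomsByOpenIdx(pair, "closed")
  idx <- .withinCutoff(at, lig, cutoff)
  sort(.resnoOfIndex(pair, idx))
}

#' Terminal-margin positions
#'
#' The first and last \code{margin} protein positions, which are excluded
#' from design because mutations too close to the termini are poorly
#' constrained.
#'
#' @param n number of protein residues
#' @param margin margin width in residues (default 5)
#' @return integer vector of 1-based positions (empty if margin = 0)
#' @export
terminalMargin <- function(n, margin = 5) {
  if (margin < 0) stop("margin must be >= 0")
  if (margin == 0) return(integer(0))
  if (2 * margin >= n)
    stop("terminal margins (2 x ", margin, ") would cover the whole protein (N = ", n, ")")
  c(seq_len(margin), (n - margin + 1L):n)
}

#' Assemble the fixed-position set of a design tier
#'
#' Tiers X.1-X.3 fix the binding pocket and the terminal margins; tier X.4
#' additionally fixes the hinge region and the lobe interface. A position may
#' carry several provenance tags.
#'
#' @param tier one of "X.1", "X.2", "X.3", "X.4"
#' @param pocket,hinge,interface,terminal integer vectors of open-state
#'   author residue numbers
#' @return a [FixedPositionSet]
#' @export
assembleFixedSet <- function(tier, pocket = integer(0), hinge = integer(0),
                             interface = integer(0), terminal = integer(0)) {
  tier <- match.arg(tier, c("X.1", "X.2", "X.3", "X.4"))
  tagged <- list(pocket = pocket, terminus = terminal)
  if (tier == "X.4")
    tagged <- c(tagged, list(hinge = hinge, interface = interface))
  pos <- sort(unique(as.integer(unlist(tagged))))
  prov <- lapply(pos, function(p)
    sort(names(tagged)[vapply(tagged, function(v) p %in% v, logical(1))]))
  names(prov) <- as.character(pos)
  new("FixedPositionSet", positions = pos, provenance = prov, tier = tier)
}

#' @describeIn assembleFixedSet positions of a FixedPositionSet
#' @param x a FixedPositionSet
#' @export
setMethod("fixedPositions", "FixedPositionSet", function(x) x@positions)

setMethod("show", "FixedPositionSet", function(object) {
  tags <- table(unlist(object@provenance))
  cat("FixedPositionSet [", object@tier, "]: ", length(object@positions),
      " position(s); tags: ",
      paste(names(tags), tags, sep = "=", collapse = ", "), "\n", sep = "")
})
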