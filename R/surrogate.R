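#' @include AllClasses.R AllGenerics.R structure-io.R
NULL

#' Surrogate stability-model parameters
#'
#' The surrogate replaces an external atomistic energy calculator for
#' testing and demonstration. It is deliberately naive but monotone and
#' fully explainable: the stability change of a substitution is the burial
#' of the site times the hydropathy lost, plus a flat penalty for placing a
#' strongly hydrophobic identity at an exposed site. Because burial is
#' evaluated per conformational state, sites that are buried in only one
#' state naturally produce state-dependent, sign-discordant energies.
#'
#' @param contactRadius C-beta neighbour radius in Angstrom (default 8)
#' @param hydrophobicity named scale over the 20 amino acids (default
#'   Kyte-Doolittle)
#' @param burialWeight energy per neighbour per hydropathy unit (default
#'   0.04, placing typical single-substitution energies inside the design
#'   cutoff ladder)
#' @param exposurePenalty penalty for hydrophobic identities at exposed
#'   sites (default 1.2; 0 disables)
#' @param exposedBurial neighbour count below which a site is exposed
#'   (default 7, the lower quartile of C-beta neighbour counts in compact
#'   folds at the default radius)
#' @return a [ContactModel]
#' @export
contactModel <- function(contactRadius = 8, hydrophobicity = .KD_HYDROPATHY,
                         burialWeight = 0.04, exposurePenalty = 1.2,
                         exposedBurial = 7) {
  new("ContactModel", contactRadius = contactRadius,
      hydrophobicity = hydrophobicity, burialWeight = burialWeight,
      exposurePenalty = exposurePenalty, exposedBurial = exposedBurial)
}

## internal: side-chain anchor coordinates (CB, else CA) per protein residue
.anchorCoords <- function(s) {
  a <- s@atoms[!s@atoms$is_ligand, , drop = FALSE]
  ids <- unique(a$res_id)
  m <- matrix(NA_real_, length(ids), 3)
  for (i in seq_along(ids)) {
    sub <- a[a$res_id == ids[i], , drop = FALSE]
    row <- sub[sub$elety == "CB", , drop = FALSE]
    if (!nrow(row)) row <- sub[sub$elety == "CA", , drop = FALSE]
    m[i, ] <- as.numeric(row[1, c("x", "y", "z")])
  }
  m
}

## internal: burial (neighbour count) per residue in one state, indexed by
## the state's own residue order
.burialCounts <- function(s, radius) {
  m <- .anchorCoords(s)
  D <- as.matrix(stats::dist(m))
  rowSums(D <= radius) - 1L
}

#' Surrogate ddG of candidate substitutions in both states
#'
#' Per state, \code{ddg = burialWeight * b * (h(wt) - h(mut)) + penalty},
#' where b is the number of C-beta neighbours of the site within the contact
#' radius and the penalty applies to strongly hydrophobic mutant identities
#' (h > 2) at exposed sites (b below the exposure threshold). Deterministic
#' and geometry-only.
#'
#' @param pair a [StructurePair]
#' @param position open-state author residue number(s)
#' @param wt,mut one-letter identities (vectorized with position)
#' @param model a [ContactModel]
#' @return data.frame(position, wt, mut, ddg_open, ddg_closed)
#' @export
surrogateDdg <- function(pair, position, wt, mut, model = contactModel()) {
  stopifnot(is(pair, "StructurePair"), is(model, "ContactModel"))
  if (any(wt == mut)) stop("wt and mut identities must differ")
  mp <- pair@mapping
  openIdx <- .indexOfResno(pair, position)
  row <- match(openIdx, mp$open_idx)
  if (anyNA(row))
    stop("position ", position[which(is.na(row))[1]],
         " is not mapped in both states")
  bOpen <- .burialCounts(pair@open, model@contactRadius)
  bClosed <- .burialCounts(pair@closed, model@contactRadius)
  h <- model@hydrophobicity
  dh <- h[wt] - h[mut]
  ddgFor <- function(b) {
    pen <- model@exposurePenalty * (h[mut] > 2 & b < model@exposedBurial)
    unname(model@burialWeight * b * dh + pen)
  }
  data.frame(position = position, wt = wt, mut = mut,
             ddg_open = ddgFor(bOpen[mp$open_idx[row]]),
             ddg_closed = ddgFor(bClosed[mp$closed_idx[row]]),
             stringsAsFactors = FALSE)
}

#' Scan all allowed single substitutions with the surrogate model
#'
#' Emits one ddG table per state in the standard dialect (position, wt, mut,
#' ddg), covering every mapped position and every identity in the allowed
#' alphabet (all 19 alternatives when no alphabet is supplied).
#'
#' @param pair a [StructurePair]
#' @param allowed named list from [allowedIdentities()] (names = sequence
#'   positions), or NULL for the full alphabet
#' @param model a [ContactModel]
#' @return list(open = data.frame, closed = data.frame)
#' @export
scanDdg <- function(pair, allowed = NULL, model = contactModel()) {
  seqv <- strsplit(pair@sequence, "")[[1]]
  mp <- pair@mapping
  rows <- list()
  for (k in seq_len(nrow(mp))) {
    i <- mp$open_idx[k]
    wt <- seqv[i]
    muts <- if (is.null(allowed)) .AA1 else allowed[[as.character(i)]]
    muts <- setdiff(muts, wt)
    if (length(muts))
      rows[[length(rows) + 1L]] <- data.frame(
        position = mp$resno_open[k], wt = wt, mut = muts,
        stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, rows)
  res <- surrogateDdg(pair, cand$position, cand$wt, cand$mut, model)
  list(open = data.frame(position = res$position, wt = res$wt, mut = res$mut,
                         ddg = res$ddg_open, stringsAsFactors = FALSE),
       closed = data.frame(position = res$position, wt = res$wt, mut = res$mut,
                           ddg = res$ddg_closed, stringsAsFactors = FALSE))
}

setMethod("show", "ContactModel", function(object) {
  cat("ContactModel: radius", object@contactRadius, "A; burial weight",
      object@burialWeight, "; exposure penalty", object@exposurePenalty, "\n")
})
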