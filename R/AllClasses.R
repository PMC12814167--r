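#' @import methods
NULL

## ---------------------------------------------------------------------------
## ProteinStructure
## ---------------------------------------------------------------------------

#' ProteinStructure: one conformation of a protein
#'
#' A light-weight container for one structure read from a PDB file. Atoms are
#' stored as a flat data frame (one row per atom); residues are identified by
#' the triplet (chain, residue number, insertion code) in file order. Waters
#' are removed at parse time and HETATM residues are flagged as ligands.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{icode}, \code{resname}, \code{elety} (atom name), \code{element},
#'   \code{x}, \code{y}, \code{z}, \code{is_ligand}, \code{res_id} (an
#'   integer residue index in file order).
#' @slot label free-text label, e.g. \code{"open"} or \code{"closed"}.
#'
#' @seealso [readStructure()], [stripLigands()], [pairStates()]
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", label = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "icode", "resname", "elety", "element",
            "x", "y", "z", "is_ligand", "res_id")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  prot <- a[!a$is_ligand, ]
  if (nrow(prot) > 0L) {
    has_ca <- tapply(prot$elety == "CA", prot$res_id, any)
    if (!all(has_ca)) return("protein residue without a CA atom")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## StructurePair
## ---------------------------------------------------------------------------

#' StructurePair: the open and closed conformations of one protein
#'
#' Produced by [pairStates()]. Holds the two protein-only structures, the
#' ligand atoms stripped from each, and a residue mapping built by global
#' sequence alignment. All downstream reporting uses open-state author residue
#' numbers; the mapping carries the correspondence to the closed state (whose
#' crystal structures are frequently numbered differently).
#'
#' @slot open,closed protein-only [ProteinStructure] objects.
#' @slot openLigands,closedLigands data.frames of ligand atoms (0 rows if the
#'   state is apo).
#' @slot mapping data.frame with columns \code{open_idx}, \code{closed_idx}
#'   (1-based indices into the protein residues of each state),
#'   \code{resno_open}, \code{resno_closed}, and \code{aa}.
#' @slot sequence one-letter sequence of the open-state protein.
#' @export
setClass("StructurePair",
  representation(open = "ProteinStructure", closed = "ProteinStructure",
                 openLigands = "data.frame", closedLigands = "data.frame",
                 mapping = "data.frame", sequence = "character"))

setValidity("StructurePair", function(object) {
  m <- object@mapping
  if (!all(c("open_idx", "closed_idx", "resno_open", "resno_closed", "aa")
           %in% names(m)))
    return("malformed mapping")
  nOpen <- length(unique(object@open@atoms$res_id[!object@open@atoms$is_ligand]))
  nClosed <- length(unique(object@closed@atoms$res_id[!object@closed@atoms$is_ligand]))
  if (nrow(m) < 0.9 * nOpen || nrow(m) < 0.9 * nClosed)
    return("mapping covers < 90% of protein residues of a state")
  if (anyDuplicated(m$open_idx) || anyDuplicated(m$closed_idx))
    return("mapping is not a bijection")
  TRUE
})

## ---------------------------------------------------------------------------
## GNM machinery
## ---------------------------------------------------------------------------

#' GNMModel: eigendecomposition of a Gaussian network model
#'
#' The Kirchhoff (connectivity) matrix of the C-alpha contact graph together
#' with its spectrum. Zero modes (rigid-body translations; one per connected
#' component of the contact graph) are removed and counted; mode 1 is the
#' retained mode with the smallest eigenvalue.
#'
#' @slot kirchhoff N x N symmetric connectivity matrix (graph Laplacian scaled
#'   by the spring constant).
#' @slot eigenvalues retained eigenvalues, ascending, all positive.
#' @slot eigenvectors N x K matrix of retained eigenvectors (unit norm,
#'   column k matches \code{eigenvalues[k]}); each column is oriented so its
#'   first non-negligible component is >= 0.
#' @slot nZeroModes number of modes removed as numerically zero.
#' @slot gamma spring constant.
#' @slot cutoff contact distance cutoff in Angstrom.
#' @seealso [buildKirchhoff()], [gnmDecompose()], [squareFluctuations()],
#'   [detectHinges()]
#' @export
setClass("GNMModel",
  representation(kirchhoff = "matrix", eigenvalues = "numeric",
                 eigenvectors = "matrix", nZeroModes = "integer",
                 gamma = "numeric", cutoff = "numeric"))

setValidity("GNMModel", function(object) {
  if (length(object@eigenvalues) != ncol(object@eigenvectors))
    return("eigenvalue/eigenvector count mismatch")
  if (length(object@eigenvalues) && any(object@eigenvalues <= 0))
    return("retained eigenvalues must be positive")
  if (is.unsorted(object@eigenvalues)) return("eigenvalues not ascending")
  V <- object@eigenvectors
  if (ncol(V)) {
    G <- crossprod(V)
    if (max(abs(G - diag(ncol(V)))) > 1e-8)
      return("eigenvectors not orthonormal to 1e-8")
  }
  TRUE
})

#' FluctuationProfile: per-residue square fluctuations
#'
#' @slot values per-residue square fluctuation (arbitrary units, >= 0).
#' @slot nModes number of slow modes summed.
#' @export
setClass("FluctuationProfile",
  representation(values = "numeric", nModes = "integer"))

setValidity("FluctuationProfile", function(object) {
  if (any(object@values < -1e-12)) return("negative fluctuation value")
  TRUE
})

#' HingeSet: hinge residues from the slowest mode
#'
#' Sign crossings of mode 1 of a [GNMModel], merged into hinge blocks.
#' Indices are 1-based positions along the model's residue order.
#'
#' @slot residues integer vector of hinge residue indices.
#' @slot crossings two-column integer matrix; each row is an adjacent pair
#'   (i, i+1) across which mode 1 changes sign.
#' @export
setClass("HingeSet",
  representation(residues = "integer", crossings = "matrix"))

setValidity("HingeSet", function(object) {
  cr <- object@crossings
  if (nrow(cr) && any(cr[, 2] != cr[, 1] + 1L))
    return("crossing pairs must be sequence-adjacent")
  if (nrow(cr) && !all(as.integer(cr) %in% object@residues))
    return("crossing residues missing from hinge residue set")
  TRUE
})

#' LobePartition: lobe membership of every residue
#'
#' @slot lobeA,lobeB,hinge disjoint integer index sets whose union covers all
#'   residues; lobe A is the lobe with positive mean mode-1 component.
#' @export
setClass("LobePartition",
  representation(lobeA = "integer", lobeB = "integer", hinge = "integer"))

setValidity("LobePartition", function(object) {
  all3 <- c(object@lobeA, object@lobeB, object@hinge)
  if (anyDuplicated(all3)) return("lobe/hinge sets are not disjoint")
  TRUE
})

## ---------------------------------------------------------------------------
## Design-side classes
## ---------------------------------------------------------------------------

#' FixedPositionSet: positions barred from mutation
#'
#' Positions are open-state author residue numbers; each carries one or more
#' provenance tags saying why it is fixed.
#'
#' @slot positions sorted integer vector.
#' @slot provenance named list (names = positions as character) of character
#'   vectors drawn from \code{pocket}, \code{hinge}, \code{interface},
#'   \code{terminus}.
#' @slot tier design tier this set was assembled for ("X.1".."X.4").
#' @export
setClass("FixedPositionSet",
  representation(positions = "integer", provenance = "list", tier = "character"))

setValidity("FixedPositionSet", function(object) {
  if (length(object@positions) != length(object@provenance))
    return("positions/provenance length mismatch")
  if (length(object@provenance) &&
      !identical(names(object@provenance), as.character(object@positions)))
    return("provenance names must match positions")
  if (any(vapply(object@provenance, length, 1L) < 1L))
    return("every fixed position needs >= 1 provenance tag")
  bad <- setdiff(unique(unlist(object@provenance)),
                 c("pocket", "hinge", "interface", "terminus"))
  if (length(bad)) return(paste("unknown provenance tag:", bad[1]))
  TRUE
})

#' PSSMatrix: position-specific scoring matrix in bits
#'
#' Log2-odds scores of the 20 amino acids at each position of the design
#' target, computed from an MSA with pseudocounts (see [computePSSM()]).
#'
#' @slot scores positions x 20 numeric matrix (columns in alphabetical
#'   one-letter order).
#' @slot countsEffective per-position effective (weighted) sequence count.
#' @slot background length-20 background frequencies, summing to 1.
#' @slot tau pseudocount weight (> 0, so all scores are finite).
#' @slot wildtype one-letter sequence of the query row.
#' @export
setClass("PSSMatrix",
  representation(scores = "matrix", countsEffective = "numeric",
                 background = "numeric", tau = "numeric", wildtype = "character"))

setValidity("PSSMatrix", function(object) {
  if (ncol(object@scores) != 20L) return("scores must have 20 columns")
  if (abs(sum(object@background) - 1) > 1e-9)
    return("background frequencies must sum to 1")
  if (!all(is.finite(object@scores))) return("non-finite PSSM score")
  if (object@tau <= 0) return("tau must be > 0")
  TRUE
})

#' DesignMSA: a parsed multiple sequence alignment
#'
#' Columns where the query (design target) carries a gap are dropped, so MSA
#' positions correspond 1:1 to query positions.
#'
#' @slot seqs character matrix (rows = sequences, columns = positions);
#'   gaps are \code{"-"}.
#' @slot names sequence identifiers.
#' @slot queryRow row index of the design target.
#' @export
setClass("DesignMSA",
  representation(seqs = "matrix", names = "character", queryRow = "integer"))

setValidity("DesignMSA", function(object) {
  if (nrow(object@seqs) != length(object@names)) return("names/rows mismatch")
  if (object@queryRow < 1L || object@queryRow > nrow(object@seqs))
    return("queryRow out of range")
  if (any(object@seqs[object@queryRow, ] == "-"))
    return("query row still contains gap columns")
  TRUE
})

#' DesignVariant: one assembled design
#'
#' @slot tier "X.0".."X.4".
#' @slot cutoff the energy cutoff the variant was assembled at (NA for X.0).
#' @slot mutations data.frame (position, wt, mut, ddg_open, ddg_closed,
#'   score, layer); at most one row per position.
#' @slot sequence the full designed sequence (open-state coordinates).
#' @slot mutationalLoad percent, 100 * n_mutations / length.
#' @slot outOfRange TRUE if no cutoff satisfied the target load window.
#' @slot layerSummary named integer counts per layer (surface/boundary/core).
#' @export
setClass("DesignVariant",
  representation(tier = "character", cutoff = "numeric", mutations = "data.frame",
                 sequence = "character", mutationalLoad = "numeric",
                 outOfRange = "logical", layerSummary = "integer"))

setValidity("DesignVariant", function(object) {
  m <- object@mutations
  if (nrow(m) && anyDuplicated(m$position)) return("more than one mutation per position")
  if (nrow(m) && any(m$wt == m$mut)) return("identity substitution")
  TRUE
})

#' DesignRun: the result of the full two-state design workflow
#'
#' @slot variants list of [DesignVariant] (X.0 .. X.4).
#' @slot mutationTable per-candidate table with both-state energies and layer
#'   labels (the open-vs-closed scatter data).
#' @slot profiles list with per-state 5-mode fluctuation profiles and mode-1
#'   components.
#' @slot fixed list of [FixedPositionSet] per tier.
#' @slot config the configuration the run used.
#' @export
setClass("DesignRun",
  representation(variants = "list", mutationTable = "data.frame",
                 profiles = "list", fixed = "list", config = "list"))

#' ContactModel: parameters of the surrogate stability calculator
#'
#' @slot contactRadius neighbour radius in Angstrom (C-beta based).
#' @slot hydrophobicity named numeric over the 20 amino acids
#'   (transfer-scale values; default Kyte-Doolittle).
#' @slot burialWeight coefficient converting burial x hydropathy change into
#'   energy units.
#' @slot exposurePenalty flat penalty for introducing a strongly hydrophobic
#'   identity at an exposed site (0 disables).
#' @slot exposedBurial burial count below which a site counts as exposed.
#' @export
setClass("ContactModel",
  representation(contactRadius = "numeric", hydrophobicity = "numeric",
                 burialWeight = "numeric", exposurePenalty = "numeric",
                 exposedBurial = "numeric"))

setValidity("ContactModel", function(object) {
  if (object@contactRadius <= 0) return("contactRadius must be > 0")
  if (!all(.AA1 %in% names(object@hydrophobicity)))
    return("hydrophobicity must cover all 20 amino acids")
  TRUE
})
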