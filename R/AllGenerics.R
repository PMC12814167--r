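#' @include AllClasses.R
NULL

#' Number of protein residues
#' @param x a ProteinStructure or StructurePair
#' @return integer count of protein (non-ligand) residues
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' One-letter amino-acid sequence
#' @param x a ProteinStructure, StructurePair or DesignMSA
#' @return character scalar (open-state sequence for a StructurePair)
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))

#' C-alpha coordinate matrix of the protein residues
#' @param x a ProteinStructure
#' @return N x 3 numeric matrix in residue order
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' Author residue numbers of the protein residues, in order
#' @param x a ProteinStructure
#' @return integer vector
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname StructurePair-class
#' @param x a StructurePair
#' @export
setGeneric("openState", function(x) standardGeneric("openState"))

#' @rdname StructurePair-class
#' @export
setGeneric("closedState", function(x) standardGeneric("closedState"))

#' @rdname StructurePair-class
#' @export
setGeneric("residueMapping", function(x) standardGeneric("residueMapping"))

#' Hinge residue indices of a HingeSet
#' @param x a HingeSet
#' @return sorted integer vector (possibly empty)
#' @export
setGeneric("hingeResidues", function(x) standardGeneric("hingeResidues"))

#' Fixed positions of a FixedPositionSet
#' @param x a FixedPositionSet
#' @return sorted integer vector of open-state author residue numbers
#' @export
setGeneric("fixedPositions", function(x) standardGeneric("fixedPositions"))

#' Mutation table of a design variant
#' @param x a DesignVariant
#' @return data.frame with one row per designed substitution
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' Designed full-length sequence
#' @param x a DesignVariant
#' @return character scalar
#' @export
setGeneric("designedSequence", function(x) standardGeneric("designedSequence"))

#' Mutational load in percent
#' @param x a DesignVariant
#' @return numeric scalar, 100 * n_mutations / length
#' @export
setGeneric("mutationalLoad", function(x) standardGeneric("mutationalLoad"))

#' Design variants of a DesignRun
#' @param x a DesignRun
#' @return named list of DesignVariant objects
#' @export
setGeneric("designVariants", function(x) standardGeneric("designVariants"))
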