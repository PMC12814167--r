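#' @include AllClasses.R AllGenerics.R
NULL

## internal: normalize input that may be a file path (possibly .gz) or a
## character vector of PDB lines.
.asLines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    con <- file(x)                      # transparently decompresses .gz
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read one conformational state from PDB text
#'
#' Parses ATOM/HETATM records into a [ProteinStructure]. Waters are dropped;
#' every other HETATM residue (including ions) is flagged as a ligand so it
#' can seed binding-pocket detection. For alternate locations the highest
#' occupancy wins (ties keep the first); exact duplicate atoms within a
#' residue raise a warning and keep the first. Protein (ATOM) residues
#' without a C-alpha are demoted to ligands with a warning.
#'
#' @param x path to a PDB file (plain or gzipped) or a character vector of
#'   PDB lines.
#' @param label free-text state label, e.g. "open" or "closed".
#' @param chain restrict to one chain identifier; default: the first chain
#'   carrying protein residues (ligands of any chain are kept).
#' @return a [ProteinStructure]
#' @examples
#' lines <- c("ATOM      1  CA  ALA A   1      0.000   0.000   0.000  1.00  0.00           C")
#' s <- readStructure(lines, label = "demo")
#' nResidues(s)
#' @export
readStructure <- function(x, label = "structure", chain = NULL) {
  lines <- .asLines(x)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(rec == "ATOM  "))
    stop("no ATOM records found: not a protein PDB file")
  lines <- lines[keep]
  type <- trimws(substr(lines, 1, 6))
  atoms <- data.frame(
    type    = type,
    elety   = trimws(substr(lines, 13, 16)),
    alt     = trimws(substr(lines, 17, 17)),
    resname = trimws(substr(lines, 18, 20)),
    chain   = trimws(substr(lines, 22, 22)),
    resno   = as.integer(substr(lines, 23, 26)),
    icode   = trimws(substr(lines, 27, 27)),
    x       = as.numeric(substr(lines, 31, 38)),
    y       = as.numeric(substr(lines, 39, 46)),
    z       = as.numeric(substr(lines, 47, 54)),
    occ     = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$element[atoms$element == ""] <- substr(atoms$elety, 1, 1)

  atoms <- atoms[!(atoms$resname %in% .WATER_RESNAMES), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms left after removing waters")
  atoms$is_ligand <- atoms$type == "HETATM"

  if (is.null(chain)) {
    protChains <- unique(atoms$chain[!atoms$is_ligand])
    chain <- protChains[1]
  }
  atoms <- atoms[atoms$is_ligand | atoms$chain == chain, , drop = FALSE]
  if (!any(!atoms$is_ligand))
    stop("no protein residues on chain '", chain, "'")

  ## altloc / duplicate handling within (chain, resno, icode, atom name)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety, atoms$is_ligand)
  if (anyDuplicated(key)) {
    dupTrue <- duplicated(paste(key, atoms$alt))
    if (any(dupTrue))
      warning(sum(dupTrue), " duplicate atom record(s); keeping the first")
    ord <- order(match(key, unique(key)), -atoms$occ, seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                     atoms$elety, atoms$is_ligand)), , drop = FALSE]
    atoms <- atoms[order(match(paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety,
                                     atoms$is_ligand), key)), , drop = FALSE]
  }

  rkey <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$is_ligand)
  atoms$res_id <- match(rkey, unique(rkey))

  ## ATOM residues without CA cannot enter the C-alpha network
  prot_ids <- unique(atoms$res_id[!atoms$is_ligand])
  has_ca <- vapply(prot_ids, function(id)
    any(atoms$elety[atoms$res_id == id] == "CA"), logical(1))
  if (any(!has_ca)) {
    warning(sum(!has_ca), " ATOM residue(s) without CA treated as ligand")
    atoms$is_ligand[atoms$res_id %in% prot_ids[!has_ca]] <- TRUE
  }

  atoms$type <- NULL; atoms$alt <- NULL; atoms$occ <- NULL
  new("ProteinStructure", atoms = atoms, label = label)
}

#' Separate protein from bound ligands
#'
#' @param s a [ProteinStructure]
#' @return list with \code{protein} (a ligand-free [ProteinStructure]) and
#'   \code{ligands} (data.frame of ligand atoms; 0 rows if apo)
#' @export
stripLigands <- function(s) {
  stopifnot(is(s, "ProteinStructure"))
  a <- s@atoms
  lig <- a[a$is_ligand, , drop = FALSE]
  prot <- a[!a$is_ligand, , drop = FALSE]
  prot$res_id <- match(prot$res_id, unique(prot$res_id))
  list(protein = new("ProteinStructure", atoms = prot, label = s@label),
       ligands = lig)
}

## internal: per-protein-residue table (one row per residue, in order)
.residueTable <- function(s) {
  a <- s@atoms[!s@atoms$is_ligand, , drop = FALSE]
  first <- !duplicated(a$res_id)
  data.frame(res_id = a$res_id[first], chain = a$chain[first],
             resno = a$resno[first], icode = a$icode[first],
             resname = a$resname[first], stringsAsFactors = FALSE)
}

#' @describeIn nResidues protein residue count of one structure
#' @export
setMethod("nResidues", "ProteinStructure", function(x) nrow(.residueTable(x)))

#' @describeIn proteinSequence sequence of one structure
#' @export
setMethod("proteinSequence", "ProteinStructure", function(x)
  paste(.aa321(.residueTable(x)$resname), collapse = ""))

#' @describeIn caCoords C-alpha coordinates of one structure
#' @export
setMethod("caCoords", "ProteinStructure", function(x) {
  a <- x@atoms[!x@atoms$is_ligand & x@atoms$elety == "CA", , drop = FALSE]
  a <- a[!duplicated(a$res_id), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
})

#' @describeIn residueNumbers author numbering of one structure
#' @export
setMethod("residueNumbers", "ProteinStructure", function(x) .residueTable(x)$resno)

setMethod("show", "ProteinStructure", function(object) {
  nl <- length(unique(object@atoms$res_id[object@atoms$is_ligand]))
  cat("ProteinStructure '", object@label, "': ", nResidues(object),
      " protein residues, ", nl, " ligand residue(s), ",
      nrow(object@atoms), " atoms\n", sep = "")
})

## ---------------------------------------------------------------------------
## Pairing the two states
## ---------------------------------------------------------------------------

.globalAlign <- function(s1, s2) {
  alphabet <- sort(unique(c(strsplit(s1, "")[[1]], strsplit(s2, "")[[1]], "X")))
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  pa <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  list(p = strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]],
       s = strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]])
}

#' Pair the open- and closed-state structures
#'
#' Strips ligands from both states, aligns the two protein sequences globally
#' (match +1, mismatch -1, gap -2), and keeps aligned identical residue pairs
#' as the shared coordinate system. The closed state is thereby adjusted to
#' open-state numbering: every downstream position report uses open-state
#' author residue numbers. Sequence identity over aligned columns must be at
#' least 95%, otherwise the two files are not two states of the same protein.
#'
#' @param open,closed [ProteinStructure] objects (ligands allowed; they are
#'   stripped and retained for pocket detection).
#' @param minIdentity minimum identity over aligned columns (default 0.95).
#' @return a [StructurePair]
#' @export
pairStates <- function(open, closed, minIdentity = 0.95) {
  so <- stripLigands(open); sc <- stripLigands(closed)
  seqO <- proteinSequence(so$protein); seqC <- proteinSequence(sc$protein)
  al <- .globalAlign(seqO, seqC)
  both <- al$p != "-" & al$s != "-"
  if (!any(both)) stop("pairing error: sequences do not align")
  ident <- sum(al$p[both] == al$s[both]) / sum(both)
  if (ident < minIdentity)
    stop(sprintf("pairing error: aligned identity %.1f%% < %.1f%%: not the same protein",
                 100 * ident, 100 * minIdentity))
  iO <- cumsum(al$p != "-"); iC <- cumsum(al$s != "-")
  keep <- both & al$p == al$s
  rtO <- .residueTable(so$protein); rtC <- .residueTable(sc$protein)
  mapping <- data.frame(open_idx = iO[keep], closed_idx = iC[keep],
                        resno_open = rtO$resno[iO[keep]],
                        resno_closed = rtC$resno[iC[keep]],
                        aa = al$p[keep], stringsAsFactors = FALSE)
  new("StructurePair", open = so$protein, closed = sc$protein,
      openLigands = so$ligands, closedLigands = sc$ligands,
      mapping = mapping, sequence = seqO)
}

#' @describeIn StructurePair-class the open-state structure
#' @export
setMethod("openState", "StructurePair", function(x) x@open)
#' @describeIn StructurePair-class the closed-state structure
#' @export
setMethod("closedState", "StructurePair", function(x) x@closed)
#' @describeIn StructurePair-class the residue-index mapping
#' @export
setMethod("residueMapping", "StructurePair", function(x) x@mapping)
#' @describeIn StructurePair-class number of mapped residues
#' @export
setMethod("nResidues", "StructurePair", function(x) nResidues(x@open))
#' @describeIn StructurePair-class open-state one-letter sequence
#' @export
setMethod("proteinSequence", "StructurePair", function(x) x@sequence)

setMethod("show", "StructurePair", function(object) {
  cat("StructurePair: open", nResidues(object@open), "res / closed",
      nResidues(object@closed), "res;", nrow(object@mapping),
      "mapped;", nrow(object@closedLigands), "closed-state ligand atoms\n")
})

## open-state author resno <-> open internal index
.resnoOfIndex <- function(pair, idx) {
  rt <- .residueTable(pair@open)
  rt$resno[idx]
}
.indexOfResno <- function(pair, resno) {
  rt <- .residueTable(pair@open)
  match(resno, rt$resno)
}

#' Write a normalized PDB representation
#'
#' Debug/interchange output: one ATOM or HETATM record per atom in storage
#' order, author numbering preserved.
#'
#' @param s a [ProteinStructure]
#' @param path output file; if NULL, the lines are returned invisibly.
#' @return character vector of PDB lines, invisibly
#' @export
writeStructurePDB <- function(s, path = NULL) {
  a <- s@atoms
  rec <- ifelse(a$is_ligand, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)),
                   ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
                   " ", a$resname, a$chain, a$resno, ifelse(a$icode == "", " ", a$icode),
                   a$x, a$y, a$z, 1, 0, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
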