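#' @include AllClasses.R AllGenerics.R structure-io.R gnm.R constraints.R pssm.R
NULL

#' Default energy cutoffs of the combinatorial design ladder
#'
#' Nine cutoffs, ascending; a candidate joins a design at every cutoff at or
#' above its own selection score. Units are those of the upstream energy
#' calculator.
#' @export
DESIGN_CUTOFFS <- c(-4, -3.20, -2.88, -2.4, -2, -1.6, -1.2, -0.72, 0)

#' Load and join the two per-state ddG tables
#'
#' Each table is TSV with columns \code{position}, \code{wt}, \code{mut},
#' \code{ddg} (positions in open-state author numbering, one row per
#' candidate substitution). The tables are joined on (position, wt, mut);
#' candidates present in only one state's table are dropped with a warning
#' giving the count. The wild-type identity of every candidate must match
#' the paired sequence at its position.
#'
#' @param open,closed file paths or data.frames in the ddG table dialect
#' @param pair a [StructurePair] used to validate positions and identities
#' @return data.frame with columns position, wt, mut, ddg_open, ddg_closed
#' @export
loadDdgTables <- function(open, closed, pair) {
  readOne <- function(x, what) {
    df <- if (is.data.frame(x)) x else
      utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("position", "wt", "mut", "ddg")
    if (!all(need %in% names(df)))
      stop(what, " ddG table needs columns: ", paste(need, collapse = ", "))
    df[need]
  }
  dfo <- readOne(open, "open"); dfc <- readOne(closed, "closed")
  seqv <- strsplit(pair@sequence, "")[[1]]
  for (df in list(dfo, dfc)) {
    idx <- .indexOfResno(pair, df$position)
    if (anyNA(idx))
      stop("position ", df$position[which(is.na(idx))[1]],
           " not resolvable in the structure pair")
    bad <- seqv[idx] != df$wt
    if (any(bad))
      stop("wild-type mismatch at position ", df$position[which(bad)[1]],
           ": table says ", df$wt[which(bad)[1]], ", sequence has ",
           seqv[idx[which(bad)[1]]])
  }
  joined <- merge(dfo, dfc, by = c("position", "wt", "mut"),
                  suffixes = c("_open", "_closed"))
  names(joined)[names(joined) == "ddg_open"] <- "ddg_open"
  dropped <- nrow(dfo) + nrow(dfc) - 2L * nrow(joined)
  if (dropped > 0L)
    warning(dropped, " candidate(s) present in only one state's table were dropped")
  joined <- joined[order(joined$position, joined$mut), , drop = FALSE]
  rownames(joined) <- NULL
  joined
}

#' The two-state filter
#'
#' Keeps a candidate mutation only if it is stabilizing -- ddG strictly
#' below zero -- in both the open- and the closed-state calculation.
#' Mutations that are destabilizing in either state (including exact zeros)
#' are removed, protecting the conformational equilibrium from mutations
#' that favour one state.
#'
#' @param records data.frame from [loadDdgTables()]
#' @return the subset with \code{ddg_open < 0 & ddg_closed < 0}
#' @export
twoStateFilter <- function(records) {
  out <- records[records$ddg_open < 0 & records$ddg_closed < 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## internal: selection score under a tier's scoring rule
.selectionScore <- function(records, scoreOf) {
  switch(scoreOf,
         open = records$ddg_open,
         closed = records$ddg_closed,
         max_of_both = pmax(records$ddg_open, records$ddg_closed),
         mean = (records$ddg_open + records$ddg_closed) / 2,
         stop("unknown scoreOf: ", scoreOf))
}

#' Enumerate the per-cutoff combinatorial designs
#'
#' For each cutoff c, the design contains every candidate whose selection
#' score is <= c, whose position is not fixed, and whose mutant identity is
#' evolutionarily allowed. Where several candidates target one position the
#' lowest selection score wins (ties: lexicographically smallest mutant
#' identity), so combination is additive with at most one substitution per
#' position.
#'
#' @param records data.frame of candidates (position, wt, mut, ddg_open,
#'   ddg_closed)
#' @param cutoffs ascending numeric cutoffs (default [DESIGN_CUTOFFS])
#' @param fixed a [FixedPositionSet] (or integer vector of positions)
#' @param allowed named list from [allowedIdentities()], names = positions
#'   as open-state author numbers mapped 1:1 to sequence positions; NULL
#'   disables the alphabet check
#' @param scoreOf "open", "closed", "max_of_both", or "mean"
#' @param positionOfSeq function mapping an author position to the 1-based
#'   sequence position used to look up \code{allowed}; default identity
#' @return named list (one element per cutoff, names = formatted cutoffs)
#'   of mutation data.frames with a \code{score} column
#' @export
enumerateCutoffDesigns <- function(records, cutoffs = DESIGN_CUTOFFS,
                                   fixed = integer(0), allowed = NULL,
                                   scoreOf = "max_of_both",
                                   positionOfSeq = identity) {
  if (is.unsorted(cutoffs)) stop("cutoffs must be ascending")
  fixedPos <- if (is(fixed, "FixedPositionSet")) fixed@positions else as.integer(fixed)
  rec <- records
  rec$score <- .selectionScore(rec, scoreOf)
  rec <- rec[!(rec$position %in% fixedPos), , drop = FALSE]
  if (!is.null(allowed)) {
    seqPos <- positionOfSeq(rec$position)
    ok <- vapply(seq_len(nrow(rec)), function(i) {
      al <- allowed[[as.character(seqPos[i])]]
      !is.null(al) && rec$mut[i] %in% al
    }, logical(1))
    rec <- rec[ok, , drop = FALSE]
  }
  ## deterministic per-position winner: lowest score, then alphabetical mut
  rec <- rec[order(rec$position, rec$score, rec$mut), , drop = FALSE]
  out <- lapply(cutoffs, function(cc) {
    sub <- rec[rec$score <= cc, , drop = FALSE]
    sub <- sub[!duplicated(sub$position), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- formatC(cutoffs, format = "g")
  out
}

#' Select the design at the target mutational load
#'
#' Chooses the strictest (most negative) cutoff whose design has a
#' mutational load inside \code{loadRange} (percent). If no cutoff
#' qualifies, the cutoff whose load is closest to the range is chosen (ties:
#' the stricter cutoff) and the result is flagged out-of-range.
#'
#' @param perCutoff named list from [enumerateCutoffDesigns()]
#' @param loadRange percent interval (default c(4, 10))
#' @param length protein length used for the load
#' @return list(cutoff, mutations, load, outOfRange)
#' @export
selectDesign <- function(perCutoff, loadRange = c(4, 10), length) {
  if (length(perCutoff) == 0L) stop("no cutoff designs supplied")
  cutoffs <- as.numeric(names(perCutoff))
  loads <- unname(vapply(perCutoff, nrow, 1L)) * 100 / length
  if (all(vapply(perCutoff, nrow, 1L) == 0L))
    stop("all cutoff designs are empty")
  inRange <- loads >= loadRange[1] & loads <= loadRange[2]
  if (any(inRange)) {
    pick <- which(inRange)[1]         # cutoffs ascending: first = strictest
    oor <- FALSE
  } else {
    distToRange <- pmax(loadRange[1] - loads, loads - loadRange[2], 0)
    pick <- which(distToRange == min(distToRange))[1]
    oor <- TRUE
  }
  list(cutoff = cutoffs[pick], mutations = perCutoff[[pick]],
       load = loads[pick], outOfRange = oor)
}

## ---------------------------------------------------------------------------
## Layer classification
## ---------------------------------------------------------------------------

## internal: per-residue side-chain anchor (CB, CA for glycine) and the
## CA->CB direction (pseudo-CB direction from the backbone where CB absent).
.sideChainFrames <- function(s) {
  rt <- .residueTable(s)
  ca <- caCoords(s)
  n <- nrow(rt)
  cb <- matrix(NA_real_, n, 3)
  a <- s@atoms[!s@atoms$is_ligand, , drop = FALSE]
  for (i in seq_len(n)) {
    rows <- a[a$res_id == rt$res_id[i] & a$elety == "CB", , drop = FALSE]
    if (nrow(rows)) cb[i, ] <- as.numeric(rows[1, c("x", "y", "z")])
  }
  miss <- which(is.na(cb[, 1]))
  nonGly <- miss[rt$resname[miss] != "GLY"]
  if (length(nonGly))
    warning(length(nonGly), " non-glycine residue(s) without CB; using a pseudo-CB")
  dirv <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (!is.na(cb[i, 1])) {
      v <- cb[i, ] - ca[i, ]
    } else {
      ## pseudo side-chain direction: away from the backbone neighbours
      nb <- ca[pmax(1, i - 1), ] + ca[pmin(n, i + 1), ]
      v <- 2 * ca[i, ] - nb
      if (sum(v^2) < 1e-9) v <- c(0, 0, 1)
      cb[i, ] <- ca[i, ]              # glycine measures distances from CA
    }
    dirv[i, ] <- v / sqrt(sum(v^2))
  }
  list(anchor = cb, dir = dirv, resno = rt$resno)
}

#' Classify residues into surface, boundary, and core layers
#'
#' Burial is measured as a weighted side-chain neighbour count
#' \eqn{n_i = \sum_{j \ne i} f(d_{ij})\, g(\theta_{ij})}: \eqn{d_{ij}} is the
#' C-beta--C-beta distance (C-alpha for glycine), f a sigmoid falling from 1
#' to 0 between 9 and 11 Angstrom, and g a squared cosine cone weight
#' \eqn{g = (\max(0, \cos\theta + 0.5)/1.5)^2} on the angle between residue
#' i's C-alpha-to-C-beta direction and the vector to neighbour j. Residues
#' with \eqn{n_i \ge} \code{coreCut} are core, \eqn{n_i \le}
#' \code{surfaceCut} surface, anything between boundary.
#'
#' @param structure a [ProteinStructure]
#' @param positions author residue numbers to classify (default: all)
#' @param surfaceCut,coreCut layer thresholds (defaults 2.0 and 5.2)
#' @return character vector of layer labels named by position
#' @export
classifyLayer <- function(structure, positions = NULL,
                          surfaceCut = 2.0, coreCut = 5.2) {
  fr <- .sideChainFrames(structure)
  n <- nrow(fr$anchor)
  if (is.null(positions)) positions <- fr$resno
  idx <- match(positions, fr$resno)
  if (anyNA(idx)) stop("position ", positions[which(is.na(idx))[1]], " not in structure")
  counts <- vapply(idx, function(i) {
    d <- sqrt(rowSums(sweep(fr$anchor, 2, fr$anchor[i, ])^2))
    f <- ifelse(d <= 9, 1, ifelse(d >= 11, 0, (1 + cos(pi * (d - 9) / 2)) / 2))
    vj <- sweep(fr$anchor, 2, fr$anchor[i, ])
    nv <- sqrt(rowSums(vj^2))
    cosT <- (vj %*% fr$dir[i, ]) / pmax(nv, 1e-9)
    g <- pmin(1, (pmax(0, cosT + 0.5) / 1.5)^2)
    sum((f * g)[-i])
  }, numeric(1))
  lab <- ifelse(counts >= coreCut, "core",
                ifelse(counts <= surfaceCut, "surface", "boundary"))
  stats::setNames(lab, positions)
}

## ---------------------------------------------------------------------------
## Workflow
## ---------------------------------------------------------------------------

.applyMutations <- function(sequence, mutTable, pair) {
  seqv <- strsplit(sequence, "")[[1]]
  if (nrow(mutTable)) {
    idx <- .indexOfResno(pair, mutTable$position)
    seqv[idx] <- mutTable$mut
  }
  paste(seqv, collapse = "")
}

.makeVariant <- function(tier, sel, pair, layers) {
  m <- sel$mutations
  m$layer <- if (nrow(m)) unname(layers[as.character(m$position)]) else character(0)
  counts <- table(factor(m$layer, levels = c("surface", "boundary", "core")))
  new("DesignVariant", tier = tier, cutoff = sel$cutoff, mutations = m,
      sequence = .applyMutations(pair@sequence, m, pair),
      mutationalLoad = sel$load, outOfRange = sel$outOfRange,
      layerSummary = stats::setNames(as.integer(counts), names(counts)))
}

#' Default workflow configuration
#'
#' All tunables of the two-state design workflow with their defaults:
#' the GNM contact cutoff (10 A) and spring constant (1), the number of slow
#' modes in fluctuation profiles (5), hinge merging, the 6 A pocket and
#' interface radii, the interface/hinge state policy, the 5-residue terminal
#' margin, the PSSM pseudocount weight (tau = 10), the nine-step energy
#' cutoff ladder, the 4-10% target load window, and the tier scoring rules.
#'
#' @return named list of configuration values
#' @export
designConfig <- function() {
  list(gnm_cutoff = 10, gamma = 1, n_modes = 5,
       merge_window = 2, amp_floor = 0,
       pocket_cutoff = 6, interface_cutoff = 6,
       interface_state = "union", hinge_state = "union",
       terminal_margin = 5,
       tau = 10, pssm_weighting = "position_based",
       cutoffs = DESIGN_CUTOFFS, load_range = c(4, 10),
       score_single = c(X.1 = "open", X.2 = "closed"),
       score_two_state = "max_of_both",
       couple_x4_cutoff = TRUE,
       pool = "all")
}

#' Run the full two-state stability-design workflow
#'
#' Orchestrates the whole pipeline: GNM hinge detection on both states,
#' lobe splitting and interface detection, pocket and terminal constraints,
#' the PSSM alphabet filter, per-state candidate loading, the two-state
#' filter, cutoff enumeration and load-based selection -- yielding the four
#' design tiers plus the wild-type control:
#' \itemize{
#'   \item X.0 wild type (control, no mutations);
#'   \item X.1 single-state design on the open structure;
#'   \item X.2 single-state design on the closed structure;
#'   \item X.3 two-state-filtered design (both-state-stabilizing mutations
#'     only, scored by their worse state);
#'   \item X.4 as X.3 with hinge and lobe-interface positions additionally
#'     fixed.
#' }
#'
#' @param pair a [StructurePair]
#' @param msa a [DesignMSA], a [PSSMatrix], or NULL to disable the alphabet
#'   filter
#' @param ddgOpen,ddgClosed ddG tables (paths or data.frames); if both are
#'   NULL the built-in surrogate calculator is used
#' @param config list from [designConfig()]; supplied values override
#'   defaults, unknown keys are rejected
#' @param contactModel surrogate parameters, see [contactModel()]
#' @return a [DesignRun]
#' @export
runWorkflow <- function(pair, msa = NULL, ddgOpen = NULL, ddgClosed = NULL,
                        config = list(), contactModel = NULL) {
  cfg <- designConfig()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config

  n <- nResidues(pair@open)
  seqv <- strsplit(pair@sequence, "")[[1]]

  ## --- dynamics on both states ---
  gOpen <- gnmFromStructure(pair@open, cutoff = cfg$gnm_cutoff, gamma = cfg$gamma)
  gClosed <- gnmFromStructure(pair@closed, cutoff = cfg$gnm_cutoff, gamma = cfg$gamma)
  hOpen <- detectHinges(gOpen, mergeWindow = cfg$merge_window, ampFloor = cfg$amp_floor)
  hClosed <- detectHinges(gClosed, mergeWindow = cfg$merge_window, ampFloor = cfg$amp_floor)
  ## closed-state hinge indices mapped into open internal indices
  mp <- pair@mapping
  hClosedOpenIdx <- mp$open_idx[match(hClosed@residues, mp$closed_idx)]
  hClosedOpenIdx <- hClosedOpenIdx[!is.na(hClosedOpenIdx)]
  hingeIdx <- switch(cfg$hinge_state,
                     open = hOpen@residues,
                     closed = as.integer(hClosedOpenIdx),
                     union = sort(unique(c(hOpen@residues, hClosedOpenIdx))))
  hingePos <- .resnoOfIndex(pair, hingeIdx)

  partition <- splitLobes(gOpen@eigenvectors[, 1], hingeIdx)
  interfacePos <- if (length(partition@lobeA) && length(partition@lobeB))
    interfaceResidues(pair, partition, cutoff = cfg$interface_cutoff,
                      state = cfg$interface_state) else integer(0)
  pocketPos <- if (nrow(pair@closedLigands)) pocketResidues(pair, cfg$pocket_cutoff)
               else integer(0)
  terminalPos <- .resnoOfIndex(pair, terminalMargin(n, cfg$terminal_margin))

  fixed <- lapply(c("X.1", "X.2", "X.3", "X.4"), assembleFixedSet,
                  pocket = pocketPos, hinge = hingePos,
                  interface = interfacePos, terminal = terminalPos)
  names(fixed) <- c("X.1", "X.2", "X.3", "X.4")

  ## --- evolutionary alphabet ---
  allowed <- NULL
  if (!is.null(msa)) {
    pssm <- if (is(msa, "PSSMatrix")) msa
            else computePSSM(msa, tau = cfg$tau, weighting = cfg$pssm_weighting)
    allowed <- allowedIdentities(pssm, pair@sequence)
  }
  posOfSeq <- function(p) .indexOfResno(pair, p)

  ## --- candidate energies ---
  if (is.null(ddgOpen) && is.null(ddgClosed)) {
    cm <- contactModel %||% contactModel()
    scan <- scanDdg(pair, allowed = allowed, model = cm)
    ddgOpen <- scan$open; ddgClosed <- scan$closed
  }
  records <- loadDdgTables(ddgOpen, ddgClosed, pair)
  filtered <- twoStateFilter(records)

  layers <- classifyLayer(pair@open)

  variants <- list()
  variants[["X.0"]] <- new("DesignVariant", tier = "X.0", cutoff = NA_real_,
    mutations = records[0, c("position", "wt", "mut", "ddg_open", "ddg_closed")],
    sequence = pair@sequence, mutationalLoad = 0, outOfRange = FALSE,
    layerSummary = stats::setNames(integer(3), c("surface", "boundary", "core")))
  for (tier in c("X.1", "X.2")) {
    per <- enumerateCutoffDesigns(records, cutoffs = cfg$cutoffs,
                                  fixed = fixed[[tier]], allowed = allowed,
                                  scoreOf = cfg$score_single[[tier]],
                                  positionOfSeq = posOfSeq)
    variants[[tier]] <- .makeVariant(tier, selectDesign(per, cfg$load_range, n),
                                     pair, layers)
  }
  pool <- filtered
  if (cfg$pool == "selected")
    pool <- filtered[paste(filtered$position, filtered$mut) %in%
                     c(paste(variants[["X.1"]]@mutations$position,
                             variants[["X.1"]]@mutations$mut),
                       paste(variants[["X.2"]]@mutations$position,
                             variants[["X.2"]]@mutations$mut)), , drop = FALSE]
  for (tier in c("X.3", "X.4")) {
    per <- enumerateCutoffDesigns(pool, cutoffs = cfg$cutoffs,
                                  fixed = fixed[[tier]], allowed = allowed,
                                  scoreOf = cfg$score_two_state,
                                  positionOfSeq = posOfSeq)
    if (tier == "X.4" && isTRUE(cfg$couple_x4_cutoff) &&
        !is.na(variants[["X.3"]]@cutoff)) {
      ## X.4 is X.3 with extra positions fixed, taken at the cutoff chosen
      ## for X.3, so the extra constraints can only remove mutations; its
      ## load may drop below the target window
      cut3 <- variants[["X.3"]]@cutoff
      pick <- which(abs(as.numeric(names(per)) - cut3) < 1e-9)[1]
      load <- nrow(per[[pick]]) * 100 / n
      sel <- list(cutoff = cut3, mutations = per[[pick]], load = load,
                  outOfRange = load < cfg$load_range[1] | load > cfg$load_range[2])
    } else {
      sel <- selectDesign(per, cfg$load_range, n)
    }
    variants[[tier]] <- .makeVariant(tier, sel, pair, layers)
  }

  mutationTable <- records
  mutationTable$layer <- unname(layers[as.character(records$position)])
  profiles <- list(
    open = list(fluct = fluctuationValues(squareFluctuations(
                  gOpen, min(cfg$n_modes, length(gOpen@eigenvalues)))),
                mode1 = gOpen@eigenvectors[, 1],
                hinges = hOpen@residues, resno = residueNumbers(pair@open)),
    closed = list(fluct = fluctuationValues(squareFluctuations(
                    gClosed, min(cfg$n_modes, length(gClosed@eigenvalues)))),
                  mode1 = gClosed@eigenvectors[, 1],
                  hinges = hClosed@residues, resno = residueNumbers(pair@closed)))
  new("DesignRun", variants = variants, mutationTable = mutationTable,
      profiles = profiles, fixed = fixed, config = cfg)
}

#' @describeIn runWorkflow design variants of a run
#' @param x a DesignRun
#' @export
setMethod("designVariants", "DesignRun", function(x) x@variants)

setMethod("mutations", "DesignVariant", function(x) x@mutations)
setMethod("designedSequence", "DesignVariant", function(x) x@sequence)
setMethod("mutationalLoad", "DesignVariant", function(x) x@mutationalLoad)

setMethod("show", "DesignVariant", function(object) {
  cat(sprintf("DesignVariant %s: %d mutation(s), load %.1f%%, cutoff %s%s\n",
              object@tier, nrow(object@mutations), object@mutationalLoad,
              ifelse(is.na(object@cutoff), "-", format(object@cutoff)),
              if (object@outOfRange) " [load out of range]" else ""))
})

setMethod("show", "DesignRun", function(object) {
  cat("DesignRun over", nchar(object@variants[[1]]@sequence), "residues\n")
  cat(sprintf("  %-5s %9s %8s %8s\n", "tier", "mutations", "load%", "cutoff"))
  for (v in object@variants)
    cat(sprintf("  %-5s %9d %8.1f %8s\n", v@tier, nrow(v@mutations),
                v@mutationalLoad, ifelse(is.na(v@cutoff), "-", format(v@cutoff))))
})

#' Mutation bookkeeping between a wild type and a design
#'
#' Pairwise comparison of two equal-length sequences: the substituted
#' positions, their count, and the mutational load in percent. This is the
#' check used to recompute published per-design mutation counts from their
#' full sequences.
#'
#' @param wt,designed equal-length one-letter sequences
#' @return list(n, load, positions, wt, mut)
#' @export
mutationBookkeeping <- function(wt, designed) {
  a <- strsplit(wt, "")[[1]]; b <- strsplit(designed, "")[[1]]
  if (length(a) != length(b))
    stop("sequences differ in length (", length(a), " vs ", length(b), ")")
  d <- which(a != b)
  list(n = length(d), load = 100 * length(d) / length(a),
       positions = d, wt = a[d], mut = b[d])
}
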