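#' @include AllClasses.R AllGenerics.R structure-io.R gnm.R surrogate.R pssm.R
NULL

## run expr under a given seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of one synthetic two-lobe fixture
#'
#' The fixture generator emulates the essentials of a periplasmic binding
#' protein pair: two compact helical lobes joined by a short linker
#' ("Venus flytrap"), a closed state with the lobes clamped around a ligand
#' in the cleft, and an open state produced by a rigid rotation of lobe B
#' about the hinge axis, with the rotation distributed progressively across
#' the linker residues. The same specification always yields bit-identical
#' output.
#'
#' @param nPerLobe residues per lobe (>= 15)
#' @param linkerLen linker (planted hinge) length in residues
#' @param closureAngle opening rotation in degrees (0..90)
#' @param ligand place a small ligand in the closed-state cleft?
#' @param seed integer seed; drives every random choice of the fixture
#' @param msaRows rows of the companion alignment
#' @param conservedFraction fraction of fully conserved alignment columns
#' @param closedOffset author-numbering offset of the closed state,
#'   emulating differently numbered crystal structures
#' @param classFractions named fractions of the four planted ddG classes
#'   (both_stabilizing, both_destabilizing, open_only, closed_only)
#' @return a list of class "FixtureSpec"
#' @export
fixtureSpec <- function(nPerLobe = 30, linkerLen = 4, closureAngle = 35,
                        ligand = TRUE, seed = 1, msaRows = 50,
                        conservedFraction = 0.6, closedOffset = 5,
                        classFractions = c(both_stabilizing = 0.20,
                                           both_destabilizing = 0.40,
                                           open_only = 0.25,
                                           closed_only = 0.15)) {
  if (nPerLobe < 15) stop("nPerLobe must be >= 15")
  if (closureAngle < 0 || closureAngle > 90)
    stop("closureAngle must be within 0..90 degrees")
  if (abs(sum(classFractions) - 1) > 1e-9)
    stop("classFractions must sum to 1")
  structure(list(nPerLobe = as.integer(nPerLobe),
                 linkerLen = as.integer(linkerLen),
                 closureAngle = closureAngle, ligand = isTRUE(ligand),
                 seed = as.integer(seed), msaRows = as.integer(msaRows),
                 conservedFraction = conservedFraction,
                 closedOffset = as.integer(closedOffset),
                 classFractions = classFractions),
            class = "FixtureSpec")
}

## compact helical trace wound on a sphere: sequential spacing `step`,
## adjacent turns about `turn` apart -> a rigid, well-connected lobe
.sphericalSpiral <- function(n, step = 3.8, turn = 5.3) {
  R <- sqrt(n * turn * step / (4 * pi))
  repeat {
    kk <- 2 * pi * R / turn
    th <- 0.35
    pts <- matrix(NA_real_, n, 3)
    ok <- TRUE
    for (i in seq_len(n)) {
      ph <- kk * th
      pts[i, ] <- R * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      th <- th + step / sqrt(R^2 * (1 + kk^2 * sin(th)^2))
      if (th > pi - 0.30 && i < n) { ok <- FALSE; break }
    }
    if (ok && min(stats::dist(pts)) >= 2.6) return(pts)
    R <- R * 1.06
  }
}

.rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * (a %o% a)
}

## pseudo C-beta positions from a C-alpha trace
.pseudoCB <- function(ca) {
  n <- nrow(ca)
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    v <- if (i == 1) ca[1, ] - ca[2, ]
         else if (i == n) ca[n, ] - ca[n - 1, ]
         else 2 * ca[i, ] - ca[i - 1, ] - ca[i + 1, ]
    if (sum(v^2) < 1e-9) v <- c(0, 0, 1)
    cb[i, ] <- ca[i, ] + 1.53 * v / sqrt(sum(v^2))
  }
  cb
}

.pdbLines <- function(ca, cb, seqv, resno, chain = "A", ligXYZ = NULL,
                      header = NULL) {
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("REMARK   9 ", header)
  serial <- 0L
  fmt <- function(rec, name, resn, rn, xyz, elem) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, paste0(" ", name), resn, chain, rn,
            xyz[1], xyz[2], xyz[3], 1, 0, elem)
  }
  for (i in seq_len(nrow(ca))) {
    resn <- .aa123(seqv[i])
    lines <- c(lines, fmt("ATOM", "CA", resn, resno[i], ca[i, ], "C"))
    if (seqv[i] != "G")
      lines <- c(lines, fmt("ATOM", "CB", resn, resno[i], cb[i, ], "C"))
  }
  if (!is.null(ligXYZ))
    for (j in seq_len(nrow(ligXYZ)))
      lines <- c(lines, fmt("HETATM", paste0("C", j), "LIG",
                            max(resno) + 1L, ligXYZ[j, ], "C"))
  c(lines, "END")
}

#' Generate a synthetic open/closed structure pair with known truth
#'
#' Builds the fixture geometry described in [fixtureSpec()], writes both
#' states as PDB text, reads them back through [readStructure()] and
#' [pairStates()] (so the fixture also exercises the parsing path), and
#' returns the pair together with a truth record: the planted hinge
#' (linker) indices, lobe membership, and the residues within 6 Angstrom of
#' the planted ligand.
#'
#' @param spec a [fixtureSpec()]
#' @return list(pair, truth, openPDB, closedPDB, sequence)
#' @export
makeStructurePair <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  nl <- spec$nPerLobe; L <- spec$linkerLen
  n <- 2L * nl + L
  .withSeed(spec$seed, {
    seqv <- sample(.AA1, n, replace = TRUE)
    built <- NULL
    for (attempt in 1:10) {
      jitterScale <- 0.15 + 0.05 * (attempt - 1)
      A <- .sphericalSpiral(nl)
      B <- .sphericalSpiral(nl)[nl:1, ]
      R <- sqrt(max(rowSums(A^2)))
      d <- R + 2.3
      A[, 1] <- A[, 1] - d
      B[, 1] <- B[, 1] + d
      p0 <- A[nl, ]; p1 <- B[1, ]
      lin <- t(vapply(seq_len(L), function(j) p0 + (p1 - p0) * j / (L + 1),
                      numeric(3)))
      lin[, 3] <- lin[, 3] - 2.0 * sin(pi * seq_len(L) / (L + 1))
      ## relax linker points off the lobe surfaces (keeps >= 2.8 A clearance)
      lobes <- rbind(A, B)
      for (rep in 1:8) {
        moved <- FALSE
        for (j in seq_len(L)) {
          v <- sweep(lobes, 2, lin[j, ], "-")
          dd <- sqrt(rowSums(v^2))
          k <- which.min(dd)
          if (dd[k] < 2.8) {
            lin[j, ] <- lobes[k, ] - v[k, ] / dd[k] * 2.8
            moved <- TRUE
          }
        }
        if (!moved) break
      }
      closed <- rbind(A, lin, B)
      closed <- closed + matrix(stats::runif(3 * n, -jitterScale, jitterScale), n, 3)
      ## open the clamshell: progressive rotation of linker + lobe B about
      ## an axis through the linker midpoint
      m <- colMeans(lin)
      idxLin <- nl + seq_len(L); idxB <- (nl + L + 1L):n
      cA <- colMeans(closed[seq_len(nl), , drop = FALSE])
      best <- NULL
      for (sgn in c(1, -1)) {
        o <- closed
        rot <- function(rows, frac) {
          Rm <- .rotationMatrix(c(0, 1, 0), sgn * frac * spec$closureAngle * pi / 180)
          sweep(sweep(closed[rows, , drop = FALSE], 2, m) %*% t(Rm), 2, m, "+")
        }
        for (j in seq_len(L)) o[idxLin[j], ] <- rot(idxLin[j], j / (L + 1))
        o[idxB, ] <- rot(idxB, 1)
        dd <- sqrt(sum((colMeans(o[idxB, , drop = FALSE]) - cA)^2))
        if (is.null(best) || dd > best$dd) best <- list(o = o, dd = dd)
      }
      open <- best$o
      if (min(stats::dist(closed)) >= 2 && min(stats::dist(open)) >= 2) {
        built <- list(open = open, closed = closed, m = m)
        break
      }
    }
    if (is.null(built)) stop("fixture geometry clash after 10 attempts")

    lig <- NULL
    if (spec$ligand) {
      cleft <- (colMeans(built$closed[seq_len(nl), , drop = FALSE]) +
                colMeans(built$closed[(nl + L + 1L):n, , drop = FALSE])) / 2
      tet <- rbind(c(0.8, 0.8, 0.8), c(-0.8, -0.8, 0.8),
                   c(-0.8, 0.8, -0.8), c(0.8, -0.8, -0.8)) * 0.9
      lig <- sweep(tet, 2, cleft, "+")
    }
    resnoOpen <- seq_len(n)
    resnoClosed <- seq_len(n) + spec$closedOffset
    hdr <- sprintf("fixture seed=%d nPerLobe=%d linkerLen=%d closureAngle=%g",
                   spec$seed, nl, L, spec$closureAngle)
    openPDB <- .pdbLines(built$open, .pseudoCB(built$open), seqv, resnoOpen,
                         header = paste(hdr, "state=open"))
    closedPDB <- .pdbLines(built$closed, .pseudoCB(built$closed), seqv,
                           resnoClosed, ligXYZ = lig,
                           header = paste(hdr, "state=closed"))
    pair <- pairStates(readStructure(openPDB, "open"),
                       readStructure(closedPDB, "closed"))
    ## truth: planted pocket from the raw closed geometry
    pocket <- integer(0)
    if (!is.null(lig)) {
      ## same atom set as the written PDB: CA everywhere, CB except glycine
      hasCB <- seqv != "G"
      allAtoms <- rbind(built$closed, .pseudoCB(built$closed)[hasCB, , drop = FALSE])
      resOf <- c(seq_len(n), seq_len(n)[hasCB])
      d2 <- outer(rowSums(allAtoms^2), rowSums(lig^2), "+") -
        2 * allAtoms %*% t(lig)
      pocket <- sort(unique(resOf[rowSums(d2 <= 36 + 1e-9) > 0]))
    }
    list(pair = pair,
         truth = list(hinge = nl + seq_len(L), lobeA = seq_len(nl),
                      lobeB = (nl + L + 1L):n, pocket = pocket,
                      seed = spec$seed),
         openPDB = openPDB, closedPDB = closedPDB,
         sequence = paste(seqv, collapse = ""))
  })
}

#' Generate a companion alignment with planted conservation
#'
#' Conserved columns carry the wild-type identity in every row; variable
#' columns sample 3-6 identities (wild type favoured) with a small gap
#' fraction. The query (first row) is exactly the wild-type sequence.
#'
#' @param wtSeq one-letter wild-type sequence
#' @param spec a [fixtureSpec()] (uses msaRows, conservedFraction, seed)
#' @return list(msa = [DesignMSA], fasta = character lines,
#'   conservedColumns = integer vector)
#' @export
makeMSA <- function(wtSeq, spec = fixtureSpec()) {
  seqv <- strsplit(wtSeq, "")[[1]]
  n <- length(seqv); rows <- spec$msaRows
  .withSeed(spec$seed + 1000003L, {
    nCons <- round(spec$conservedFraction * n)
    consCols <- sort(sample.int(n, nCons))
    m <- matrix("", rows, n)
    m[1, ] <- seqv
    for (c in seq_len(n)) {
      if (c %in% consCols) {
        m[, c] <- seqv[c]
      } else {
        k <- sample(3:6, 1)
        ids <- unique(c(seqv[c], sample(setdiff(.AA1, seqv[c]), k - 1)))
        pr <- c(0.45, rep(0.55 / (length(ids) - 1), length(ids) - 1))
        m[2:rows, c] <- sample(ids, rows - 1, replace = TRUE, prob = pr)
        gap <- stats::runif(rows - 1) < 0.03
        m[2:rows, c][gap] <- "-"
      }
    }
    nms <- c("query", sprintf("homolog%03d", seq_len(rows - 1)))
    fasta <- as.vector(rbind(paste0(">", nms), apply(m, 1, paste, collapse = "")))
    list(msa = new("DesignMSA", seqs = m, names = nms, queryRow = 1L),
         fasta = fasta, conservedColumns = consCols)
  })
}

#' Plant ddG tables with known class structure
#'
#' Assigns each candidate substitution to one of four classes --
#' both-stabilizing, both-destabilizing, stabilizing only in the open
#' state, stabilizing only in the closed state -- with exact class quotas
#' (largest-remainder rounding of the spec fractions), and draws energies
#' from disjoint ranges per class: stabilizing values in (-4.2, -0.5),
#' destabilizing in (0.4, 3.5). The truth record lists class membership, so
#' filter correctness can be scored exactly.
#'
#' @param candidates data.frame(position, wt, mut)
#' @param spec a [fixtureSpec()] (uses seed and classFractions)
#' @return list(open, closed, truth) with per-state ddG tables and a class
#'   factor aligned with \code{candidates}
#' @export
plantDdg <- function(candidates, spec = fixtureSpec()) {
  n <- nrow(candidates)
  fr <- spec$classFractions
  quota <- floor(fr * n)
  rem <- n - sum(quota)
  if (rem > 0) {
    extra <- order(fr * n - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1
  }
  .withSeed(spec$seed + 2000003L, {
    cls <- sample(rep(names(fr), times = quota))
    stab <- function(k) stats::runif(k, -4.2, -0.5)
    destab <- function(k) stats::runif(k, 0.4, 3.5)
    ddgO <- ddgC <- numeric(n)
    for (cl in names(fr)) {
      i <- which(cls == cl); k <- length(i)
      ddgO[i] <- switch(cl, both_stabilizing = stab(k),
                        both_destabilizing = destab(k),
                        open_only = stab(k), closed_only = destab(k))
      ddgC[i] <- switch(cl, both_stabilizing = stab(k),
                        both_destabilizing = destab(k),
                        open_only = destab(k), closed_only = stab(k))
    }
    list(open = data.frame(candidates, ddg = round(ddgO, 4)),
         closed = data.frame(candidates, ddg = round(ddgC, 4)),
         truth = factor(cls, levels = names(fr)))
  })
}

#' Write a complete fixture preset
#'
#' Presets: \code{"small"} -- one compact pair for fast tests;
#' \code{"pbplike"} -- one realistic pair with alignment and surrogate ddG
#' tables; \code{"fourprot"} -- four distinct pairs (pbp1..pbp4 with
#' different lobe sizes and closure angles), emulating a four-protein study
#' design. If \code{dir} is given, files (open.pdb, closed.pdb, msa.fasta,
#' ddg_open.tsv, ddg_closed.tsv) are written per protein.
#'
#' @param preset preset name
#' @param dir output directory or NULL for in-memory only
#' @param seed integer master seed
#' @return named list of fixtures (each as returned by
#'   [makeStructurePair()], plus \code{msa} and \code{ddg})
#' @export
fixturePreset <- function(preset = c("pbplike", "small", "fourprot"),
                          dir = NULL, seed = 1) {
  preset <- match.arg(preset)
  specs <- switch(preset,
    small = list(p1 = fixtureSpec(nPerLobe = 18, linkerLen = 3,
                                  closureAngle = 30, seed = seed)),
    pbplike = list(pbp = fixtureSpec(seed = seed)),
    fourprot = list(
      pbp1 = fixtureSpec(nPerLobe = 26, linkerLen = 3, closureAngle = 25,
                         seed = seed + 11L),
      pbp2 = fixtureSpec(nPerLobe = 30, linkerLen = 4, closureAngle = 35,
                         seed = seed + 22L),
      pbp3 = fixtureSpec(nPerLobe = 34, linkerLen = 4, closureAngle = 45,
                         seed = seed + 33L),
      pbp4 = fixtureSpec(nPerLobe = 30, linkerLen = 5, closureAngle = 55,
                         seed = seed + 44L)))
  out <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    fx <- makeStructurePair(sp)
    msa <- makeMSA(fx$sequence, sp)
    ddg <- scanDdg(fx$pair, model = contactModel())
    if (!is.null(dir)) {
      sub <- file.path(dir, nm)
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      writeLines(fx$openPDB, file.path(sub, "open.pdb"))
      writeLines(fx$closedPDB, file.path(sub, "closed.pdb"))
      writeLines(msa$fasta, file.path(sub, "msa.fasta"))
      utils::write.table(ddg$open, file.path(sub, "ddg_open.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(ddg$closed, file.path(sub, "ddg_closed.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    c(fx, list(msa = msa$msa, ddg = ddg, spec = sp))
  })
  names(out) <- names(specs)
  out
}
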