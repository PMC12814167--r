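#' @include AllClasses.R AllGenerics.R structure-io.R
NULL

#' Build the Kirchhoff (connectivity) matrix of a C-alpha network
#'
#' The Gaussian network model places identical springs between every pair of
#' C-alpha atoms closer than a distance cutoff. Its Kirchhoff matrix is the
#' graph Laplacian of that contact graph scaled by the spring constant:
#' off-diagonal entries are -gamma for contacting pairs and 0 otherwise, and
#' each diagonal entry is minus the sum of its row's off-diagonals, so rows
#' sum to zero.
#'
#' @param coords N x 3 matrix of C-alpha coordinates (Angstrom), or a
#'   [ProteinStructure] whose C-alpha coordinates are used.
#' @param cutoff contact distance cutoff in Angstrom (default 10).
#' @param gamma spring constant (default 1).
#' @return N x N symmetric matrix with attributes \code{gamma} and
#'   \code{cutoff}.
#' @examples
#' buildKirchhoff(rbind(c(0, 0, 0), c(5, 0, 0)))   # two residues in contact
#' @export
buildKirchhoff <- function(coords, cutoff = 10, gamma = 1) {
  if (is(coords, "ProteinStructure")) coords <- caCoords(coords)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 residues")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  D <- as.matrix(stats::dist(coords))
  K <- -gamma * (D <= cutoff)
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  dimnames(K) <- NULL
  attr(K, "gamma") <- gamma
  attr(K, "cutoff") <- cutoff
  K
}

#' Eigendecompose a Kirchhoff matrix into a GNM model
#'
#' Eigenvalues are sorted ascending; modes with eigenvalue below
#' \code{zeroTol * max(eigenvalue)} are removed as rigid-body (zero) modes --
#' one per connected component of the contact graph -- and counted. Each
#' retained eigenvector is oriented so that its first non-negligible
#' component is non-negative, making reports deterministic.
#'
#' @param kirchhoff symmetric matrix from [buildKirchhoff()].
#' @param zeroTol relative tolerance for dropping zero modes (default 1e-8).
#' @return a [GNMModel]
#' @export
gnmDecompose <- function(kirchhoff, zeroTol = 1e-8) {
  K <- as.matrix(kirchhoff)
  if (max(abs(K - t(K))) > 1e-10) stop("kirchhoff matrix must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  lam <- rev(e$values)
  V <- e$vectors[, ncol(e$vectors):1, drop = FALSE]
  lamMax <- max(lam)
  if (lamMax <= 0) stop("degenerate model: no positive eigenvalues")
  zero <- lam <= zeroTol * lamMax
  if (all(zero)) stop("degenerate model: all modes numerically zero")
  lam <- lam[!zero]
  V <- V[, !zero, drop = FALSE]
  for (k in seq_len(ncol(V))) {
    lead <- which(abs(V[, k]) > 1e-12)[1]
    if (!is.na(lead) && V[lead, k] < 0) V[, k] <- -V[, k]
  }
  new("GNMModel", kirchhoff = K, eigenvalues = lam, eigenvectors = V,
      nZeroModes = as.integer(sum(zero)),
      gamma = attr(kirchhoff, "gamma") %||% 1,
      cutoff = attr(kirchhoff, "cutoff") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call GNM for a structure
#'
#' Convenience wrapper: [buildKirchhoff()] on the C-alpha trace followed by
#' [gnmDecompose()]. Emits a warning if the contact graph is disconnected
#' (more than one zero mode), which can happen for sparse synthetic traces.
#'
#' @inheritParams buildKirchhoff
#' @inheritParams gnmDecompose
#' @param x a [ProteinStructure] or coordinate matrix
#' @return a [GNMModel]
#' @export
gnmFromStructure <- function(x, cutoff = 10, gamma = 1, zeroTol = 1e-8) {
  model <- gnmDecompose(buildKirchhoff(x, cutoff = cutoff, gamma = gamma),
                        zeroTol = zeroTol)
  if (model@nZeroModes > 1L)
    warning("C-alpha contact graph is disconnected (", model@nZeroModes,
            " components); hinge detection uses mode 1 of the full spectrum")
  model
}

#' Per-residue square fluctuations from the slow modes
#'
#' Computes \eqn{\langle \Delta R_i^2 \rangle \propto
#' \frac{1}{\gamma}\sum_{k=1}^{K} \lambda_k^{-1} u_{k,i}^2} over the K
#' slowest retained (non-zero) modes. With all retained modes this equals the
#' diagonal of the Moore-Penrose pseudo-inverse of the Kirchhoff matrix.
#' Five modes is the profile used for lobe/hinge interpretation; the profile
#' is the inverse picture of local packing density.
#'
#' @param model a [GNMModel]
#' @param nModes number of slow modes to sum (default 5)
#' @return a [FluctuationProfile]
#' @export
squareFluctuations <- function(model, nModes = 5) {
  stopifnot(is(model, "GNMModel"))
  K <- length(model@eigenvalues)
  if (nModes > K)
    stop("nModes = ", nModes, " exceeds the ", K, " retained mode(s)")
  if (nModes < 1L) stop("nModes must be >= 1")
  V <- model@eigenvectors[, seq_len(nModes), drop = FALSE]
  vals <- as.vector(V^2 %*% (1 / model@eigenvalues[seq_len(nModes)])) / model@gamma
  new("FluctuationProfile", values = vals, nModes = as.integer(nModes))
}

#' @describeIn squareFluctuations extract the per-residue values
#' @param profile a [FluctuationProfile]
#' @export
fluctuationValues <- function(profile) {
  stopifnot(is(profile, "FluctuationProfile"))
  profile@values
}

setMethod("show", "FluctuationProfile", function(object) {
  cat("FluctuationProfile:", length(object@values), "residues,",
      object@nModes, "modes; range",
      sprintf("%.4g..%.4g", min(object@values), max(object@values)), "\n")
})

#' Detect hinge residues from the slowest mode
#'
#' Hinges are the pivot points between rigid lobes: positions where the
#' slowest mode's eigenvector changes sign. Every sequence-adjacent pair
#' (i, i+1) with opposite mode-1 signs is a crossing; crossings closer than
#' \code{mergeWindow} residues are merged into one hinge block spanning them,
#' and low-amplitude residues (|u1| below \code{ampFloor} times the maximum
#' amplitude) adjacent to a block are absorbed into it.
#'
#' @param model a [GNMModel] with at least one retained mode
#' @param mergeWindow merge crossings closer than this many residues
#'   (default 2)
#' @param ampFloor amplitude fraction below which flanking residues are
#'   absorbed into a hinge block (default 0 = none)
#' @return a [HingeSet]; empty if mode 1 never changes sign
#' @export
detectHinges <- function(model, mergeWindow = 2, ampFloor = 0) {
  stopifnot(is(model, "GNMModel"))
  if (length(model@eigenvalues) < 1L) stop("model has no retained modes")
  u1 <- model@eigenvectors[, 1]
  n <- length(u1)
  cross <- which(u1[-n] * u1[-1] < 0)
  if (length(cross) == 0L)
    return(new("HingeSet", residues = integer(0),
               crossings = matrix(integer(0), 0, 2)))
  ## merge crossings into blocks
  blockStart <- cross[c(TRUE, diff(cross) >= mergeWindow)]
  blockId <- cumsum(cross %in% blockStart)
  res <- integer(0)
  floorAbs <- ampFloor * max(abs(u1))
  for (b in unique(blockId)) {
    cb <- cross[blockId == b]
    lo <- min(cb); hi <- max(cb) + 1L
    while (lo > 1L && abs(u1[lo - 1L]) <= floorAbs && floorAbs > 0) lo <- lo - 1L
    while (hi < n && abs(u1[hi + 1L]) <= floorAbs && floorAbs > 0) hi <- hi + 1L
    res <- c(res, lo:hi)
  }
  new("HingeSet", residues = sort(unique(res)),
      crossings = cbind(cross, cross + 1L))
}

#' @describeIn detectHinges hinge residue indices
#' @param x a HingeSet
#' @export
setMethod("hingeResidues", "HingeSet", function(x) x@residues)

setMethod("show", "HingeSet", function(object) {
  if (length(object@residues) == 0L) {
    cat("HingeSet: empty (no sign change in mode 1)\n")
  } else {
    cat("HingeSet:", length(object@residues), "residue(s) at",
        paste(object@residues, collapse = ","), "(",
        nrow(object@crossings), "crossing(s) )\n")
  }
})

setMethod("show", "GNMModel", function(object) {
  cat("GNMModel:", nrow(object@kirchhoff), "nodes; cutoff",
      object@cutoff, "A; gamma", object@gamma, ";",
      length(object@eigenvalues), "retained modes,",
      object@nZeroModes, "zero mode(s)\n")
})
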