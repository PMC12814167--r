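#' @include AllClasses.R AllGenerics.R
NULL

#' Read an aligned FASTA multiple sequence alignment
#'
#' Sequences are uppercased and '.' gap characters normalized to '-'.
#' Columns where the query (the design target) carries a gap are dropped, so
#' that MSA positions correspond one-to-one to query positions.
#'
#' @param x path to an aligned FASTA file, or a character vector of FASTA
#'   lines
#' @param query name or row index of the design target (default: first row)
#' @return a [DesignMSA]
#' @export
readMSA <- function(x, query = 1L) {
  if (length(x) > 1L || grepl("\n", x[1]) || grepl("^>", x[1])) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(unlist(strsplit(x, "\n", fixed = TRUE)), tmp)
    x <- tmp
  }
  set <- Biostrings::readBStringSet(x)
  if (length(set) < 2L) stop("an MSA needs at least 2 sequences")
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(w), collapse = ", "))
  rows <- toupper(as.character(set))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  qi <- if (is.character(query)) match(query, names(set)) else as.integer(query)
  if (is.na(qi) || qi < 1L || qi > length(set))
    stop("query sequence '", query, "' not found in the alignment")
  m <- do.call(rbind, strsplit(unname(rows), ""))
  keep <- m[qi, ] != "-"
  new("DesignMSA", seqs = m[, keep, drop = FALSE],
      names = names(set) %||% paste0("seq", seq_along(set)), queryRow = qi)
}

#' @describeIn readMSA query sequence of the alignment
#' @param x a DesignMSA
#' @export
setMethod("proteinSequence", "DesignMSA", function(x)
  paste(x@seqs[x@queryRow, ], collapse = ""))

setMethod("show", "DesignMSA", function(object) {
  cat("DesignMSA:", nrow(object@seqs), "sequences x", ncol(object@seqs),
      "positions; query =", object@names[object@queryRow], "\n")
})

## internal: position-based sequence weights (Henikoff & Henikoff style).
## Exact duplicate rows are collapsed first and share the weight of a single
## observation, so redundant alignments do not inflate any count.
.sequenceWeights <- function(m) {
  rowKey <- apply(m, 1, paste, collapse = "")
  uniq <- !duplicated(rowKey)
  mu <- m[uniq, , drop = FALSE]
  nu <- nrow(mu)
  w <- numeric(nu)
  for (c in seq_len(ncol(mu))) {
    col <- mu[, c]
    obs <- col != "-"
    if (!any(obs)) next
    tab <- table(col[obs])
    k <- length(tab)
    w[obs] <- w[obs] + 1 / (k * as.numeric(tab[col[obs]]))
  }
  if (sum(w) == 0) w[] <- 1
  w <- w * nu / sum(w)
  ## expand back: copies of a duplicated row split its weight
  full <- w[match(rowKey, rowKey[uniq])]
  mult <- as.numeric(table(rowKey)[rowKey])
  full / mult
}

#' Compute a position-specific scoring matrix from an MSA
#'
#' Scores are log2-odds in bits: \eqn{s_{i,a} = \log_2(p_{i,a}/b_a)} with
#' pseudocounted frequencies \eqn{p_{i,a} = (n_{i,a} + \tau b_a)/(N_i + \tau)},
#' where \eqn{n_{i,a}} are (optionally weighted) observation counts,
#' \eqn{N_i} their per-position total, \eqn{b_a} the background frequencies
#' and \eqn{\tau > 0} the pseudocount weight that keeps every score finite.
#'
#' With \code{weighting = "position_based"}, sequences receive
#' position-based weights: each sequence accumulates 1/(k_c * m_c) per
#' column c, where k_c is the number of distinct identities in the column
#' and m_c how many sequences carry that identity; weights are normalized to
#' sum to the number of distinct rows, and exact duplicate rows share one
#' row's weight (so adding a redundant copy changes no score).
#'
#' @param msa a [DesignMSA]
#' @param tau pseudocount weight (default 10)
#' @param background length-20 amino-acid background frequencies in
#'   alphabetical order (default uniform)
#' @param weighting "position_based" (default) or "none" (raw counts)
#' @return a [PSSMatrix]
#' @export
computePSSM <- function(msa, tau = 10, background = rep(1 / 20, 20),
                        weighting = c("position_based", "none")) {
  stopifnot(is(msa, "DesignMSA"))
  weighting <- match.arg(weighting)
  if (tau <= 0) stop("tau must be > 0")
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-9)
    stop("background must be 20 frequencies summing to 1")
  background <- stats::setNames(as.numeric(background), .AA1)
  m <- msa@seqs
  w <- if (weighting == "position_based") .sequenceWeights(m) else rep(1, nrow(m))
  P <- ncol(m)
  counts <- matrix(0, P, 20, dimnames = list(NULL, .AA1))
  for (a in .AA1) counts[, a] <- colSums(w * (m == a))
  Ni <- rowSums(counts)
  p <- (counts + tau * matrix(background, P, 20, byrow = TRUE)) / (Ni + tau)
  scores <- log2(sweep(p, 2, background, "/"))
  rownames(scores) <- as.character(seq_len(P))
  new("PSSMatrix", scores = scores, countsEffective = Ni,
      background = background, tau = tau,
      wildtype = paste(m[msa@queryRow, ], collapse = ""))
}

#' Restrict the design alphabet to evolutionarily tolerated identities
#'
#' Identities that do not occur frequently in the MSA -- PSSM score below
#' zero -- are disallowed at each position; a score of exactly zero is kept.
#' The wild-type identity is always allowed, even where its own score is
#' negative.
#'
#' @param pssm a [PSSMatrix]
#' @param wildtype one-letter wild-type sequence; default: the PSSM's query
#' @return named list (one element per position) of allowed identity vectors
#' @export
allowedIdentities <- function(pssm, wildtype = NULL) {
  stopifnot(is(pssm, "PSSMatrix"))
  wt <- strsplit(wildtype %||% pssm@wildtype, "")[[1]]
  if (length(wt) != nrow(pssm@scores))
    stop("wild-type length ", length(wt), " != ", nrow(pssm@scores), " PSSM positions")
  out <- lapply(seq_along(wt), function(i)
    sort(unique(c(wt[i], .AA1[pssm@scores[i, ] >= 0]))))
  names(out) <- as.character(seq_along(wt))
  out
}

setMethod("show", "PSSMatrix", function(object) {
  cat("PSSMatrix:", nrow(object@scores), "positions x 20; tau =", object@tau,
      "; mean effective count", sprintf("%.1f", mean(object@countsEffective)), "\n")
})

#' Write / read a PSSM as TSV
#'
#' The tab-separated layout is \code{position}, \code{wt}, then one column
#' per amino acid in alphabetical order. [readPSSMTable()] allows importing
#' an externally produced PSSM, bypassing [computePSSM()].
#'
#' @param pssm a [PSSMatrix]
#' @param path output/input file path
#' @return readPSSMTable: a [PSSMatrix] (uniform background, recorded tau 1)
#' @export
writePSSMTable <- function(pssm, path) {
  df <- data.frame(position = seq_len(nrow(pssm@scores)),
                   wt = strsplit(pssm@wildtype, "")[[1]],
                   round(pssm@scores, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePSSMTable
#' @export
readPSSMTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (!all(c("position", "wt", .AA1) %in% names(df)))
    stop("PSSM table needs columns: position, wt, and the 20 amino acids")
  df <- df[order(df$position), , drop = FALSE]
  scores <- as.matrix(df[, .AA1])
  rownames(scores) <- as.character(df$position)
  new("PSSMatrix", scores = scores,
      countsEffective = rep(NA_real_, nrow(scores)),
      background = stats::setNames(rep(1 / 20, 20), .AA1), tau = 1,
      wildtype = paste(df$wt, collapse = ""))
}
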