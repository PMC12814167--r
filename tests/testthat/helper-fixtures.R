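## Shared fixtures, built once per test run and memoised by seed.

.fxCache <- new.env(parent = emptyenv())

cachedFixture <- function(seed = 3, ...) {
  key <- paste0("fx", seed, paste(c(...), collapse = "_"))
  if (is.null(.fxCache[[key]]))
    .fxCache[[key]] <- makeStructurePair(fixtureSpec(seed = seed, ...))
  .fxCache[[key]]
}

## minimal hand-written PDB: one residue, three atoms
miniPDB <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CB  ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
  "END")

## a short helical chain of CA/CB atoms with the given sequence; returns lines
chainPDB <- function(seq1, chain = "A", startRes = 1L, extra = character(0)) {
  n <- nchar(seq1)
  seqv <- strsplit(seq1, "")[[1]]
  t <- seq_len(n)
  ca <- cbind(2.3 * cos(t * 100 * pi / 180), 2.3 * sin(t * 100 * pi / 180), 1.5 * t)
  lines <- character(0)
  ser <- 0L
  for (i in seq_len(n)) {
    resn <- bio3d::aa123(seqv[i])
    ser <- ser + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      ser, resn, chain, startRes + i - 1L, ca[i, 1], ca[i, 2], ca[i, 3]))
  }
  c(lines, extra, "END")
}

## brute-force neighbour-count oracle for the layer classifier
layerCountOracle <- function(anchor, dirs, i) {
  total <- 0
  for (j in seq_len(nrow(anchor))) {
    if (j == i) next
    v <- anchor[j, ] - anchor[i, ]
    d <- sqrt(sum(v^2))
    f <- if (d <= 9) 1 else if (d >= 11) 0 else (1 + cos(pi * (d - 9) / 2)) / 2
    ct <- sum(v * dirs[i, ]) / max(d, 1e-9)
    g <- min(1, (max(0, ct + 0.5) / 1.5)^2)
    total <- total + f * g
  }
  total
}
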