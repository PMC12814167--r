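fastaLines <- function(seqs, nms = paste0("s", seq_along(seqs)))
  as.vector(rbind(paste0(">", nms), seqs))

test_that("aligned FASTA parsing normalizes gaps and drops query-gap columns", {
  msa <- readMSA(fastaLines(c("ACDEFGHIKL", "ACDEFGHIKL")))
  expect_identical(dim(msa@seqs), c(2L, 10L))
  msa2 <- readMSA(fastaLines(c("AC-EF.HIKL", "ACDEFGHIKL")))
  expect_identical(ncol(msa2@seqs), 8L)          # 2 query gap columns dropped
  expect_identical(proteinSequence(msa2), "ACEFHIKL")
  expect_error(readMSA(fastaLines(c("ACDEF", "ACD"))), "ragged")
  expect_error(readMSA(fastaLines(c("ACDEF", "ACDEF")), query = "nope"), "not found")
})

test_that("PSSM scores follow the pseudocount log-odds formula", {
  ## column holding all 20 identities once, raw counts: observed frequency
  ## equals the uniform background, so every score is exactly
  ## log2(((1 + tau/20) / (20 + tau)) * 20)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  msa <- readMSA(fastaLines(aa))
  pssm <- computePSSM(msa, tau = 10, weighting = "none")
  expected <- log2(((1 + 10 / 20) / (20 + 10)) * 20)
  expect_equal(unname(pssm@scores[1, ]), rep(expected, 20))
  expect_equal(expected, 0)                       # counts match background
  ## identity never observed among 100 raw counts
  msa2 <- readMSA(fastaLines(rep("A", 100)))
  pssm2 <- computePSSM(msa2, tau = 10, weighting = "none")
  expect_equal(unname(pssm2@scores[1, "W"]),
               log2(((0 + 10 / 20) / (100 + 10)) / (1 / 20)))
  expect_lt(pssm2@scores[1, "W"], 0)
  ## prior dominates as tau grows
  pssm3 <- computePSSM(msa2, tau = 1e9, weighting = "none")
  expect_lt(max(abs(pssm3@scores)), 1e-4)
  expect_error(computePSSM(msa2, tau = 0), "tau")
})

test_that("PSSM is invariant to row order and to exact duplicate rows", {
  fx <- cachedFixture(3)
  mk <- makeMSA(fx$sequence, fixtureSpec(seed = 3))
  msa <- mk$msa
  p1 <- computePSSM(msa)
  set.seed(7)
  shuf <- new("DesignMSA",
              seqs = msa@seqs[c(1, sample(2:nrow(msa@seqs))), , drop = FALSE],
              names = msa@names, queryRow = 1L)
  expect_equal(computePSSM(shuf)@scores, p1@scores)
  dup <- new("DesignMSA", seqs = rbind(msa@seqs, msa@seqs[5, ]),
             names = c(msa@names, "dup"), queryRow = 1L)
  expect_equal(computePSSM(dup)@scores, p1@scores, tolerance = 1e-9)
})

test_that("the allowed alphabet keeps scores >= 0 plus the wild type", {
  fx <- cachedFixture(3)
  mk <- makeMSA(fx$sequence, fixtureSpec(seed = 3))
  pssm <- computePSSM(mk$msa)
  allowed <- allowedIdentities(pssm)
  wt <- strsplit(fx$sequence, "")[[1]]
  for (i in seq_along(wt)) {
    expect_true(wt[i] %in% allowed[[i]])          # wild-type rescue
    extra <- setdiff(allowed[[i]], wt[i])
    if (length(extra))
      expect_true(all(pssm@scores[i, extra] >= 0))
    notAllowed <- setdiff(colnames(pssm@scores), allowed[[i]])
    if (length(notAllowed))
      expect_true(all(pssm@scores[i, notAllowed] < 0))
  }
  ## monotone in threshold: a stricter cut keeps a subset
  strict <- lapply(seq_along(wt), function(i)
    sort(unique(c(wt[i], colnames(pssm@scores)[pssm@scores[i, ] >= 1]))))
  for (i in seq_along(wt)) expect_true(all(strict[[i]] %in% allowed[[i]]))
  expect_error(allowedIdentities(pssm, "ACD"), "length")
})

test_that("a score of exactly zero stays allowed", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  msa <- readMSA(fastaLines(aa))                  # every score exactly 0
  pssm <- computePSSM(msa, tau = 10, weighting = "none")
  allowed <- allowedIdentities(pssm, "A")
  expect_identical(allowed[["1"]], sort(aa))
})

test_that("fully conserved alignments allow only the wild type", {
  fx <- cachedFixture(3)
  mk <- makeMSA(fx$sequence, fixtureSpec(seed = 3, conservedFraction = 1))
  allowed <- allowedIdentities(computePSSM(mk$msa))
  wt <- strsplit(fx$sequence, "")[[1]]
  expect_identical(unname(lengths(allowed)), rep(1L, length(wt)))
  expect_identical(unname(unlist(allowed)), wt)
})

test_that("PSSM tables round-trip through the TSV writer", {
  fx <- cachedFixture(3)
  pssm <- computePSSM(makeMSA(fx$sequence, fixtureSpec(seed = 3))$msa)
  path <- tempfile(fileext = ".tsv")
  writePSSMTable(pssm, path)
  back <- readPSSMTable(path)
  expect_equal(back@scores, pssm@scores, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back@wildtype, pssm@wildtype)
})
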