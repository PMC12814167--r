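test_that("fixture generation is deterministic and validates its spec", {
  a <- makeStructurePair(fixtureSpec(seed = 7))
  b <- makeStructurePair(fixtureSpec(seed = 7))
  expect_identical(a$openPDB, b$openPDB)
  expect_identical(a$closedPDB, b$closedPDB)
  c <- makeStructurePair(fixtureSpec(seed = 8))
  expect_false(identical(a$openPDB, c$openPDB))
  expect_error(fixtureSpec(nPerLobe = 10), ">= 15")
  expect_error(fixtureSpec(closureAngle = 120), "0..90")
})

test_that("zero closure angle leaves the two states identical", {
  fx <- makeStructurePair(fixtureSpec(seed = 5, closureAngle = 0))
  expect_equal(unname(caCoords(openState(fx$pair))),
               unname(caCoords(closedState(fx$pair))), tolerance = 1e-3)
})

test_that("the planted linker is recovered by hinge detection", {
  fx <- makeStructurePair(fixtureSpec(nPerLobe = 30, linkerLen = 4,
                                      closureAngle = 35, seed = 7))
  h <- hingeResidues(detectHinges(gnmFromStructure(openState(fx$pair))))
  win <- (min(fx$truth$hinge) - 2):(max(fx$truth$hinge) + 2)
  expect_gt(length(h), 0)
  expect_true(all(h %in% win))
})

test_that("MSA fixtures are deterministic with bounded gaps", {
  fx <- cachedFixture(3)
  m1 <- makeMSA(fx$sequence, fixtureSpec(seed = 3))
  m2 <- makeMSA(fx$sequence, fixtureSpec(seed = 3))
  expect_identical(m1$fasta, m2$fasta)
  expect_identical(proteinSequence(m1$msa), fx$sequence)
  expect_lt(mean(m1$msa@seqs == "-"), 0.05)
  ## conserved columns keep the wild type everywhere
  seqv <- strsplit(fx$sequence, "")[[1]]
  for (cc in m1$conservedColumns)
    expect_true(all(m1$msa@seqs[, cc] == seqv[cc]))
  ## round-trips through the FASTA reader
  back <- readMSA(m1$fasta, query = "query")
  expect_identical(back@seqs, m1$msa@seqs)
})

test_that("planted ddG classes have exact quotas and drive the filter", {
  fx <- cachedFixture(3)
  seqv <- strsplit(fx$sequence, "")[[1]]
  cand <- data.frame(position = rep(6:45, each = 5))
  cand$wt <- seqv[cand$position]
  set.seed(11)
  cand$mut <- vapply(seq_len(nrow(cand)), function(i)
    sample(setdiff(c("A", "C", "D", "E", "F", "G"), cand$wt[i]), 1), "")
  cand <- cand[!duplicated(cand[c("position", "mut")]), ]
  spec <- fixtureSpec(seed = 3)
  pd <- plantDdg(cand, spec)
  expect_identical(nrow(pd$open), nrow(cand))
  ## deterministic class quotas (largest-remainder of the spec fractions)
  n <- nrow(cand)
  tab <- table(pd$truth)
  expect_identical(sum(tab), as.integer(n))
  for (cl in names(spec$classFractions))
    expect_lte(abs(tab[[cl]] - spec$classFractions[[cl]] * n), 1)
  ## same seed -> identical tables
  pd2 <- plantDdg(cand, spec)
  expect_identical(pd$open, pd2$open)
  ## the two-state filter recovers exactly the planted both-stabilizing class
  rec <- loadDdgTables(pd$open, pd$closed, fx$pair)
  kept <- twoStateFilter(rec)
  planted <- pd$open[pd$truth == "both_stabilizing", c("position", "mut")]
  expect_identical(paste(sort(paste(kept$position, kept$mut))),
                   paste(sort(paste(planted$position, planted$mut))))
})

test_that("fixture presets write files the readers accept unchanged", {
  dir <- tempfile("preset")
  fp <- fixturePreset("small", dir = dir, seed = 2)
  expect_identical(names(fp), "p1")
  files <- list.files(file.path(dir, "p1"))
  expect_setequal(files, c("open.pdb", "closed.pdb", "msa.fasta",
                           "ddg_open.tsv", "ddg_closed.tsv"))
  pair <- pairStates(readStructure(file.path(dir, "p1", "open.pdb")),
                     readStructure(file.path(dir, "p1", "closed.pdb")))
  expect_identical(nResidues(pair), nResidues(fp$p1$pair))
  msa <- readMSA(file.path(dir, "p1", "msa.fasta"))
  expect_identical(proteinSequence(msa), fp$p1$sequence)
  rec <- loadDdgTables(file.path(dir, "p1", "ddg_open.tsv"),
                       file.path(dir, "p1", "ddg_closed.tsv"), pair)
  expect_gt(nrow(rec), 0)
  unlink(dir, recursive = TRUE)
})
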