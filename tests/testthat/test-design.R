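## small deterministic candidate tables against the seed-3 fixture
ddgTables <- function(pair, positions, muts, ddgO, ddgC) {
  seqv <- strsplit(proteinSequence(pair), "")[[1]]
  wt <- seqv[match(positions, residueNumbers(openState(pair)))]
  list(open = data.frame(position = positions, wt = wt, mut = muts, ddg = ddgO),
       closed = data.frame(position = positions, wt = wt, mut = muts, ddg = ddgC))
}

test_that("ddG tables join on candidate identity and validate the wild type", {
  fx <- cachedFixture(3)
  seqv <- strsplit(fx$sequence, "")[[1]]
  tb <- ddgTables(fx$pair, c(10L, 20L, 30L), c("A", "C", "D"),
                  c(-1, -2, -3), c(-0.5, 0.5, -3))
  rec <- loadDdgTables(tb$open, tb$closed, fx$pair)
  expect_identical(nrow(rec), 3L)
  expect_identical(names(rec), c("position", "wt", "mut", "ddg_open", "ddg_closed"))
  ## candidate present only in the open table is dropped with a warning
  tb$open <- rbind(tb$open, data.frame(position = 40L, wt = seqv[40], mut = "E", ddg = -2))
  expect_warning(rec2 <- loadDdgTables(tb$open, tb$closed, fx$pair), "1 candidate")
  expect_identical(nrow(rec2), 3L)
  ## wild-type mismatch errors with the position named
  bad <- tb$closed
  bad$wt[1] <- setdiff(c("A", "C"), bad$wt[1])[1]
  expect_error(loadDdgTables(tb$open, bad, fx$pair), "position 10")
})

test_that("the two-state filter keeps strictly both-negative candidates", {
  rec <- data.frame(position = 1:4, wt = "A", mut = "C",
                    ddg_open = c(-1.5, -2.0, 0.0, -0.1),
                    ddg_closed = c(-0.3, 0.5, -1.0, -0.0001))
  kept <- twoStateFilter(rec)
  expect_identical(kept$position, c(1L, 4L))      # (0, -1) removed: strict sign
})

test_that("cutoff enumeration follows thresholds, fixing, and tie-breaks", {
  rec <- data.frame(position = c(5L, 5L, 8L, 9L), wt = "A",
                    mut = c("C", "D", "E", "F"),
                    ddg_open = c(-2, -3, -3.0, -5), ddg_closed = c(-2, -3, -3.0, -5))
  per <- enumerateCutoffDesigns(rec, scoreOf = "open")
  ## score -3.0 present at cutoffs >= -2.88, absent at -4 and -3.20
  expect_false(8L %in% per[["-4"]]$position)
  expect_false(8L %in% per[["-3.2"]]$position)
  expect_true(8L %in% per[["-2.88"]]$position)
  ## per-position winner is the lowest score
  expect_identical(per[["-2"]]$mut[per[["-2"]]$position == 5L], "D")
  ## fixed positions are excluded
  perFix <- enumerateCutoffDesigns(rec, fixed = 9L, scoreOf = "open")
  expect_false(9L %in% perFix[["0"]]$position)
  ## alphabetical tie-break at equal scores
  tie <- data.frame(position = 1L, wt = "A", mut = c("F", "C"),
                    ddg_open = c(-2, -2), ddg_closed = c(-2, -2))
  perTie <- enumerateCutoffDesigns(tie, scoreOf = "open")
  expect_identical(perTie[["0"]]$mut, "C")
  expect_error(enumerateCutoffDesigns(rec, cutoffs = c(0, -1)), "ascending")
})

test_that("per-cutoff sets equal brute force and grow monotonically", {
  fx <- cachedFixture(3)
  pos <- rep(6:55, each = 4)
  set.seed(99)
  muts <- unlist(lapply(1:50, function(i) sample(setdiff(c("A", "C", "D", "E", "F"),
    strsplit(fx$sequence, "")[[1]][i + 5]), 4)))
  tb <- ddgTables(fx$pair, pos, muts,
                  round(runif(200, -5, 1), 3), round(runif(200, -5, 1), 3))
  rec <- loadDdgTables(tb$open, tb$closed, fx$pair)
  expect_identical(nrow(rec), 200L)
  per <- enumerateCutoffDesigns(rec, scoreOf = "max_of_both")
  cuts <- as.numeric(names(per))
  prev <- character(0)
  for (ci in seq_along(cuts)) {
    ## brute-force oracle: filter then per-position argmin with tie-break
    sc <- pmax(rec$ddg_open, rec$ddg_closed)
    pool <- rec[sc <= cuts[ci], ]
    pool$score <- sc[sc <= cuts[ci]]
    ref <- do.call(rbind, lapply(split(pool, pool$position), function(g) {
      g <- g[order(g$score, g$mut), ]
      g[1, ]
    }))
    got <- per[[ci]]
    expect_identical(got$position, sort(unique(pool$position)))
    if (nrow(got))
      expect_identical(paste(got$position, got$mut),
                       paste(ref$position, ref$mut))
    ## monotone non-decreasing along the ascending ladder
    expect_true(all(prev %in% paste(got$position, got$mut, got$score)))
    prev <- paste(got$position, got$mut, got$score)
  }
})

test_that("design selection picks the strictest in-range cutoff", {
  mk <- function(n) data.frame(position = 1:12, wt = "A", mut = "C",
                               score = -1)[seq_len(n), , drop = FALSE]
  per <- list("-4" = mk(2), "-2.88" = mk(5), "0" = mk(12))
  sel <- selectDesign(per, loadRange = c(4, 10), length = 100)
  expect_equal(sel$cutoff, -2.88)
  expect_false(sel$outOfRange)
  ## all loads below range: closest (largest) load, flagged
  per2 <- list("-4" = mk(1), "-2" = mk(2), "0" = mk(3))
  sel2 <- selectDesign(per2, loadRange = c(4, 10), length = 100)
  expect_equal(sel2$cutoff, 0)
  expect_true(sel2$outOfRange)
  expect_error(selectDesign(list("-4" = mk(0)), c(4, 10), 100), "empty")
})

test_that("layer classification matches the neighbour-count oracle", {
  fx <- cachedFixture(3)
  s <- openState(fx$pair)
  labels <- classifyLayer(s)
  fr <- TwoStateDesign:::.sideChainFrames(s)
  for (i in seq(1, nResidues(s), by = 7)) {
    n_i <- layerCountOracle(fr$anchor, fr$dir, i)
    ref <- if (n_i >= 5.2) "core" else if (n_i <= 2.0) "surface" else "boundary"
    expect_identical(unname(labels[as.character(fr$resno[i])]), ref)
  }
  ## an isolated residue has no neighbours and is surface
  iso <- readStructure(c(miniPDB()[2:3],
    "ATOM      4  CA  ALA A   2      40.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CB  ALA A   2      41.500   0.000   0.000  1.00  0.00           C",
    "END"))
  expect_identical(unname(classifyLayer(iso, 2L)), "surface")
  ## geometry-only: identical for the renumbered closed state of an
  ## identical conformation
  fx0 <- makeStructurePair(fixtureSpec(seed = 5, closureAngle = 0))
  expect_identical(unname(classifyLayer(openState(fx0$pair))),
                   unname(classifyLayer(closedState(fx0$pair))))
})

test_that("a hinge-site mutation survives X.3 but is removed in X.4", {
  fx <- cachedFixture(3)
  run0 <- runWorkflow(fx$pair)                    # to learn the hinge positions
  hingePos <- as.integer(names(Filter(function(t) "hinge" %in% t,
                                      run0@fixed[["X.4"]]@provenance)))
  expect_gt(length(hingePos), 0)
  freePos <- setdiff(6:59, fixedPositions(run0@fixed[["X.4"]]))[1:5]
  pos <- c(hingePos[1], freePos)
  seqv <- strsplit(fx$sequence, "")[[1]]
  muts <- ifelse(seqv[pos] == "A", "C", "A")
  tb <- ddgTables(fx$pair, pos, muts, rep(-3, 6), rep(-3, 6))
  run <- runWorkflow(fx$pair, ddgOpen = tb$open, ddgClosed = tb$closed)
  v <- designVariants(run)
  expect_true(hingePos[1] %in% mutations(v$X.3)$position)
  expect_false(hingePos[1] %in% mutations(v$X.4)$position)
  ## with no hinge/interface candidates and no discordance, X.3 == X.4
  tb2 <- ddgTables(fx$pair, freePos, muts[-1], rep(-3, 5), rep(-3, 5))
  run2 <- runWorkflow(fx$pair, ddgOpen = tb2$open, ddgClosed = tb2$closed)
  v2 <- designVariants(run2)
  expect_identical(mutations(v2$X.3)[c("position", "mut")],
                   mutations(v2$X.4)[c("position", "mut")])
})

test_that("the full workflow produces coherent tiers", {
  fx <- cachedFixture(3)
  msa <- makeMSA(fx$sequence, fixtureSpec(seed = 3))$msa
  run <- runWorkflow(fx$pair, msa = msa)
  v <- designVariants(run)
  expect_identical(names(v), c("X.0", "X.1", "X.2", "X.3", "X.4"))
  expect_identical(nrow(mutations(v$X.0)), 0L)
  expect_identical(designedSequence(v$X.0), fx$sequence)
  allowed <- allowedIdentities(computePSSM(msa))
  for (tier in c("X.1", "X.2", "X.3", "X.4")) {
    m <- mutations(v[[tier]])
    ## load bookkeeping is exact
    expect_equal(mutationalLoad(v[[tier]]), 100 * nrow(m) / 64)
    bk <- mutationBookkeeping(fx$sequence, designedSequence(v[[tier]]))
    expect_identical(bk$n, nrow(m))
    expect_identical(bk$positions, sort(m$position))
    ## no fixed position, no disallowed identity
    expect_length(intersect(m$position, fixedPositions(run@fixed[[tier]])), 0)
    for (k in seq_len(nrow(m)))
      expect_true(m$mut[k] %in% allowed[[as.character(m$position[k])]])
  }
  ## X.3/X.4 mutations are stabilizing in both states
  for (tier in c("X.3", "X.4")) {
    m <- mutations(v[[tier]])
    expect_true(all(m$ddg_open < 0 & m$ddg_closed < 0))
  }
  expect_error(runWorkflow(fx$pair, config = list(bogus = 1)), "unknown config")
})

test_that("sequence bookkeeping validates lengths", {
  expect_error(mutationBookkeeping("ACD", "AC"), "length")
  bk <- mutationBookkeeping("ACDEF", "ACDQF")
  expect_identical(bk$n, 1L)
  expect_equal(bk$load, 20)
  expect_identical(bk$wt, "E")
  expect_identical(bk$mut, "Q")
})
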