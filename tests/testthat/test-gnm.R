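test_that("Kirchhoff construction follows the contact definition", {
  K <- buildKirchhoff(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 10, gamma = 1)
  expect_equal(unclass(K)[1:2, 1:2], matrix(c(1, -1, -1, 1), 2),
               ignore_attr = TRUE)
  Kfar <- buildKirchhoff(rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_equal(unclass(Kfar)[1:2, 1:2], matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(buildKirchhoff(rbind(c(0, 0, 0))), "at least 2")
})

test_that("Kirchhoff equals the brute-force double-loop construction", {
  fx <- cachedFixture(9, nPerLobe = 25)
  xyz <- caCoords(openState(fx$pair))[1:50, ]
  K <- buildKirchhoff(xyz)
  n <- nrow(xyz)
  Kref <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 10) Kref[i, j] <- -1
  }
  diag(Kref) <- -rowSums(Kref)
  expect_equal(unclass(K), Kref, ignore_attr = TRUE)
  ## conservation: rows sum to zero exactly for integer gamma
  expect_true(all(rowSums(K) == 0))
})

test_that("decomposition removes zero modes and matches analytic spectra", {
  K <- buildKirchhoff(rbind(c(0, 0, 0), c(5, 0, 0)))
  m <- gnmDecompose(K)
  expect_identical(m@nZeroModes, 1L)
  expect_equal(m@eigenvalues, 2)
  ## two disconnected cliques: one zero mode per connected component
  set.seed(42)
  far <- rbind(matrix(runif(30, 0, 6), 10), matrix(runif(30, 0, 6), 10) + 100)
  m2 <- gnmDecompose(buildKirchhoff(far))
  expect_identical(m2@nZeroModes, 2L)
})

test_that("eigenpairs match an independent dense solver", {
  fx <- cachedFixture(11, nPerLobe = 28)
  K <- buildKirchhoff(caCoords(openState(fx$pair)))
  m <- gnmDecompose(K)
  sv <- svd(unclass(K))                 # independent decomposition route
  lamRef <- sort(sv$d[sv$d > 1e-8 * max(sv$d)])
  expect_equal(m@eigenvalues, lamRef, tolerance = 1e-6)
  ## eigenvector property: K u = lambda u
  for (k in c(1, 2, length(m@eigenvalues))) {
    resid <- unclass(K) %*% m@eigenvectors[, k] -
      m@eigenvalues[k] * m@eigenvectors[, k]
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("all-mode fluctuations equal the pseudo-inverse diagonal", {
  K <- buildKirchhoff(rbind(c(0, 0, 0), c(5, 0, 0)))
  m <- gnmDecompose(K)
  expect_equal(fluctuationValues(squareFluctuations(m, 1)), c(0.25, 0.25))
  ## larger system, oracle via MASS::ginv
  fx <- cachedFixture(11, nPerLobe = 28)
  K2 <- buildKirchhoff(caCoords(openState(fx$pair)))
  m2 <- gnmDecompose(K2)
  all <- fluctuationValues(squareFluctuations(m2, length(m2@eigenvalues)))
  ref <- diag(MASS::ginv(unclass(K2)))
  expect_equal(all, ref, tolerance = 1e-6)
})

test_that("fluctuations are non-negative, normalized, and monotone in modes", {
  fx <- cachedFixture(3)
  m <- gnmDecompose(buildKirchhoff(caCoords(openState(fx$pair))))
  expect_true(all(colSums(m@eigenvectors^2) - 1 < 1e-9))
  prev <- rep(0, nrow(m@kirchhoff))
  for (k in c(1, 3, 5, 10)) {
    cur <- fluctuationValues(squareFluctuations(m, k))
    expect_true(all(cur >= 0))
    expect_true(all(cur - prev >= -1e-12))   # adding modes never decreases
    prev <- cur
  }
  expect_error(squareFluctuations(m, length(m@eigenvalues) + 1), "retained")
})

test_that("hinge detection finds sign crossings of mode 1", {
  mk <- function(u) new("GNMModel", kirchhoff = diag(length(u)),
                        eigenvalues = 1, eigenvectors = cbind(u / sqrt(sum(u^2))),
                        nZeroModes = 1L, gamma = 1, cutoff = 10)
  expect_length(hingeResidues(detectHinges(mk(rep(1, 6)))), 0)
  h <- detectHinges(mk(c(1, 1, 1, -1, -1, -1)))
  expect_identical(hingeResidues(h), c(3L, 4L))
  expect_equal(h@crossings[1, ], c(3L, 4L), ignore_attr = TRUE)
  ## nearby double crossing merges into one block
  h2 <- detectHinges(mk(c(1, 1, -0.05, 1, -1, -1)), mergeWindow = 2)
  expect_identical(hingeResidues(h2), 2:5)
})

test_that("fluctuations and hinges are invariant to eigenvector sign flips", {
  fx <- cachedFixture(3)
  m <- gnmDecompose(buildKirchhoff(caCoords(openState(fx$pair))))
  V <- m@eigenvectors
  V[, 1] <- -V[, 1]
  mFlip <- new("GNMModel", kirchhoff = m@kirchhoff, eigenvalues = m@eigenvalues,
               eigenvectors = V, nZeroModes = m@nZeroModes, gamma = m@gamma,
               cutoff = m@cutoff)
  expect_equal(fluctuationValues(squareFluctuations(m, 5)),
               fluctuationValues(squareFluctuations(mFlip, 5)))
  expect_identical(hingeResidues(detectHinges(m)),
                   hingeResidues(detectHinges(mFlip)))
})

test_that("the two-lobe fixture has hinge minima and lobe-extremity maxima", {
  fx <- cachedFixture(3)
  m <- gnmFromStructure(openState(fx$pair))
  fl <- fluctuationValues(squareFluctuations(m, 5))
  hinge <- fx$truth$hinge
  ## the hinge is a local minimum region; the profile peaks inside a lobe
  expect_lt(mean(fl[hinge]), mean(fl[-hinge]))
  expect_false(which.max(fl) %in% hinge)
  h <- detectHinges(m)
  win <- (min(hinge) - 2):(max(hinge) + 2)
  expect_true(all(hingeResidues(h) %in% win))
})
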