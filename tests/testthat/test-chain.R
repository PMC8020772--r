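# hand-buildable 3x3 likelihood whose first column is (0.1, 0.6, 0.3)
.lik3 <- function(g) new("LikelihoodMatrix", grid = g, probs = rbind(
  c(0.1, 0.45, 0.45), c(0.6, 0.2, 0.2), c(0.3, 0.35, 0.35)))

test_that("posteriorField multiplies likelihood column by prior and normalizes", {
  g <- spatialGrid(3)
  lik <- .lik3(g)
  # flat prior: posterior proportional to the likelihood column
  u <- uniformPrior(g)
  expect_equal(fieldMass(posteriorField(u, lik, 1L)), c(0.1, 0.6, 0.3))
  # delta prior: delta posterior
  d <- densityField(c(0, 1, 0), g)
  expect_equal(fieldMass(posteriorField(d, lik, 1L)), c(0, 1, 0))
  # hand-computed case
  pri <- densityField(c(0.5, 0.3, 0.2), g)
  expect_equal(fieldMass(posteriorField(pri, lik, 1L)),
               c(0.05, 0.18, 0.06) / 0.29)
})

test_that("posteriorField rejects zero-evidence observations", {
  g <- spatialGrid(2)
  lik <- new("LikelihoodMatrix", grid = g, probs = rbind(c(0, 1), c(1, 0)))
  pri <- densityField(c(0, 1), g)
  expect_error(posteriorField(pri, lik, 2L), "degenerate posterior")
})

test_that("transitionKernel reproduces simple closed-form cases", {
  g <- spatialGrid(2)
  eps <- 0.1
  lik <- new("LikelihoodMatrix", grid = g,
             probs = rbind(c(1 - eps, eps), c(eps, 1 - eps)))
  K <- kernelProbs(transitionKernel(uniformPrior(g), lik))
  expect_equal(K, t(K))                       # symmetric kernel
  expect_equal(as.numeric(rep(0.5, 2) %*% K), c(0.5, 0.5))
  # noiseless likelihood: identity kernel
  gid <- spatialGrid(4)
  lid <- new("LikelihoodMatrix", grid = gid, probs = diag(4))
  expect_equal(kernelProbs(transitionKernel(randomPrior(gid, 5), lid)), diag(4))
})

test_that("transitionKernel equals a brute-force triple loop on 4 cells", {
  g <- spatialGrid(4)
  set.seed(11)
  pri <- randomPrior(g, 11)
  W <- matrix(runif(16, 0.1, 1), 4)
  lik <- new("LikelihoodMatrix", grid = g, probs = W / rowSums(W))
  L <- likProbs(lik); pm <- fieldMass(pri)
  Kbf <- matrix(0, 4, 4)
  for (s in 1:4) for (r in 1:4) for (t in 1:4) {
    post <- L[r, t] * pm[r] / sum(L[, t] * pm)
    Kbf[s, r] <- Kbf[s, r] + post * L[s, t]
  }
  expect_equal(kernelProbs(transitionKernel(pri, lik)), Kbf, tolerance = 1e-12)
})

test_that("stationarity and detailed balance hold for all observers", {
  for (g in list(spatialGrid(64), spatialGrid(c(16, 16)))) {
    pri <- randomPrior(g, 21 + nCells(g))
    for (obs in allObservers(pri, 0.06)) {
      K <- transitionKernel(pri, buildLikelihood(obs, g))
      p1 <- propagateChain(K, pri, 1)[[1]]
      expect_lt(sum(abs(fieldMass(p1) - fieldMass(pri))), 1e-8)
      Fm <- fieldMass(pri) * kernelProbs(K)
      expect_lt(max(abs(Fm - t(Fm))), 1e-10)
    }
  }
})

test_that("propagateChain preserves stationary starts and identity kernels", {
  g <- spatialGrid(32)
  pri <- bimodalPrior1d(g)
  K <- transitionKernel(pri, buildLikelihood(efficientObserver(pri, 0.05), g))
  for (p in propagateChain(K, pri, 5))
    expect_lt(sum(abs(fieldMass(p) - fieldMass(pri))), 1e-8)
  Kid <- new("TransitionKernel", grid = g, probs = diag(32))
  start <- randomPrior(g, 3)
  for (p in propagateChain(Kid, start, 3))
    expect_equal(fieldMass(p), fieldMass(start))
})

test_that("KL to the prior is non-increasing and vanishes from a uniform start", {
  g <- spatialGrid(64)
  pri <- bimodalPrior1d(g)
  K <- transitionKernel(pri, buildLikelihood(efficientObserver(pri, 0.05), g))
  kl <- vapply(propagateChain(K, uniformPrior(g), 200),
               klDivergence, 0, q = pri)
  expect_true(all(diff(kl) <= 1e-12))
  expect_lt(kl[200], 1e-3)
})

test_that("sampleChain is deterministic and fixed under a noiseless likelihood", {
  g <- spatialGrid(16)
  pri <- randomPrior(g, 4)
  lid <- new("LikelihoodMatrix", grid = g, probs = diag(16))
  rec <- chainRecords(sampleChain(pri, lid, 0.52, nIter = 6, seed = 1))
  expect_equal(length(unique(rec$x)), 1L)
  lik <- buildLikelihood(efficientObserver(pri, 0.07), g)
  a <- sampleChain(pri, lik, 0.3, nIter = 10, seed = 99)
  b <- sampleChain(pri, lik, 0.3, nIter = 10, seed = 99)
  expect_identical(chainRecords(a), chainRecords(b))
})

test_that("sampled chains match the analytic iterate distribution", {
  g <- spatialGrid(32)
  pri <- bimodalPrior1d(g)
  lik <- buildLikelihood(efficientObserver(pri, 0.06), g)
  ds <- simulateExperiment(pri, lik, nChains = 200, nIter = 10, seed = 17)
  K <- transitionKernel(pri, lik)
  p10 <- propagateChain(K, uniformPrior(g), 10)[[10]]
  emp <- tabulate(pointToCell(iterationPoints(ds, 10), g), 32) / 200
  tv <- sum(abs(emp - fieldMass(p10))) / 2
  expect_lt(tv, 3 * sqrt(32 / 200))
})

test_that("markovDummyCheck flags carry-over but not memoryless observers", {
  g <- spatialGrid(64)
  pri <- bimodalPrior1d(g)
  lik <- buildLikelihood(efficientObserver(pri, 0.06), g)
  base <- simulateExperiment(pri, lik, nChains = 120, nIter = 10, seed = 31)
  expect_error(markovDummyCheck(base, base, g), "no flagged dummy")
  mkv <- simulateExperiment(pri, lik, nChains = 120, nIter = 10, seed = 32,
                            dummyEvery = 1L)
  rMarkov <- markovDummyCheck(mkv, base, g)$correlation
  expect_gt(rMarkov, 0.9)
  co <- simulateExperiment(pri, lik, nChains = 120, nIter = 10, seed = 33,
                           dummyEvery = 1L, carryOver = 0.7)
  coRef <- simulateExperiment(pri, lik, nChains = 120, nIter = 10, seed = 34,
                              carryOver = 0.7)
  rCarry <- markovDummyCheck(co, coRef, g)$correlation
  expect_lt(rCarry, rMarkov)
})
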