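test_that("reproductionMoments: noiseless kernels give zero variance at s", {
  g <- spatialGrid(16)
  pri <- randomPrior(g, 2)
  lid <- new("LikelihoodMatrix", grid = g, probs = diag(16))
  mom <- reproductionMoments(pri, lid, 0.53)
  expect_equal(as.numeric(mom$mean), as.numeric(cellToPoint(pointToCell(0.53, g), g)))
  expect_equal(mom$cov[1, 1], 0)
})

test_that("fixed observer on a uniform prior doubles the encoding variance", {
  g <- spatialGrid(400)
  u <- uniformPrior(g)
  sg <- 0.04
  lik <- buildLikelihood(fixedObserver(sg), g)
  mom <- reproductionMoments(u, lik, 0.5)
  expect_equal(as.numeric(mom$mean), 0.49875, tolerance = 1e-3)  # cell center at 0.5
  expect_equal(mom$cov[1, 1], 2 * sg^2, tolerance = 0.01)
})

test_that("efficient-observer reproductions are biased toward the nearer mode", {
  g <- spatialGrid(128)
  pri <- bimodalPrior1d(g)
  lik <- buildLikelihood(efficientObserver(pri, 0.05), g)
  K <- transitionKernel(pri, lik)
  s <- 0.15  # in the attraction field outside the 0.3 mode
  mom <- reproductionMoments(pri, lik, s, kernel = K)
  expect_gt(mom$mean, s)
})

test_that("predictDprime is antisymmetric, zero at equality, and matches the closed form", {
  g <- spatialGrid(250)
  u <- uniformPrior(g)
  lik <- buildLikelihood(fixedObserver(0.05), g)
  K <- transitionKernel(u, lik)
  expect_equal(predictDprime(u, lik, 0.5, 0.5, kernel = K), 0)
  d12 <- predictDprime(u, lik, 0.55, 0.45, kernel = K)
  d21 <- predictDprime(u, lik, 0.45, 0.55, kernel = K)
  expect_equal(d12, -d21)
  expect_equal(abs(d12), 0.1 / (0.05 * sqrt(2)), tolerance = 0.02)
})

test_that("d' increases with separation for a fixed observer on a uniform prior", {
  g <- spatialGrid(250)
  u <- uniformPrior(g)
  lik <- buildLikelihood(fixedObserver(0.05), g)
  K <- transitionKernel(u, lik)
  d <- vapply(c(0.04, 0.08, 0.12, 0.16),
              function(dl) abs(predictDprime(u, lik, 0.5 - dl / 2, 0.5 + dl / 2,
                                             kernel = K)), 0)
  expect_true(all(diff(d) > 0))
})

test_that("mode-straddling pairs discriminate better only under efficient encoding", {
  g <- spatialGrid(128)
  pri <- bimodalPrior1d(g)
  K <- list(eff = transitionKernel(pri, buildLikelihood(efficientObserver(pri, 0.05), g)),
            fix = transitionKernel(pri, buildLikelihood(fixedObserver(0.05), g)))
  likE <- buildLikelihood(efficientObserver(pri, 0.05), g)
  likF <- buildLikelihood(fixedObserver(0.05), g)
  dl <- 0.06
  atMode <- function(lik, K) abs(predictDprime(pri, lik, 0.3 - dl / 2, 0.3 + dl / 2, kernel = K))
  atTrough <- function(lik, K) abs(predictDprime(pri, lik, 0.5 - dl / 2, 0.5 + dl / 2, kernel = K))
  expect_gt(atMode(likE, K$eff), atTrough(likE, K$eff))
  expect_lt(atMode(likF, K$fix), atTrough(likF, K$fix))
})

test_that("predicted d' maps are flat for a translation-invariant observer", {
  g <- spatialGrid(c(24, 24))
  u <- uniformPrior(g)
  lik <- buildLikelihood(fixedObserver(0.06), g)
  m <- dprimeMapPredicted(u, lik, radius = 0.1)
  V <- dprimeMatrix(m)[8:17, 8:17]  # well away from truncation edges
  expect_lt((max(V) - min(V)) / mean(V), 0.02)
})

test_that("d'-prior correlation is positive for efficient, negative for fixed encoding", {
  g <- spatialGrid(c(32, 32))
  pri <- threeModePrior2d(g)
  pm <- priorToMap(pri)
  mE <- dprimeMapPredicted(pri, buildLikelihood(efficientObserver(pri, 0.06), g),
                           radius = 0.07)
  mF <- dprimeMapPredicted(pri, buildLikelihood(fixedObserver(0.06), g),
                           radius = 0.07)
  expect_gt(correlateMaps(mE, pm, excludeEdge = 6L), 0)
  expect_lt(correlateMaps(mF, pm, excludeEdge = 6L), 0)
})

test_that("dprimeMapPredicted enforces radius and drops edge probes", {
  g <- spatialGrid(c(16, 16))
  pri <- bimodalPrior2d(g)
  lik <- buildLikelihood(efficientObserver(pri, 0.08), g)
  expect_error(dprimeMapPredicted(pri, lik, radius = 0.01), "cell spacing")
  m <- dprimeMapPredicted(pri, lik, radius = 0.2)
  ret <- m@retained
  pts <- dprimePoints(m)
  expect_true(all(pts[ret, ] >= 0.2 & pts[ret, ] <= 0.8))
  expect_true(any(!ret))
  expect_true(all(is.na(dprimeValues(m)[!ret])))
})

test_that("dprimeFromCounts matches the normal-quantile oracle", {
  expect_equal(dprimeFromCounts(10, 10, 10, 10), 0)
  expect_equal(dprimeFromCounts(16, 4, 4, 16), qnorm(0.8) - qnorm(0.2))
  expect_equal(dprimeFromCounts(20, 0, 0, 20), qnorm(0.975) - qnorm(0.025))
  expect_error(dprimeFromCounts(-1, 5, 5, 5), "nonnegative")
  expect_error(dprimeFromCounts(0, 0, 5, 5), "positive")
})

test_that("2AFC simulation plus analysis recovers the generating d' values", {
  g <- spatialGrid(c(16, 16))
  pri <- bimodalPrior2d(g)
  lik <- buildLikelihood(efficientObserver(pri, 0.06), g)
  probes <- gridCenters(spatialGrid(c(6, 6)))
  afc <- simulate2afc(pri, lik, radius = 0.15, probes = probes,
                      nPerPoint = 2000, seed = 8)
  est <- analyze2afc(afc)
  gen <- afc@meta$generatingMap
  expect_equal(dprimeValues(est), dprimeValues(gen)[gen@retained],
               tolerance = 0.08, ignore_attr = TRUE)
})

test_that("chance-level 2AFC data yield d' near zero", {
  g <- spatialGrid(c(16, 16))
  u <- uniformPrior(g)
  lik <- buildLikelihood(fixedObserver(0.06), g)
  # uniform prior fixed observer: flat map; check rates near d'/2 criterion
  probes <- matrix(c(0.5, 0.5), 1)
  afc <- simulate2afc(u, lik, radius = 0.15, probes = probes,
                      nPerPoint = 4000, seed = 3)
  d <- afc@data
  hit <- mean(d$response[d$condition == "shifted"] == "shifted")
  fa <- mean(d$response[d$condition == "same"] == "shifted")
  dp <- dprimeValues(afc@meta$generatingMap)[1]
  expect_lt(abs(hit - pnorm(dp / 2)), 0.03)
  expect_lt(abs(fa - pnorm(-dp / 2)), 0.03)
})

test_that("smoothDprimeMap handles identity, constants, and spikes correctly", {
  g <- spatialGrid(c(12, 12))
  u <- uniformPrior(g)
  lik <- buildLikelihood(fixedObserver(0.1), g)
  m <- dprimeMapPredicted(u, lik, radius = 0.15)
  expect_equal(dprimeValues(smoothDprimeMap(m, 0)), dprimeValues(m))
  # constant map stays constant under smoothing
  mc <- m; mc@values[] <- 1.5; mc@retained[] <- TRUE
  expect_equal(dprimeValues(smoothDprimeMap(mc, 0.1)), rep(1.5, 144))
  # single spike: center value = center kernel weight^2 (separable, renormalized)
  ms <- mc; ms@values[] <- 0; ms@values[6 + 5 * 12] <- 1
  sdSteps <- 0.5  # kernelSd of half a probe step
  step <- diff(sort(unique(ms@points[, 1])))[1]
  sm <- smoothDprimeMap(ms, sdSteps * step)
  k <- dnorm(-2:2, sd = sdSteps); w0 <- k[3] / sum(k)
  expect_equal(dprimeValues(sm)[6 + 5 * 12], w0^2, tolerance = 1e-6)
  expect_error(smoothDprimeMap(m, 0.1, targetResolution = c(6, 6)), "coarser")
  fine <- smoothDprimeMap(m, 0, targetResolution = c(24, 24))
  expect_identical(fine@shape, c(24L, 24L))
  expect_true(fine@interpolated)
})
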