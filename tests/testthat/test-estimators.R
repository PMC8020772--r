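.mkChain <- function(points, id = 1L) {
  data.frame(chain_id = id, iteration = seq_len(nrow(points)) - 1L,
             x = points[, 1], y = points[, 2], is_dummy = FALSE)
}

test_that("nonparametric KDE of a collapsed chain is a lambda-width Gaussian", {
  g <- spatialGrid(c(64, 64))
  x0 <- c(0.453, 0.547)
  pts <- matrix(rep(x0, each = 6), ncol = 2)
  ds <- chainDataset(.mkChain(pts))
  f <- kdeNonparametric(ds, g, lambda = 0.015)
  ref <- makeMixturePrior(list(list(center = x0, cov = 0.015^2, weight = 1)), g)
  expect_lt(max(abs(fieldMass(f) - fieldMass(ref))), 1e-12)
})

test_that("nonparametric KDE is invariant to duplicating chains", {
  g <- spatialGrid(c(32, 32))
  set.seed(6)
  pts <- matrix(runif(12, 0.2, 0.8), ncol = 2)
  one <- chainDataset(.mkChain(pts))
  two <- chainDataset(rbind(.mkChain(pts, 1L), .mkChain(pts, 2L)))
  expect_equal(fieldMass(kdeNonparametric(one, g)),
               fieldMass(kdeNonparametric(two, g)), tolerance = 1e-12)
})

test_that("nonparametric KDE equals a direct mixture-summation oracle", {
  g <- spatialGrid(c(24, 24))
  set.seed(8)
  recs <- do.call(rbind, lapply(1:3, function(i)
    .mkChain(matrix(runif(10, 0.2, 0.8), ncol = 2), i)))
  ds <- chainDataset(recs)
  lambda <- 0.02
  X <- gridCenters(g)
  total <- numeric(nrow(X))
  for (i in 1:3) {
    P <- recs[recs$chain_id == i & recs$iteration >= 1, c("x", "y")]
    mu <- colMeans(P); S <- cov(P) + diag(lambda^2, 2)
    Si <- solve(S)
    D <- sweep(X, 2, as.numeric(mu))
    q <- rowSums((D %*% Si) * D)
    total <- total + exp(-q / 2) / (2 * pi * sqrt(det(S)))
  }
  oracle <- total / sum(total)
  expect_lt(max(abs(fieldMass(kdeNonparametric(ds, g, lambda)) - oracle)), 1e-10)
})

test_that("parametric KDE uses last-iteration points with fixed-width kernels", {
  g <- spatialGrid(c(48, 48))
  pts <- rbind(c(0.2, 0.2), c(0.5, 0.5), c(0.31, 0.74))
  ds <- chainDataset(.mkChain(pts))
  # only the final point contributes
  f <- kdeParametric(ds, g, width = 0.025)
  ref <- makeMixturePrior(list(list(center = c(0.31, 0.74), cov = 0.025^2,
                                    weight = 1)), g)
  expect_lt(max(abs(fieldMass(f) - fieldMass(ref))), 1e-12)
  expect_equal(sum(fieldMass(f)), 1, tolerance = 1e-9)
})

test_that("both KDE estimators return valid density fields on simulated data", {
  g <- spatialGrid(c(16, 16))
  pri <- bimodalPrior2d(g)
  ds <- simulateExperiment(pri, efficientObserver(pri, 0.06), nChains = 40,
                           nIter = 5, seed = 2)
  for (f in list(kdeNonparametric(ds, g), kdeParametric(ds, g, width = 0.04))) {
    expect_true(all(fieldMass(f) >= 0))
    expect_equal(sum(fieldMass(f)), 1, tolerance = 1e-9)
  }
})

test_that("camPredict matches hand-computed interpolation cases", {
  # pure memory and pure prototype
  p2 <- camParams(1, 5, rbind(c(0.1, 0.1), c(0.9, 0.9)))
  expect_equal(as.numeric(camPredict(c(0.4, 0.6), p2)), c(0.4, 0.6))
  p1 <- camParams(0, 5, c(0.7, 0.2))
  expect_equal(as.numeric(camPredict(c(0.4, 0.6), p1)), c(0.7, 0.2))
  # 1D worked example: P = (0, 1), c = 1, w = 0.5, s = 0.25
  pp <- camParams(0.5, 1, matrix(c(0, 1), ncol = 1))
  v1 <- 1 / (1 + exp(-0.5))
  expect_equal(as.numeric(camPredict(matrix(0.25), pp)),
               0.5 * 0.25 + 0.5 * (1 - v1), tolerance = 1e-12)
  expect_equal(as.numeric(camPredict(matrix(0.25), pp)), 0.3138, tolerance = 1e-4)
})

test_that("camFit recovers noise-free single-prototype data exactly", {
  set.seed(4)
  S <- matrix(runif(100), ncol = 2)
  true <- camParams(0.6, 8, c(0.3, 0.7))
  R <- camPredict(S, true)
  fit <- camFit(S, R, M = 1, nRestarts = 5, seed = 2)
  expect_lt(fit$loss, 1e-8)
  expect_equal(fit$params@w, 0.6, tolerance = 0.01)
  expect_lt(matchPrototypes(fit$params@prototypes, true@prototypes)$maxDistance,
            0.01)
})

test_that("camFit recovers multi-prototype structure from noisy data", {
  true <- camParams(0.5, 10, rbind(c(0.25, 0.25), c(0.75, 0.25),
                                   c(0.25, 0.75), c(0.75, 0.75)))
  set.seed(12)
  S <- matrix(runif(1000), ncol = 2)
  R <- pmin(pmax(camPredict(S, true) + matrix(rnorm(1000, sd = 0.01), ncol = 2), 0), 1)
  fit <- camFit(S, R, M = 4, nRestarts = 10, seed = 3)
  mt <- matchPrototypes(fit$params@prototypes, true@prototypes)
  expect_lt(mt$maxDistance, 0.02)
  expect_equal(fit$params@w, 0.5, tolerance = 0.05)
})

test_that("underparameterized CAM fits lose to the true model order", {
  centers <- as.matrix(expand.grid(c(0.15, 0.5, 0.85), c(0.2, 0.8)))[1:6, ]
  true <- camParams(0.4, 15, centers)
  set.seed(21)
  S <- matrix(runif(800), ncol = 2)
  R <- pmin(pmax(camPredict(S, true) + matrix(rnorm(800, sd = 0.005), ncol = 2), 0), 1)
  fit3 <- camFit(S, R, M = 3, nRestarts = 10, seed = 5)
  fit6 <- camFit(S, R, M = 6, nRestarts = 10, seed = 5)
  expect_gt(fit3$loss, fit6$loss)
})

test_that("camFit validates identifiability", {
  S <- matrix(runif(8), ncol = 2)
  expect_error(camFit(S, S, M = 10), "identifiability")
})

test_that("camIterate contracts geometrically to the prototype", {
  p <- camParams(0.5, 5, c(0.6, 0.4))
  tr <- camIterate(p, c(0.2, 0.9), nIter = 10)
  d0 <- sqrt(sum((c(0.2, 0.9) - c(0.6, 0.4))^2))
  dist <- sqrt(rowSums(sweep(tr, 2, c(0.6, 0.4))^2))
  expect_equal(dist, d0 * 0.5^(1:10), tolerance = 1e-12)
  # prototype is a fixed point
  trP <- camIterate(p, c(0.6, 0.4), nIter = 3)
  expect_equal(trP, matrix(rep(c(0.6, 0.4), each = 3), ncol = 2))
})

test_that("symmetric two-prototype iteration stays on the midline, else converges to a basin", {
  p <- camParams(0.5, 10, rbind(c(0.3, 0.5), c(0.7, 0.5)))
  mid <- camIterate(p, c(0.5, 0.5), nIter = 5)
  expect_equal(mid[, 1], rep(0.5, 5))
  psharp <- camParams(0.5, 50, rbind(c(0.3, 0.5), c(0.7, 0.5)))
  offp <- camIterate(psharp, c(0.55, 0.5), nIter = 60)
  expect_equal(as.numeric(offp[60, ]), c(0.7, 0.5), tolerance = 1e-6)
})
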