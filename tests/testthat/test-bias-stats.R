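.attractorDataset <- function(n = 60, proto = c(0.7, 0.7), w = 0.6, seed = 5) {
  set.seed(seed)
  S <- matrix(runif(2 * n, 0.05, 0.95), ncol = 2)
  R <- camPredict(S, camParams(w, 5, proto))
  recs <- rbind(
    data.frame(chain_id = seq_len(n), iteration = 0L, x = S[, 1], y = S[, 2],
               is_dummy = FALSE),
    data.frame(chain_id = seq_len(n), iteration = 1L, x = R[, 1], y = R[, 2],
               is_dummy = FALSE))
  chainDataset(recs)
}

test_that("biasField is zero for identity chains and aggregates to the mean", {
  n <- 30
  set.seed(1)
  S <- matrix(runif(2 * n, 0.1, 0.9), ncol = 2)
  recs <- rbind(
    data.frame(chain_id = 1:n, iteration = 0L, x = S[, 1], y = S[, 2], is_dummy = FALSE),
    data.frame(chain_id = 1:n, iteration = 1L, x = S[, 1], y = S[, 2], is_dummy = FALSE))
  bf <- biasField(chainDataset(recs), 1L)
  expect_true(all(abs(bf@vectors) < 1e-12))
  # single global bin = global mean bias
  ds <- .attractorDataset()
  bfall <- biasField(ds, 1L, binWidth = 1)
  S0 <- iterationPoints(ds, 0L); R1 <- iterationPoints(ds, 1L)
  expect_equal(as.numeric(bfall@vectors), colMeans(R1 - S0), tolerance = 1e-12)
  expect_identical(sum(bfall@counts), 60L)
})

test_that("single-attractor chains produce bias vectors pointing at the prototype", {
  ds <- .attractorDataset(proto = c(0.7, 0.7))
  bf <- biasField(ds, 1L, binWidth = 0.1)
  toProto <- cbind(0.7 - bf@points[, 1], 0.7 - bf@points[, 2])
  dots <- rowSums(bf@vectors * toProto)
  far <- sqrt(rowSums(toProto^2)) > 0.05  # skip bins at the prototype itself
  expect_true(all(dots[far] > 0))
})

test_that("angularCoherence is maximal for aligned fields and ~1 for random ones", {
  pts <- as.matrix(expand.grid(seq(0.1, 0.9, 0.05), seq(0.1, 0.9, 0.05)))
  aligned <- new("BiasField", points = pts,
                 vectors = matrix(rep(c(0.1, 0.05), each = nrow(pts)), ncol = 2),
                 counts = rep(1L, nrow(pts)))
  ac <- angularCoherence(aligned, neighborRadius = 0.08)
  expect_equal(ac$bandRatio, 15)  # 180/12: all pairwise differences are zero
  set.seed(7)
  th <- runif(nrow(pts), -pi, pi)
  random <- new("BiasField", points = pts,
                vectors = 0.1 * cbind(cos(th), sin(th)),
                counts = rep(1L, nrow(pts)))
  acr <- angularCoherence(random, neighborRadius = 0.15)
  expect_gt(acr$nPairs, 2000)
  expect_lt(abs(acr$bandRatio - 1), 0.25)
})

test_that("angularCoherence requires qualifying pairs", {
  lone <- new("BiasField", points = rbind(c(0.1, 0.1), c(0.9, 0.9)),
              vectors = rbind(c(0.1, 0), c(0, 0.1)), counts = c(1L, 1L))
  expect_error(angularCoherence(lone, neighborRadius = 0.05), "no bin pairs")
})

test_that("bootstrapCI is deterministic, degenerate on constants, and covers the mean", {
  ds <- .attractorDataset(n = 40)
  statMean <- function(d) mean(iterationPoints(d, 1L)[, 1])
  a <- bootstrapCI(statMean, ds, nBoot = 200, seed = 11)
  b <- bootstrapCI(statMean, ds, nBoot = 200, seed = 11)
  expect_identical(a, b)
  konst <- bootstrapCI(function(d) 3.7, ds, nBoot = 100, seed = 1)
  expect_equal(konst$lower, 3.7)
  expect_equal(konst$upper, 3.7)
  # coverage of the population mean for iid uniform chain summaries
  hits <- 0; nrep <- 120
  for (r in seq_len(nrep)) {
    set.seed(3000 + r)
    n <- 40
    xs <- runif(n)
    recs <- rbind(
      data.frame(chain_id = 1:n, iteration = 0L, x = 0.5, y = 0.5, is_dummy = FALSE),
      data.frame(chain_id = 1:n, iteration = 1L, x = xs, y = 0.5, is_dummy = FALSE))
    ci <- bootstrapCI(statMean, chainDataset(recs), nBoot = 200, seed = r)
    if (ci$lower <= 0.5 && ci$upper >= 0.5) hits <- hits + 1
  }
  expect_gt(hits / nrep, 0.85)
})

test_that("correlateMaps matches the Pearson formula and validates input", {
  set.seed(2)
  A <- matrix(runif(64), 8)
  B <- matrix(runif(64), 8)
  r <- correlateMaps(A, B, excludeEdge = 0L)
  av <- as.numeric(A); bv <- as.numeric(B)
  rf <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(r, rf, tolerance = 1e-12)
  expect_equal(correlateMaps(A, A, 0L), 1)
  expect_equal(correlateMaps(A, -A + 2, 0L), -1)
  expect_error(correlateMaps(A, matrix(1, 8, 8), 0L), "constant")
  expect_error(correlateMaps(A, B[1:4, 1:4]), "same shape")
})

test_that("disattenuation divides by the root reliability product and caps", {
  expect_equal(disattenuate(0.5, 1, 1), 0.5)
  expect_equal(disattenuate(0.5, 0.8, 0.8), 0.625)
  expect_equal(disattenuate(0.9, 0.5, 0.5), 1)
  expect_equal(disattenuate(-0.9, 0.5, 0.5), -1)
  expect_error(disattenuate(0.5, 0, 1), "reliabilities")
})

test_that("uniformityTest matches chi-square arithmetic and calibrates under the null", {
  # perfectly balanced counts
  pts <- as.matrix(expand.grid((1:4 - 0.5) / 4, (1:4 - 0.5) / 4))
  pts <- pts[rep(1:16, 5), ]
  ut <- uniformityTest(pts, bins = 4L)
  expect_equal(ut$statistic, 0)
  expect_equal(ut$p.value, 1)
  # all N points in one of 16 bins: statistic = 15 N
  one <- matrix(rep(c(0.1, 0.1), each = 80), ncol = 2)
  ut1 <- uniformityTest(one, bins = 4L)
  expect_equal(ut1$statistic, 15 * 80)
  expect_lt(ut1$p.value, 1e-10)
  # null calibration: p-values roughly uniform
  set.seed(13)
  ps <- replicate(60, uniformityTest(matrix(runif(400), ncol = 2), 4L)$p.value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(uniformityTest(matrix(runif(20), ncol = 2), bins = 4L), "too few")
})

test_that("centerOfMassPrior places bumps at region centroids", {
  g <- spatialGrid(c(64, 64))
  mask <- matrix(0L, 20, 20)
  mask[3:6, 3:6] <- 1L                      # square region
  f1 <- centerOfMassPrior(mask, 0.03, g)
  ref <- makeMixturePrior(list(list(center = c(4, 4) / 20, cov = 0.03^2,
                                    weight = 1)), g)
  expect_lt(max(abs(fieldMass(f1) - fieldMass(ref))), 1e-12)
  # two equal regions split the mass equally across the diagonal
  mask2 <- mask; mask2[14:17, 14:17] <- 2L
  f2 <- centerOfMassPrior(mask2, 0.03, g)
  X <- gridCenters(g)
  lowerHalf <- X[, 1] + X[, 2] < 1
  expect_equal(sum(fieldMass(f2)[lowerHalf]), 0.5, tolerance = 1e-6)
  # L-shaped region: centroid lies outside the region, bump goes there anyway
  maskL <- matrix(0L, 20, 20)
  maskL[1:10, 1:2] <- 1L
  maskL[1:2, 3:10] <- 1L
  w <- which(maskL == 1L, arr.ind = TRUE)
  ctr <- c(mean((w[, 1] - 0.5) / 20), mean((w[, 2] - 0.5) / 20))
  fL <- centerOfMassPrior(maskL, 0.02, g)
  peak <- gridCenters(g)[which.max(fieldMass(fL)), ]
  expect_lt(sqrt(sum((peak - ctr)^2)), 0.02)
})
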