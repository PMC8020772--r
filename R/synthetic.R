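#' @include AllClasses.R grid.R observers.R chain.R discrimination.R estimators.R
NULL

#' Gaussian-mixture prior on a grid
#'
#' Builds a normalized mixture-of-Gaussians density field, the package's
#' stand-in for the multimodal spatial priors revealed by transmission
#' chains (modes = landmarks).
#'
#' @param modes list of components, each a list with `center` (point),
#'   `cov` (scalar isotropic variance in 1D, or variance/2x2 covariance in
#'   2D), and `weight` (> 0).
#' @param grid a [SpatialGrid-class].
#' @return a [DensityField-class].
#' @examples
#' g <- spatialGrid(c(32, 32))
#' pri <- makeMixturePrior(list(
#'   list(center = c(0.3, 0.3), cov = 0.08^2, weight = 1),
#'   list(center = c(0.7, 0.7), cov = 0.08^2, weight = 1)), g)
#' @export
makeMixturePrior <- function(modes, grid) {
  if (!length(modes)) stop("at least one mode required")
  total <- numeric(nCells(grid))
  for (m in modes) {
    if (is.null(m$weight)) m$weight <- 1
    if (m$weight <= 0) stop("mode weights must be positive")
    total <- total + m$weight * .gaussOnGrid(m$center, m$cov, grid)
  }
  normalizeField(total, grid)
}

# Vertices of a regular polygon (normalized coords), first vertex at the top.
.shapeVertices <- function(shape, center = c(0.5, 0.5), circumradius = 0.35) {
  nv <- switch(shape, triangle = 3L, square = 4L, pentagon = 5L,
               stop("unknown shape: ", shape))
  # square rotated so edges are axis-aligned; others point upward
  off <- if (shape == "square") pi / 4 else pi / 2
  th <- off + 2 * pi * (seq_len(nv) - 1) / nv
  cbind(center[1] + circumradius * cos(th), center[2] + circumradius * sin(th))
}

# Distance from each point (rows of X) to the outline of the shape.
.outlineDistance <- function(shape, X, center, circumradius) {
  if (shape == "circle") {
    return(abs(sqrt(rowSums(sweep(X, 2, center)^2)) - circumradius))
  }
  V <- .shapeVertices(shape, center, circumradius)
  nv <- nrow(V)
  d <- rep(Inf, nrow(X))
  for (k in seq_len(nv)) {
    a <- V[k, ]; b <- V[k %% nv + 1, ]
    ab <- b - a
    tt <- pmin(pmax(((X[, 1] - a[1]) * ab[1] + (X[, 2] - a[2]) * ab[2]) /
                      sum(ab^2), 0), 1)
    dk <- sqrt((X[, 1] - a[1] - tt * ab[1])^2 + (X[, 2] - a[2] - tt * ab[2])^2)
    d <- pmin(d, dk)
  }
  d
}

#' Shape-outline prior: Gaussian ridges on edges, bumps on vertices
#'
#' Emulates the qualitative structure of spatial memory priors for simple
#' geometric shapes: mass concentrated along the shape's edges with extra
#' bumps at its vertices.
#'
#' @param shape one of "circle", "triangle", "square", "pentagon".
#' @param edgeWeight,vertexWeight nonnegative mixture weights (not both 0;
#'   circles have no vertices).
#' @param width ridge/bump SD in normalized units.
#' @param grid a 2D [SpatialGrid-class].
#' @param center,circumradius shape placement (defaults: centered, 0.35).
#' @return a [DensityField-class].
#' @export
makeShapePrior <- function(shape, edgeWeight = 1, vertexWeight = 1,
                           width = 0.02, grid,
                           center = c(0.5, 0.5), circumradius = 0.35) {
  shape <- match.arg(shape, c("circle", "triangle", "square", "pentagon"))
  if (edgeWeight < 0 || vertexWeight < 0 || edgeWeight + vertexWeight == 0)
    stop("weights must be nonnegative and not both zero")
  X <- gridCenters(grid)
  d <- .outlineDistance(shape, X, center, circumradius)
  total <- edgeWeight * exp(-d^2 / (2 * width^2))
  if (shape != "circle" && vertexWeight > 0) {
    V <- .shapeVertices(shape, center, circumradius)
    for (k in seq_len(nrow(V)))
      total <- total + vertexWeight *
        exp(-rowSums(sweep(X, 2, V[k, ])^2) / (2 * width^2))
  }
  normalizeField(total, grid)
}

#' Grayscale outline image of a simple shape
#'
#' Renders a binary outline raster (1 = outline, 0 = background) for
#' display and demo purposes.
#'
#' @param shape one of "circle", "triangle", "square", "pentagon".
#' @param sizePx image side in pixels (>= 32).
#' @param lineWidth outline thickness in pixels.
#' @param center,circumradius shape placement in normalized units.
#' @return numeric matrix in \[0,1\], indexed (x pixel, y pixel).
#' @export
makeShapeImage <- function(shape, sizePx = 256L, lineWidth = 2,
                           center = c(0.5, 0.5), circumradius = 0.35) {
  shape <- match.arg(shape, c("circle", "triangle", "square", "pentagon"))
  sizePx <- as.integer(sizePx)
  if (sizePx < 32L) stop("sizePx must be >= 32")
  ctr <- (seq_len(sizePx) - 0.5) / sizePx
  X <- as.matrix(expand.grid(ctr, ctr, KEEP.OUT.ATTRS = FALSE))
  d <- .outlineDistance(shape, X, center, circumradius)
  img <- matrix(as.numeric(d <= lineWidth / (2 * sizePx)), sizePx, sizePx)
  if (sum(img) == 0) stop("outline rasterized to nothing; increase lineWidth")
  img
}

.childSeed <- function(seed, i) (as.integer(seed) + 1000003 * i) %% 2147483629L

#' Simulate a full transmission-chain experiment
#'
#' Draws chain seed points uniformly over the domain and runs each chain
#' with [sampleChain()] under the given observer. Each chain uses a child
#' seed derived from `seed` by a fixed splitting rule
#' (`(seed + 1000003 * chain) mod 2147483629`), so any subset of chains is
#' independently reproducible.
#'
#' Optional Markov-violation machinery for method checks: with
#' `dummyEvery > 0`, a uniform dummy trial is interleaved after every
#' `dummyEvery` experimental trials (flagged `is_dummy`; the experimental
#' chain continues from the previous experimental response). With
#' `carryOver > 0` the observer is memory-contaminated: the effective
#' stimulus is `(1 - carryOver) * current + carryOver * previous trial's
#' stimulus`, violating the Markov assumption.
#'
#' @param prior a [DensityField-class].
#' @param observer an [Observer-class] (or a prebuilt
#'   [LikelihoodMatrix-class]).
#' @param nChains number of chains (default 500).
#' @param nIter reproductions per chain (default 20).
#' @param seed integer RNG seed.
#' @param stimulus stimulus identifier stored in the dataset.
#' @param dummyEvery interleave a uniform dummy trial after every this many
#'   experimental trials (0 = none).
#' @param carryOver carry-over mixing weight in \[0, 1) (0 = Markov).
#' @param dequantize report each point as a uniform draw within its grid
#'   cell instead of the cell center. The grid is the model's computational
#'   resolution; cell-center snapping restricts short displacement vectors
#'   to a few lattice directions, which spuriously inflates angular
#'   statistics of bias vectors. Deterministic given `seed`.
#' @return a [ChainDataset-class].
#' @export
simulateExperiment <- function(prior, observer, nChains = 500L, nIter = 20L,
                               seed = 1L, stimulus = "synthetic",
                               dummyEvery = 0L, carryOver = 0,
                               dequantize = FALSE) {
  lik <- if (is(observer, "LikelihoodMatrix")) observer
  else buildLikelihood(observer, prior@grid)
  g <- prior@grid
  K <- nCells(g)
  L <- lik@probs
  pm <- prior@mass
  set.seed(as.integer(seed))
  seedPts <- matrix(stats::runif(nChains * g@ndim), ncol = g@ndim)
  chainSeeds <- vapply(seq_len(nChains), function(i) .childSeed(seed, i), 0)
  oneStep <- function(fromCell, prevStimPoint) {
    # optional carry-over contamination, then encode -> infer -> sample
    if (carryOver > 0 && !is.null(prevStimPoint)) {
      eff <- (1 - carryOver) * cellToPoint(fromCell, g)[1, ] +
        carryOver * prevStimPoint
      fromCell <- pointToCell(eff, g)
    }
    tCell <- sample.int(K, 1L, prob = L[fromCell, ])
    w <- L[, tCell] * pm
    sample.int(K, 1L, prob = w)
  }
  recs <- vector("list", nChains)
  for (i in seq_len(nChains)) {
    set.seed(chainSeeds[i])
    sCell <- pointToCell(seedPts[i, ], g)
    rows <- list()
    sp <- cellToPoint(sCell, g)[1, ]
    rows[[1]] <- data.frame(chain_id = i, iteration = 0L,
                            x = sp[1], y = if (g@ndim == 2L) sp[2] else NA_real_,
                            is_dummy = FALSE)
    cur <- sCell
    prevStim <- NULL
    for (n in seq_len(nIter)) {
      curPoint <- cellToPoint(cur, g)[1, ]
      nxt <- oneStep(cur, prevStim)
      prevStim <- curPoint
      p <- cellToPoint(nxt, g)[1, ]
      rows[[length(rows) + 1L]] <-
        data.frame(chain_id = i, iteration = n,
                   x = p[1], y = if (g@ndim == 2L) p[2] else NA_real_,
                   is_dummy = FALSE)
      cur <- nxt
      if (dummyEvery > 0 && n %% dummyEvery == 0 && n < nIter) {
        dCell <- pointToCell(stats::runif(g@ndim), g)
        dResp <- oneStep(dCell, prevStim)
        prevStim <- cellToPoint(dCell, g)[1, ]
        dp <- cellToPoint(dResp, g)[1, ]
        rows[[length(rows) + 1L]] <-
          data.frame(chain_id = i, iteration = n,
                     x = dp[1], y = if (g@ndim == 2L) dp[2] else NA_real_,
                     is_dummy = TRUE)
      }
    }
    recs[[i]] <- do.call(rbind, rows)
  }
  recs <- do.call(rbind, recs)
  if (dequantize) {
    set.seed(.childSeed(seed, 999983L))
    sp <- g@spacing
    recs$x <- pmin(pmax(recs$x + stats::runif(nrow(recs), -sp[1] / 2, sp[1] / 2),
                        0), 1)
    if (g@ndim == 2L)
      recs$y <- pmin(pmax(recs$y + stats::runif(nrow(recs), -sp[2] / 2, sp[2] / 2),
                          0), 1)
  }
  chainDataset(recs, stimulus = stimulus,
               provenance = "simulated",
               meta = list(grid = as.integer(g@shape), seed = as.integer(seed),
                           observer = if (is(observer, "LikelihoodMatrix"))
                             "precomputed" else class(observer)[1],
                           nChains = nChains, nIter = nIter,
                           dummyEvery = dummyEvery, carryOver = carryOver))
}

#' Simulate a 2AFC same/shifted discrimination dataset
#'
#' For each probe point, the generating sensitivity is the direction-
#' averaged predicted d' at the probe (from [dprimeMapPredicted()]).
#' Responses follow the equal-variance signal-detection model with unbiased
#' criterion: P(respond "shifted" | shifted) = Phi(d'/2) and
#' P(respond "shifted" | same) = Phi(-d'/2). Probes dropped from the
#' predicted map (offsets leaving the domain) are skipped.
#'
#' @param prior a [DensityField-class].
#' @param observer an [Observer-class] or [LikelihoodMatrix-class].
#' @param radius probe offset radius (normalized units).
#' @param probes matrix of probe points (default: all grid centers).
#' @param nPerPoint trials per probe and condition (default 20).
#' @param seed integer RNG seed.
#' @param kernel optional precomputed [TransitionKernel-class] (avoids
#'   rebuilding it across repeated simulations).
#' @return a [TwoAFCDataset-class]; its meta stores the generating map.
#' @export
simulate2afc <- function(prior, observer, radius, probes = NULL,
                         nPerPoint = 20L, seed = 1L, kernel = NULL) {
  lik <- if (is(observer, "LikelihoodMatrix")) observer
  else buildLikelihood(observer, prior@grid)
  map <- dprimeMapPredicted(prior, lik, radius = radius, probes = probes,
                            kernel = kernel)
  keep <- which(map@retained)
  set.seed(as.integer(seed))
  is1d <- ncol(map@points) == 1L
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    dp <- map@values[i]
    pShiftGivenShift <- stats::pnorm(dp / 2)
    pShiftGivenSame <- stats::pnorm(-dp / 2)
    respShift <- stats::runif(nPerPoint) < pShiftGivenShift
    respSame <- stats::runif(nPerPoint) < pShiftGivenSame
    out[[j]] <- data.frame(
      probe_x = unname(map@points[i, 1]),
      probe_y = if (is1d) NA_real_ else unname(map@points[i, 2]),
      condition = rep(c("shifted", "same"), each = nPerPoint),
      response = ifelse(c(respShift, respSame), "shifted", "same"))
  }
  new("TwoAFCDataset", data = do.call(rbind, out), radius = radius,
      meta = list(nPerPoint = as.integer(nPerPoint), seed = as.integer(seed),
                  generatingMap = map))
}
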