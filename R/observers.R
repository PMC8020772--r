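#' @include AllClasses.R AllGenerics.R grid.R
NULL

#' Observer constructors
#'
#' The three encoder models of the Bayesian account of visuospatial memory:
#'
#' * `fixedObserver(sigma)`: isotropic Gaussian sensory noise of constant SD
#'   `sigma` everywhere ("fixed precision"). Predicts biases toward prior
#'   modes but reduced discriminability near them (perceptual magnet).
#' * `efficientObserver(prior, sigmaW)`: constant isotropic noise of SD
#'   `sigmaW` in a perceptually warped coordinate space in which the prior
#'   is uniform. In Euclidean units the noise is skewed toward prior modes:
#'   biased reproductions *and* higher discriminability near modes.
#' * `symmetricObserver(prior, sigma0, alpha)`: symmetric Gaussian noise
#'   whose local SD is `sigma0 * density(x)^(-alpha)` (density relative to
#'   uniform): precise near modes yet unbiased on average. `alpha` defaults
#'   to 1 in 1D and 1/2 in 2D, matching the linear scale factor of a
#'   volume-matching warp so that this model and the efficient model share
#'   local precision and differ only in bias structure.
#'
#' All SDs are in normalized units (fraction of image size).
#'
#' @param sigma,sigmaW,sigma0 positive noise SDs.
#' @param prior a [DensityField-class] spatial prior.
#' @param alpha nonnegative density exponent (see above for default).
#' @return an [Observer-class] object.
#' @examples
#' g <- spatialGrid(64)
#' pri <- makeMixturePrior(list(
#'   list(center = 0.3, cov = 0.08^2, weight = 1),
#'   list(center = 0.7, cov = 0.08^2, weight = 1)), g)
#' obs <- efficientObserver(pri, sigmaW = 0.05)
#' @export
fixedObserver <- function(sigma)
  new("FixedPrecisionObserver", sigma = as.numeric(sigma))

#' @rdname fixedObserver
#' @export
efficientObserver <- function(prior, sigmaW)
  new("EfficientEncodingObserver", prior = prior, sigmaW = as.numeric(sigmaW))

#' @rdname fixedObserver
#' @export
symmetricObserver <- function(prior, sigma0, alpha = NULL) {
  if (is.null(alpha)) alpha <- if (prior@grid@ndim == 1L) 1 else 0.5
  new("SymmetricVariablePrecisionObserver", prior = prior,
      sigma0 = as.numeric(sigma0), alpha = as.numeric(alpha))
}

setMethod("show", "FixedPrecisionObserver", function(object)
  cat(sprintf("FixedPrecisionObserver (sigma = %g)\n", object@sigma)))
setMethod("show", "EfficientEncodingObserver", function(object)
  cat(sprintf("EfficientEncodingObserver (sigmaW = %g, %s prior grid)\n",
              object@sigmaW, paste(object@prior@grid@shape, collapse = " x "))))
setMethod("show", "SymmetricVariablePrecisionObserver", function(object)
  cat(sprintf("SymmetricVariablePrecisionObserver (sigma0 = %g, alpha = %g)\n",
              object@sigma0, object@alpha)))

# Add a tiny mass floor before warping/conditioning so conditional
# distributions never degenerate; perturbation (1e-12/cell) is far below all
# tolerances used downstream.
.floorPrior <- function(prior, eps = 1e-12) {
  m <- prior@mass + eps
  m / sum(m)
}

# Piecewise-linear CDF of a 1D mass vector over [0,1] with n equal cells,
# evaluated at points x. CDF knots sit at cell boundaries; at a cell center
# the value is cumsum(mass) - mass/2, so a uniform prior gives the identity.
.cdf1d <- function(mass, x) {
  n <- length(mass)
  k <- pmin(pmax(ceiling(x * n), 1L), n)
  C <- cumsum(mass)
  lower <- (k - 1) / n
  (C[k] - mass[k]) + mass[k] * (x - lower) * n
}

#' Warp points into the prior-uniformized coordinate space
#'
#' The efficient-encoding model posits constant noise in a coordinate space
#' where the prior is uniform. In 1D this map is the prior's CDF; in 2D it
#' is the triangular (Knothe-Rosenblatt) transform: the first coordinate is
#' mapped through the marginal CDF of axis 1, the second through the
#' conditional CDF of axis 2 given the first coordinate's cell. The
#' pushforward of the prior through this map is uniform on the unit
#' interval/square.
#'
#' @param prior a [DensityField-class]; a floor of 1e-12 mass per cell is
#'   added (and renormalized) before conditioning.
#' @param p a point or matrix of points in the domain.
#' @return matrix of warped coordinates, one row per point, in \[0,1\]^ndim.
#' @examples
#' g <- spatialGrid(256)
#' u <- normalizeField(rep(1, 256), g)
#' warpForward(u, 0.3)  # uniform prior: identity map
#' @export
warpForward <- function(prior, p) {
  g <- prior@grid
  p <- asPoints(p, g@ndim)
  m <- .floorPrior(prior)
  if (g@ndim == 1L) {
    return(matrix(.cdf1d(m, p[, 1]), ncol = 1))
  }
  M <- matrix(m, nrow = g@shape[1], ncol = g@shape[2])
  mx <- rowSums(M)
  u1 <- .cdf1d(mx, p[, 1])
  k1 <- pmin(pmax(ceiling(p[, 1] * g@shape[1]), 1L), g@shape[1])
  u2 <- numeric(nrow(p))
  for (k in unique(k1)) {
    sel <- k1 == k
    cond <- M[k, ] / mx[k]
    u2[sel] <- .cdf1d(cond, p[sel, 2])
  }
  cbind(u1, u2, deparse.level = 0)
}

#' Likelihood-matrix accessors
#'
#' @param x a [LikelihoodMatrix-class] or [TransitionKernel-class].
#' @return `likProbs`/`kernelProbs` return the underlying row-stochastic
#'   matrix; `likGrid`/`kernelGrid` the grid.
#' @export
likProbs <- function(x) x@probs

#' @rdname likProbs
#' @export
likGrid <- function(x) x@grid

setMethod("show", "LikelihoodMatrix", function(object)
  cat(sprintf("LikelihoodMatrix: %d x %d on a %s grid\n",
              nrow(object@probs), ncol(object@probs),
              paste(object@grid@shape, collapse = " x "))))

# Squared Euclidean distance matrix between two point sets (rows).
.sqDistMatrix <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

.rowNormalize <- function(W, what) {
  rs <- rowSums(W)
  if (any(rs == 0) || any(!is.finite(rs)))
    stop("numeric underflow while building ", what,
         ": a likelihood row vanished; increase sigma or coarsen the grid")
  W / rs
}

.checkGridMatch <- function(prior, grid) {
  if (!identical(prior@grid@shape, grid@shape))
    stop("observer's prior grid does not match the requested grid")
}

#' @describeIn buildLikelihood rows are isotropic Gaussians of SD
#'   `sigma` centered on each cell center, truncated to the domain and
#'   renormalized over in-domain cells.
#' @export
setMethod("buildLikelihood", "FixedPrecisionObserver", function(observer, grid) {
  X <- gridCenters(grid)
  W <- exp(-.sqDistMatrix(X, X) / (2 * observer@sigma^2))
  new("LikelihoodMatrix", grid = grid,
      probs = .rowNormalize(W, "fixed-precision likelihood"))
})

#' @describeIn buildLikelihood rows are isotropic Gaussians of SD `sigmaW`
#'   in warped coordinates: every cell center is pushed through
#'   [warpForward()], the Gaussian is evaluated at the warped centers, and
#'   each row is renormalized over cells (the pullback to the original grid).
#' @export
setMethod("buildLikelihood", "EfficientEncodingObserver", function(observer, grid) {
  .checkGridMatch(observer@prior, grid)
  Wc <- warpForward(observer@prior, gridCenters(grid))
  W <- exp(-.sqDistMatrix(Wc, Wc) / (2 * observer@sigmaW^2))
  new("LikelihoodMatrix", grid = grid,
      probs = .rowNormalize(W, "efficient-encoding likelihood"))
})

#' @describeIn buildLikelihood row i is an isotropic Gaussian of local SD
#'   `sigma0 * density(x_i)^(-alpha)` (density = mass / cell volume, i.e.
#'   relative to uniform), truncated and renormalized.
#' @export
setMethod("buildLikelihood", "SymmetricVariablePrecisionObserver",
  function(observer, grid) {
    .checkGridMatch(observer@prior, grid)
    X <- gridCenters(grid)
    vol <- prod(grid@spacing)
    dens <- .floorPrior(observer@prior) / vol
    sdLoc <- observer@sigma0 * dens^(-observer@alpha)
    W <- exp(-.sqDistMatrix(X, X) / (2 * sdLoc^2))  # sdLoc recycles by row
    new("LikelihoodMatrix", grid = grid,
        probs = .rowNormalize(W, "symmetric-variable likelihood"))
  })
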