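#' @include AllClasses.R grid.R chain.R
NULL

# Evaluate an (unnormalized) Gaussian density at all grid centers.
# cov: scalar (isotropic variance) in 1D, or 2x2 matrix in 2D.
.gaussOnGrid <- function(center, cov, grid) {
  X <- gridCenters(grid)
  if (grid@ndim == 1L) {
    v <- as.numeric(cov)
    exp(-(X[, 1] - center[1])^2 / (2 * v)) / sqrt(2 * pi * v)
  } else {
    if (length(cov) == 1) cov <- diag(as.numeric(cov), 2)
    R <- tryCatch(chol(cov), error = function(e)
      stop("covariance matrix is not positive-definite"))
    D <- sweep(X, 2, center)
    z <- backsolve(R, t(D), transpose = TRUE)
    q <- colSums(z^2)
    exp(-q / 2) / (2 * pi * prod(diag(R)))
  }
}

#' Nonparametric KDE of the spatial prior from chain data
#'
#' Per-chain Gaussian summaries: for chain i, the empirical mean
#' \eqn{\mu_i} and covariance \eqn{\Sigma_i} over its reproductions (all
#' iterations >= 1) are computed, the covariance is regularized as
#' \eqn{\Sigma_i' = \Sigma_i + \lambda^2 I}, and the estimate is the
#' normalized equal-weight mixture of the per-chain Gaussians evaluated on
#' the grid. Chains with a single point (or identical points) fall back to
#' the isotropic regularizer \eqn{\lambda^2 I}.
#'
#' @param dataset a [ChainDataset-class].
#' @param grid evaluation [SpatialGrid-class].
#' @param lambda regularizer in normalized units; 0.015 suits shape-like
#'   stimuli, 0.020 natural-image-like ones.
#' @return a [DensityField-class] summing to 1.
#' @export
kdeNonparametric <- function(dataset, grid, lambda = 0.015) {
  if (lambda <= 0) stop("lambda must be positive")
  r <- dataset@records
  r <- r[!r$is_dummy & r$iteration >= 1L, , drop = FALSE]
  if (nrow(r) == 0) stop("input error: dataset has no reproductions")
  is1d <- grid@ndim == 1L
  total <- numeric(nCells(grid))
  ids <- unique(r$chain_id)
  for (id in ids) {
    ri <- r[r$chain_id == id, , drop = FALSE]
    P <- if (is1d) matrix(ri$x, ncol = 1) else cbind(ri$x, ri$y)
    mu <- colMeans(P)
    S <- if (nrow(P) > 1) stats::cov(P) else matrix(0, ncol(P), ncol(P))
    Sreg <- S + diag(lambda^2, ncol(P))
    total <- total + .gaussOnGrid(mu, if (is1d) Sreg[1, 1] else Sreg, grid)
  }
  normalizeField(total, grid)
}

#' Parametric KDE of the spatial prior from last-iteration points
#'
#' Sum of isotropic Gaussian kernels of fixed width centered on each
#' last-iteration chain point, normalized on the grid. By the stationarity
#' of the reproduction chain, last-iteration points are (approximate) draws
#' from the prior, so this is the estimator used for quantitative analyses.
#'
#' @param dataset a [ChainDataset-class].
#' @param grid evaluation [SpatialGrid-class].
#' @param width kernel SD in normalized units; 0.025 suits shape-like
#'   stimuli, 0.040 natural-image-like ones.
#' @return a [DensityField-class] summing to 1.
#' @export
kdeParametric <- function(dataset, grid, width = 0.025) {
  if (width <= 0) stop("width must be positive")
  P <- iterationPoints(dataset, -1L)
  if (ncol(P) != grid@ndim) stop("dataset dimensionality does not match grid")
  total <- numeric(nCells(grid))
  for (i in seq_len(nrow(P)))
    total <- total + .gaussOnGrid(P[i, ], width^2, grid)
  normalizeField(total, grid)
}

#' CAMParams constructor
#'
#' @param w memory weight in \[0,1\].
#' @param c sensitivity (softmax sharpness) > 0.
#' @param prototypes prototype locations: numeric matrix (one per row), or a
#'   vector for a single prototype.
#' @param noiseSd optional reproduction noise SD used when simulating.
#' @return a [CAMParams-class].
#' @export
camParams <- function(w, c, prototypes, noiseSd = NA_real_) {
  if (is.null(dim(prototypes))) prototypes <- matrix(prototypes, nrow = 1)
  new("CAMParams", w = as.numeric(w), c = as.numeric(c),
      prototypes = as.matrix(prototypes), noiseSd = as.numeric(noiseSd))
}

setMethod("show", "CAMParams", function(object) {
  cat(sprintf("CAMParams: w = %.3f, c = %.3g, %d prototype(s)%s\n",
              object@w, object@c, nrow(object@prototypes),
              if (is.finite(object@noiseSd))
                sprintf(", noise SD %.3g", object@noiseSd) else ""))
})

# Noise-free CAM prediction for a matrix of stimulus points.
.camPredictMat <- function(S, w, cc, P) {
  D2 <- .sqDistMatrix(S, P)
  E <- -cc * sqrt(D2)
  E <- E - apply(E, 1, max)          # softmax stabilization
  V <- exp(E)
  V <- V / rowSums(V)
  w * S + (1 - w) * (V %*% P)
}

#' Category adjustment model prediction
#'
#' \eqn{R = w S + (1-w) \sum_k v_k P_k} with softmax pull weights
#' \eqn{v_k = \exp(-c\|S - P_k\|) / \sum_{k'} \exp(-c\|S - P_{k'}\|)}.
#' Noise-free prediction; see [camIterate()] for noisy simulation.
#'
#' @param s a stimulus point or matrix of points.
#' @param params a [CAMParams-class].
#' @return matrix of predicted reproductions, one row per input point.
#' @export
camPredict <- function(s, params) {
  ndim <- ncol(params@prototypes)
  S <- asPoints(s, ndim)
  .camPredictMat(S, params@w, params@c, params@prototypes)
}

.camLoss <- function(par, S, R, M, ndim) {
  w <- par[1]; cc <- par[2]
  P <- matrix(par[-(1:2)], nrow = M, ncol = ndim)
  pred <- .camPredictMat(S, w, cc, P)
  mean(rowSums((R - pred)^2))
}

#' Fit the category adjustment model to seed/response pairs
#'
#' Minimizes mean squared prediction error over (w, c, prototypes) with box
#' constraints (w in \[0,1\], c > 0, prototypes in the domain) using
#' multi-start L-BFGS-B. Prototype initialization is k-means on the
#' responses plus per-restart random jitter; the fit is deterministic given
#' `seed`.
#'
#' @param seeds matrix of stimulus points (iteration 0).
#' @param responses matrix of corresponding reproductions (iteration 1).
#' @param M number of prototypes.
#' @param nRestarts number of seeded restarts (default 20).
#' @param seed integer RNG seed for the restarts.
#' @return list with `params` (a [CAMParams-class]) and `loss` (the best MSE).
#' @export
camFit <- function(seeds, responses, M, nRestarts = 20L, seed = 1L) {
  S <- as.matrix(seeds); R <- as.matrix(responses)
  if (!all(dim(S) == dim(R)))
    stop("seeds and responses must have equal dimensions")
  n <- nrow(S); ndim <- ncol(S)
  M <- as.integer(M)
  if (M > n) stop("identifiability error: more prototypes than data points")
  if (!is.null(seed)) set.seed(as.integer(seed))
  km <- tryCatch(stats::kmeans(R, centers = M, nstart = 5)$centers,
                 error = function(e) R[sample.int(n, M), , drop = FALSE])
  lower <- c(0, 1e-2, rep(0, M * ndim))
  upper <- c(1, 1e3, rep(1, M * ndim))
  best <- NULL
  for (rs in seq_len(nRestarts)) {
    P0 <- km
    if (rs > 1)
      P0 <- pmin(pmax(km + matrix(stats::rnorm(M * ndim, sd = 0.05), M, ndim), 0), 1)
    par0 <- c(stats::runif(1, 0.3, 0.7),
              exp(stats::runif(1, log(2), log(50))),
              as.numeric(pmax(P0, 0)))
    fit <- tryCatch(
      stats::optim(par0, .camLoss, S = S, R = R, M = M, ndim = ndim,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("CAM optimization failed in every restart")
  P <- matrix(best$par[-(1:2)], nrow = M, ncol = ndim)
  list(params = camParams(best$par[1], best$par[2], P), loss = best$value)
}

#' Iterate the category adjustment model from a start point
#'
#' Repeated application of [camPredict()], optionally adding isotropic
#' Gaussian reproduction noise of the parameters' `noiseSd`. In the
#' single-prototype noise-free case the distance to the prototype contracts
#' by exactly the factor w per step, so prototypes are fixed points of the
#' iterated process.
#'
#' @param params a [CAMParams-class].
#' @param start starting point.
#' @param nIter number of iterations, >= 1.
#' @param noise add Gaussian noise of SD `params@noiseSd` per step.
#' @param seed RNG seed used when `noise = TRUE`.
#' @return matrix of points: row n is the position after n steps.
#' @export
camIterate <- function(params, start, nIter, noise = FALSE, seed = NULL) {
  nIter <- as.integer(nIter)
  if (nIter < 1) stop("nIter must be >= 1")
  ndim <- ncol(params@prototypes)
  if (noise && !is.finite(params@noiseSd))
    stop("params carry no noise SD")
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- asPoints(start, ndim)[1, , drop = FALSE]
  out <- matrix(NA_real_, nIter, ndim)
  for (nit in seq_len(nIter)) {
    x <- .camPredictMat(x, params@w, params@c, params@prototypes)
    if (noise)
      x <- pmin(pmax(x + stats::rnorm(ndim, sd = params@noiseSd), 0), 1)
    out[nit, ] <- x
  }
  out
}

#' Match estimated prototypes to reference prototypes
#'
#' Optimal one-to-one assignment minimizing total Euclidean distance
#' (exhaustive over permutations for M <= 8, greedy beyond). Prototype
#' labels are unidentifiable, so recovery is always assessed after
#' matching.
#'
#' @param estimated,reference prototype matrices with equal dimensions.
#' @return list with `order` (permutation of reference rows matched to the
#'   estimated rows), `distances` (per-pair Euclidean distance), and
#'   `maxDistance`.
#' @export
matchPrototypes <- function(estimated, reference) {
  E <- as.matrix(estimated); Rf <- as.matrix(reference)
  if (!all(dim(E) == dim(Rf))) stop("prototype sets must have equal dimensions")
  M <- nrow(E)
  D <- sqrt(.sqDistMatrix(E, Rf))
  if (M <= 8L) {
    perms <- .permutations(M)
    tot <- apply(perms, 1, function(p) sum(D[cbind(seq_len(M), p)]))
    p <- perms[which.min(tot), ]
  } else {
    p <- integer(M); used <- logical(M)
    for (i in order(apply(D, 1, min))) {
      j <- which.min(ifelse(used, Inf, D[i, ]))
      p[i] <- j; used[j] <- TRUE
    }
  }
  d <- D[cbind(seq_len(M), p)]
  list(order = p, distances = d, maxDistance = max(d))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}
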