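#' @import methods
NULL

#' SpatialGrid: a discrete spatial domain on the unit interval or square
#'
#' A regular grid over normalized coordinates, each axis spanning \[0,1\].
#' Cells are half-open intervals of equal width with centers at
#' \eqn{(i + 0.5)/n}, \eqn{i = 0, \dots, n-1}. All probability objects in the
#' package (priors, likelihood rows, transition-kernel rows) are discrete
#' masses on the cells of such a grid.
#'
#' @slot ndim integer, 1 or 2.
#' @slot shape integer vector of cells per axis (length \code{ndim}).
#' @slot centers list of per-axis cell-center coordinates.
#' @slot spacing numeric vector of per-axis cell widths.
#' @export
setClass("SpatialGrid",
  representation(ndim = "integer", shape = "integer",
                 centers = "list", spacing = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@ndim %in% c(1L, 2L)) msg <- c(msg, "ndim must be 1 or 2")
    if (length(object@shape) != object@ndim)
      msg <- c(msg, "shape length must equal ndim")
    if (any(object@shape < 1L)) msg <- c(msg, "shape entries must be >= 1")
    for (a in seq_len(object@ndim)) {
      ctr <- object@centers[[a]]
      if (length(ctr) != object@shape[a])
        msg <- c(msg, "centers length mismatch")
      if (any(ctr < 0) || any(ctr > 1))
        msg <- c(msg, "cell centers must lie in [0,1]")
      if (length(ctr) > 1) {
        d <- diff(ctr)
        if (any(d <= 0)) msg <- c(msg, "cell centers must be strictly increasing")
        if (max(abs(d - object@spacing[a])) > 1e-12)
          msg <- c(msg, "cell spacing must be uniform (tol 1e-12)")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' DensityField: a probability mass function on a SpatialGrid
#'
#' Holds a nonnegative mass per grid cell, summing to one. Used for spatial
#' priors \eqn{\pi(s) = p(S = s)}, chain iterates, and estimated densities.
#'
#' @slot grid a [SpatialGrid-class].
#' @slot mass numeric vector, one nonnegative entry per cell, in cell order
#'   (first axis fastest), summing to 1 within 1e-9.
#' @export
setClass("DensityField",
  representation(grid = "SpatialGrid", mass = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@mass) != nCells(object@grid))
      msg <- c(msg, "mass must have one entry per grid cell")
    if (any(!is.finite(object@mass)) || any(object@mass < 0))
      msg <- c(msg, "mass entries must be finite and nonnegative")
    if (abs(sum(object@mass) - 1) > 1e-9)
      msg <- c(msg, "mass must sum to 1 (tol 1e-9)")
    if (length(msg)) msg else TRUE
  })

#' Observer models
#'
#' Virtual parent class for the three encoder models. Each observer yields,
#' via [buildLikelihood()], a row-stochastic likelihood matrix
#' \eqn{p(T = x_j \mid S = x_i)} on a grid.
#'
#' @name Observer-class
#' @aliases Observer
#' @export
setClass("Observer", representation("VIRTUAL"))

#' @describeIn Observer-class location-independent isotropic Gaussian sensory
#'   noise of SD \code{sigma} (normalized units).
#' @slot sigma positive Euclidean noise SD.
#' @export
setClass("FixedPrecisionObserver", contains = "Observer",
  representation(sigma = "numeric"),
  validity = function(object) {
    if (length(object@sigma) != 1 || !is.finite(object@sigma) ||
        object@sigma <= 0) "sigma must be a positive scalar" else TRUE
  })

#' @describeIn Observer-class constant isotropic Gaussian noise of SD
#'   \code{sigmaW} in the perceptually warped (prior-uniformized) coordinate
#'   space; skewed, landmark-attracted noise in Euclidean units.
#' @slot prior the spatial prior (a [DensityField-class]).
#' @slot sigmaW positive noise SD in warped coordinates.
#' @export
setClass("EfficientEncodingObserver", contains = "Observer",
  representation(prior = "DensityField", sigmaW = "numeric"),
  validity = function(object) {
    if (length(object@sigmaW) != 1 || !is.finite(object@sigmaW) ||
        object@sigmaW <= 0) "sigmaW must be a positive scalar" else TRUE
  })

#' @describeIn Observer-class symmetric Gaussian noise whose local SD scales
#'   as \code{sigma0 * density(x)^(-alpha)}: precise near prior modes but
#'   unbiased on average.
#' @slot prior the spatial prior.
#' @slot sigma0 positive baseline SD.
#' @slot alpha nonnegative exponent linking local SD to prior density.
#' @export
setClass("SymmetricVariablePrecisionObserver", contains = "Observer",
  representation(prior = "DensityField", sigma0 = "numeric", alpha = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@sigma0) != 1 || !is.finite(object@sigma0) ||
        object@sigma0 <= 0) msg <- c(msg, "sigma0 must be a positive scalar")
    if (length(object@alpha) != 1 || !is.finite(object@alpha) ||
        object@alpha < 0) msg <- c(msg, "alpha must be a nonnegative scalar")
    if (length(msg)) msg else TRUE
  })

#' LikelihoodMatrix: encoding distributions p(T = x_j | S = x_i)
#'
#' Row i is the distribution of the noisy sensory representation T given the
#' true location S at cell i. Rows are probability vectors over cells.
#'
#' @slot grid the [SpatialGrid-class] the matrix lives on.
#' @slot probs numeric matrix, entry (i, j) = p(T = x_j | S = x_i);
#'   rows sum to 1 within 1e-9.
#' @export
setClass("LikelihoodMatrix",
  representation(grid = "SpatialGrid", probs = "matrix"),
  validity = function(object) .validateRowStochastic(object, "LikelihoodMatrix"))

#' TransitionKernel: one serial-reproduction step p(S_{n+1} = r | S_n = s)
#'
#' Row s is the reproduction distribution given the previous reproduction at
#' cell s, obtained by marginalizing the sensory representation over the
#' posterior-sampling observer. Row-stochastic; satisfies detailed balance
#' with respect to the observer's prior.
#'
#' @slot grid the [SpatialGrid-class].
#' @slot probs numeric matrix, entry (s, r) = p(S_{n+1} = x_r | S_n = x_s).
#' @export
setClass("TransitionKernel",
  representation(grid = "SpatialGrid", probs = "matrix"),
  validity = function(object) .validateRowStochastic(object, "TransitionKernel"))

.validateRowStochastic <- function(object, what) {
  msg <- character(0)
  n <- nCells(object@grid)
  if (!all(dim(object@probs) == c(n, n)))
    msg <- c(msg, sprintf("%s must be nCells x nCells", what))
  if (any(object@probs < 0)) msg <- c(msg, "entries must be nonnegative")
  else if (max(abs(rowSums(object@probs) - 1)) > 1e-9)
    msg <- c(msg, "rows must sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
}

#' ChainDataset: a collection of serial-reproduction chains
#'
#' Tabular chain records: one row per (chain, iteration), iteration 0 being
#' the seed point shown to the first participant/simulated observer.
#'
#' @slot records data.frame with columns \code{chain_id}, \code{iteration},
#'   \code{x}, \code{y} (\code{y} is NA for 1D domains) and \code{is_dummy}.
#' @slot stimulus stimulus identifier shared by all chains.
#' @slot provenance \code{"simulated"} or \code{"observed"}.
#' @slot meta list of free-form metadata (observer config, seeds, grid shape).
#' @export
setClass("ChainDataset",
  representation(records = "data.frame", stimulus = "character",
                 provenance = "character", meta = "list"),
  validity = function(object) {
    msg <- character(0)
    need <- c("chain_id", "iteration", "x", "y", "is_dummy")
    if (!all(need %in% names(object@records)))
      msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
    else {
      r <- object@records
      ok <- is.finite(r$x) & r$x >= 0 & r$x <= 1
      if (!all(ok)) msg <- c(msg, "x coordinates must lie in [0,1]")
      yv <- r$y[!is.na(r$y)]
      if (any(yv < 0 | yv > 1)) msg <- c(msg, "y coordinates must lie in [0,1]")
      for (id in unique(r$chain_id)) {
        it <- sort(r$iteration[r$chain_id == id & !r$is_dummy])
        if (!identical(as.integer(it), seq(min(it), max(it)))) {
          msg <- c(msg, "iteration indices must be contiguous within chains")
          break
        }
      }
    }
    if (!object@provenance %in% c("simulated", "observed"))
      msg <- c(msg, "provenance must be 'simulated' or 'observed'")
    if (length(msg)) msg else TRUE
  })

#' DPrimeMap: discrimination sensitivity over a grid of probe points
#'
#' Holds a d' value per probe point, either predicted from an observer model
#' or estimated from 2AFC counts. Probes whose offset circle leaves the
#' domain are flagged as not retained and carry NA values.
#'
#' @slot points numeric matrix of probe coordinates (one row per probe).
#' @slot values numeric d' per probe (NA where not retained).
#' @slot shape integer probe-grid dimensions when probes form a regular grid,
#'   else \code{integer(0)}.
#' @slot radius offset radius (normalized units) used for the map.
#' @slot kernelSd Gaussian smoothing SD applied (0 = unsmoothed).
#' @slot interpolated logical, whether values were interpolated to a finer grid.
#' @slot retained logical per probe.
#' @export
setClass("DPrimeMap",
  representation(points = "matrix", values = "numeric", shape = "integer",
                 radius = "numeric", kernelSd = "numeric",
                 interpolated = "logical", retained = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@points) != length(object@values))
      msg <- c(msg, "one value per probe required")
    if (length(object@retained) != length(object@values))
      msg <- c(msg, "one retained flag per probe required")
    if (any(!is.finite(object@values[object@retained])))
      msg <- c(msg, "retained probes must have finite d' values")
    if (any(object@points < 0) || any(object@points > 1))
      msg <- c(msg, "probe points must lie in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' TwoAFCDataset: same/shifted discrimination responses
#'
#' One record per trial of the 2AFC task: a probe location, the condition
#' (whether the dot actually moved by the offset radius), and the response.
#'
#' @slot data data.frame with columns \code{probe_x}, \code{probe_y},
#'   \code{condition} ("same"/"shifted") and \code{response} ("same"/"shifted").
#' @slot radius offset radius in normalized units.
#' @slot meta list of metadata (n per point, generating model, seed).
#' @export
setClass("TwoAFCDataset",
  representation(data = "data.frame", radius = "numeric", meta = "list"),
  validity = function(object) {
    msg <- character(0)
    need <- c("probe_x", "probe_y", "condition", "response")
    if (!all(need %in% names(object@data)))
      msg <- c(msg, paste("data must have columns:", paste(need, collapse = ", ")))
    else {
      if (!all(object@data$condition %in% c("same", "shifted")))
        msg <- c(msg, "condition must be 'same' or 'shifted'")
      if (!all(object@data$response %in% c("same", "shifted")))
        msg <- c(msg, "response must be 'same' or 'shifted'")
      key <- paste(object@data$probe_x, object@data$probe_y)
      tab <- table(key, object@data$condition)
      if (ncol(tab) < 2 || any(tab == 0))
        msg <- c(msg, "every probe needs records in both conditions")
    }
    if (object@radius <= 0) msg <- c(msg, "radius must be positive")
    if (length(msg)) msg else TRUE
  })

#' CAMParams: category adjustment model parameters
#'
#' The category adjustment model reconstructs a location as a weighted
#' average of the stimulus and softmax-weighted prototypes:
#' \eqn{R = w S + (1-w) \sum_k v_k P_k}, with
#' \eqn{v_k \propto \exp(-c \|S - P_k\|)}.
#'
#' @slot w memory weight in \[0,1\].
#' @slot c sensitivity (softmax sharpness), > 0.
#' @slot prototypes numeric matrix, one prototype location per row, in domain.
#' @slot noiseSd optional reproduction noise SD for simulation (NA = none).
#' @export
setClass("CAMParams",
  representation(w = "numeric", c = "numeric", prototypes = "matrix",
                 noiseSd = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@w < 0 || object@w > 1) msg <- c(msg, "w must lie in [0,1]")
    if (object@c <= 0) msg <- c(msg, "c must be positive")
    if (nrow(object@prototypes) < 1) msg <- c(msg, "at least one prototype required")
    if (any(object@prototypes < 0) || any(object@prototypes > 1))
      msg <- c(msg, "prototypes must lie in the domain")
    if (length(msg)) msg else TRUE
  })

#' BiasField: binned average reproduction-bias vectors
#'
#' Average single-trial bias (reproduction minus shown location) within
#' spatial bins, with per-bin trial counts.
#'
#' @slot points numeric matrix of bin-center coordinates.
#' @slot vectors numeric matrix of average bias vectors (same rows).
#' @slot counts integer trials per bin, all >= 1.
#' @export
setClass("BiasField",
  representation(points = "matrix", vectors = "matrix", counts = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@points) != nrow(object@vectors) ||
        nrow(object@points) != length(object@counts))
      msg <- c(msg, "points, vectors and counts must align")
    if (any(object@counts < 1L)) msg <- c(msg, "counts must be >= 1")
    if (any(!is.finite(object@vectors))) msg <- c(msg, "bias vectors must be finite")
    if (length(msg)) msg else TRUE
  })
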