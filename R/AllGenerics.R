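#' @include AllClasses.R
NULL

#' Build the likelihood matrix of an observer on a grid
#'
#' Constructs the row-stochastic encoding matrix
#' \eqn{p(T = x_j \mid S = x_i)} for an observer model. Each row is the
#' distribution of the sensory representation given the true location at a
#' cell center, truncated to the domain by renormalizing over in-domain
#' cells.
#'
#' @param observer an [Observer-class] (fixed, efficient, or symmetric
#'   variable precision).
#' @param grid the [SpatialGrid-class] to discretize on. For observers
#'   carrying a prior, it must be the prior's grid.
#' @return a [LikelihoodMatrix-class].
#' @examples
#' g <- spatialGrid(32)
#' L <- buildLikelihood(fixedObserver(0.05), g)
#' range(rowSums(likProbs(L)))  # all 1
#' @export
setGeneric("buildLikelihood", function(observer, grid)
  standardGeneric("buildLikelihood"))

#' @rdname nCells
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
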