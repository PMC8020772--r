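#' @include AllClasses.R AllGenerics.R grid.R observers.R
NULL

#' Posterior over true location given an observed sensory cell
#'
#' Bayesian inference step of the observer: given the sensory representation
#' T at cell `tCell`, returns \eqn{p(S = r \mid T = t) \propto
#' p(T = t \mid S = r)\, p(S = r)}, normalized over cells.
#'
#' @param prior a [DensityField-class].
#' @param likelihood a [LikelihoodMatrix-class] on the same grid.
#' @param tCell integer index of the observed cell.
#' @return a [DensityField-class] posterior.
#' @export
posteriorField <- function(prior, likelihood, tCell) {
  if (!identical(prior@grid@shape, likelihood@grid@shape))
    stop("prior and likelihood must share the same grid")
  tCell <- as.integer(tCell)
  if (length(tCell) != 1 || tCell < 1 || tCell > nCells(prior@grid))
    stop("tCell out of range")
  w <- likelihood@probs[, tCell] * prior@mass
  tot <- sum(w)
  if (tot <= 0)
    stop("degenerate posterior: observed cell has zero evidence under the prior")
  densityField(w / tot, prior@grid)
}

#' Serial-reproduction transition kernel
#'
#' One step of the transmission chain for a posterior-sampling observer:
#' \deqn{K(r \mid s) = \sum_t p(R = r \mid T = t)\, p(T = t \mid S = s),}
#' where \eqn{p(R = r \mid T = t)} is the posterior. The prior is the
#' stationary distribution of this kernel and detailed balance
#' \eqn{K(r \mid s)\pi(s) = K(s \mid r)\pi(r)} holds exactly (up to
#' floating-point error), for any row-stochastic likelihood.
#'
#' @param prior a [DensityField-class].
#' @param likelihood a [LikelihoodMatrix-class] on the same grid.
#' @return a [TransitionKernel-class] with entries indexed (s-cell, r-cell).
#' @export
transitionKernel <- function(prior, likelihood) {
  if (!identical(prior@grid@shape, likelihood@grid@shape))
    stop("prior and likelihood must share the same grid")
  L <- likelihood@probs
  A <- L * prior@mass            # A[r, t] = p(T=t|S=r) pi(r)
  z <- colSums(A)                # evidence p(T=t)
  if (any(z <= 0))
    stop("degenerate posterior: some sensory cell has zero evidence")
  post <- sweep(A, 2, z, "/")    # post[r, t] = p(S=r|T=t)
  K <- L %*% t(post)             # K[s, r] = sum_t L[s,t] post[r,t]
  new("TransitionKernel", grid = prior@grid, probs = K)
}

#' @rdname likProbs
#' @export
kernelProbs <- function(x) x@probs

#' @rdname likProbs
#' @export
kernelGrid <- function(x) x@grid

setMethod("show", "TransitionKernel", function(object)
  cat(sprintf("TransitionKernel: %d x %d on a %s grid\n",
              nrow(object@probs), ncol(object@probs),
              paste(object@grid@shape, collapse = " x "))))

#' Analytically propagate a start distribution through the chain
#'
#' Computes \eqn{p(S_{n+1} = r) = \sum_s K(r \mid s)\, p(S_n = s)}
#' recursively, returning the distributions after 1..nIter steps. Starting
#' at the prior reproduces the prior at every step (stationarity); from any
#' start, the KL divergence to the prior is non-increasing.
#'
#' @param kernel a [TransitionKernel-class].
#' @param start a [DensityField-class] initial distribution.
#' @param nIter number of steps, >= 1.
#' @return list of [DensityField-class] objects, element n = p(S_n).
#' @export
propagateChain <- function(kernel, start, nIter) {
  if (!identical(kernel@grid@shape, start@grid@shape))
    stop("kernel and start must share the same grid")
  nIter <- as.integer(nIter)
  if (nIter < 1) stop("nIter must be >= 1")
  out <- vector("list", nIter)
  p <- start@mass
  for (n in seq_len(nIter)) {
    p <- as.numeric(p %*% kernel@probs)
    p <- p / sum(p)
    out[[n]] <- densityField(p, kernel@grid)
  }
  out
}

#' ChainDataset constructor and accessors
#'
#' @param records data.frame with columns `chain_id`, `iteration`, `x`, `y`
#'   (NA in 1D), `is_dummy`; iteration 0 holds the seed.
#' @param stimulus stimulus identifier.
#' @param provenance `"simulated"` or `"observed"`.
#' @param meta metadata list (grid shape, observer config, seeds, ...).
#' @return a [ChainDataset-class].
#' @export
chainDataset <- function(records, stimulus = "unnamed",
                         provenance = "simulated", meta = list()) {
  records$chain_id <- as.integer(records$chain_id)
  records$iteration <- as.integer(records$iteration)
  if (is.null(records$is_dummy)) records$is_dummy <- FALSE
  if (is.null(records$y)) records$y <- NA_real_
  records <- records[c("chain_id", "iteration", "x", "y", "is_dummy")]
  new("ChainDataset", records = records, stimulus = stimulus,
      provenance = provenance, meta = meta)
}

#' @rdname chainDataset
#' @param dataset a [ChainDataset-class].
#' @export
chainRecords <- function(dataset) dataset@records

#' @rdname chainDataset
#' @export
nChains <- function(dataset) length(unique(dataset@records$chain_id))

#' Extract the points of one iteration as a coordinate matrix
#'
#' @param dataset a [ChainDataset-class].
#' @param iteration iteration index (0 = seeds); negative = last iteration.
#' @param dropDummy exclude dummy trials (default TRUE).
#' @return numeric matrix of points (1 or 2 columns).
#' @export
iterationPoints <- function(dataset, iteration = -1L, dropDummy = TRUE) {
  r <- dataset@records
  if (dropDummy) r <- r[!r$is_dummy, , drop = FALSE]
  if (iteration < 0) iteration <- max(r$iteration)
  r <- r[r$iteration == iteration, , drop = FALSE]
  if (nrow(r) == 0) stop("no points at iteration ", iteration)
  if (all(is.na(r$y))) matrix(r$x, ncol = 1) else cbind(r$x, r$y)
}

setMethod("show", "ChainDataset", function(object) {
  r <- object@records
  cat(sprintf("ChainDataset '%s' (%s): %d chains, iterations 0-%d, %d rows%s\n",
              object@stimulus, object@provenance,
              length(unique(r$chain_id)), max(r$iteration), nrow(r),
              if (any(r$is_dummy)) " (with dummy trials)" else ""))
})

.pointRow <- function(p) {
  if (length(p) == 1) c(x = p[1], y = NA_real_) else c(x = p[1], y = p[2])
}

#' Simulate one transmission chain
#'
#' Starting from a seed point (snapped to its grid cell), each step draws
#' the sensory representation T from the likelihood row of the current cell,
#' forms the posterior, and draws the reproduction R from it; R becomes the
#' next stimulus. Reported points are cell centers. Deterministic given
#' `seed`.
#'
#' @param prior a [DensityField-class].
#' @param likelihood a [LikelihoodMatrix-class] on the same grid.
#' @param seedPoint the initial point (numeric, length ndim).
#' @param nIter number of reproductions.
#' @param seed integer RNG seed (NULL = use current RNG state).
#' @param chainId chain identifier stored in the record.
#' @return a [ChainDataset-class] with a single chain (iteration 0 = seed).
#' @export
sampleChain <- function(prior, likelihood, seedPoint, nIter = 20L,
                        seed = NULL, chainId = 1L) {
  if (!identical(prior@grid@shape, likelihood@grid@shape))
    stop("prior and likelihood must share the same grid")
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- prior@grid
  K <- nCells(g)
  sCell <- pointToCell(seedPoint, g)
  cells <- integer(nIter)
  cur <- sCell
  L <- likelihood@probs
  pm <- prior@mass
  for (n in seq_len(nIter)) {
    tCell <- sample.int(K, 1L, prob = L[cur, ])
    w <- L[, tCell] * pm
    tot <- sum(w)
    if (tot <= 0)
      stop(sprintf("degenerate posterior at chain %d, step %d", chainId, n))
    cur <- sample.int(K, 1L, prob = w)
    cells[n] <- cur
  }
  pts <- cellToPoint(c(sCell, cells), g)
  rec <- data.frame(chain_id = chainId, iteration = 0:nIter,
                    x = pts[, 1],
                    y = if (g@ndim == 2L) pts[, 2] else NA_real_,
                    is_dummy = FALSE)
  chainDataset(rec, meta = list(grid = as.integer(g@shape), seed = seed))
}

#' Markov-assumption check via dummy-trial interleaving
#'
#' Compares the prior estimated from a dummy-interleaved chain dataset
#' (experimental trials only) with the estimate from a matched dataset
#' without dummies, via the Pearson correlation of their parametric KDEs.
#' For a memoryless (Markov) observer the interleaved uniform dummy trials
#' cannot affect the chain, so the correlation is ~1; carry-over from
#' previous trials pulls it down.
#'
#' @param withDummies a [ChainDataset-class] containing flagged dummy trials.
#' @param withoutDummies a matched [ChainDataset-class] without dummies.
#' @param grid evaluation grid for the KDEs.
#' @param kernelWidth parametric KDE kernel width (normalized units).
#' @return list with the two KDE fields and their Pearson `correlation`.
#' @export
markovDummyCheck <- function(withDummies, withoutDummies, grid,
                             kernelWidth = 0.04) {
  if (!any(withDummies@records$is_dummy))
    stop("input error: dataset has no flagged dummy trials")
  kdeA <- kdeParametric(withDummies, grid, width = kernelWidth)
  kdeB <- kdeParametric(withoutDummies, grid, width = kernelWidth)
  list(kdeDummy = kdeA, kdeReference = kdeB,
       correlation = correlateMaps(kdeA, kdeB, excludeEdge = 0L))
}
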