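#' @include AllClasses.R grid.R chain.R
NULL

#' Binned single-trial bias vectors
#'
#' The single-trial bias at iteration n is the reproduction minus the shown
#' location, \eqn{R_n - S_n} (with \eqn{S_n} the previous chain point).
#' Biases are averaged within square spatial bins of the shown locations.
#'
#' @param dataset a [ChainDataset-class] (2D).
#' @param iteration which reproduction iteration to use (1 = the first
#'   reproduction of each chain), or NULL to pool the single-trial biases of
#'   every iteration, as when chain data from all iterations are
#'   superposed. Pooling gives far more trials per bin and correspondingly
#'   less noisy average bias vectors.
#' @param binWidth spatial bin width in normalized units.
#' @return a [BiasField-class]; empty bins are dropped.
#' @export
biasField <- function(dataset, iteration = NULL, binWidth = 0.025) {
  r <- dataset@records[!dataset@records$is_dummy, , drop = FALSE]
  if (is.null(iteration)) {
    r <- r[order(r$chain_id, r$iteration), , drop = FALSE]
    n <- nrow(r)
    link <- which(r$chain_id[-1] == r$chain_id[-n] &
                    r$iteration[-1] == r$iteration[-n] + 1L)
    prev <- r[link, ]
    cur <- r[link + 1L, ]
  } else {
    iteration <- as.integer(iteration)
    if (!all(c(iteration - 1L, iteration) %in% r$iteration))
      stop("requested iteration (and its predecessor) not present")
    prev <- r[r$iteration == iteration - 1L, ]
    cur <- r[r$iteration == iteration, ]
    prev <- prev[match(cur$chain_id, prev$chain_id), ]
  }
  is1d <- all(is.na(cur$y))
  S <- if (is1d) cbind(prev$x, 0) else cbind(prev$x, prev$y)
  B <- if (is1d) cbind(cur$x - prev$x, 0) else
    cbind(cur$x - prev$x, cur$y - prev$y)
  nb <- ceiling(1 / binWidth)
  bx <- pmin(floor(S[, 1] / binWidth), nb - 1)
  by <- pmin(floor(S[, 2] / binWidth), nb - 1)
  key <- bx + nb * by
  cnt <- rowsum(rep(1L, nrow(S)), key)[, 1]
  vec <- rowsum(B, key) / cnt
  ukey <- as.numeric(rownames(vec))
  pts <- cbind((ukey %% nb + 0.5) * binWidth,
               (ukey %/% nb + 0.5) * binWidth)
  dimnames(vec) <- NULL
  new("BiasField", points = pmin(pmax(pts, 0), 1), vectors = vec,
      counts = as.integer(cnt))
}

setMethod("show", "BiasField", function(object)
  cat(sprintf("BiasField: %d occupied bins, %d trials, mean |bias| %.4g\n",
              nrow(object@points), sum(object@counts),
              mean(sqrt(rowSums(object@vectors^2))))))

#' Angular coherence of neighboring bias vectors
#'
#' For all pairs of occupied bins whose centers lie within
#' `neighborRadius`, computes the absolute angular difference between their
#' average bias vectors (degrees, in \[0, 180\]). Consistent, landmark-
#' directed biases concentrate these differences near zero; independent
#' symmetric noise makes them uniform. The band ratio is the observed
#' probability of differences within `bandDeg` degrees divided by the
#' uniform expectation (`bandDeg/180`, i.e. a +/-12 degree band out of the
#' full circle of signed differences).
#'
#' @param field a [BiasField-class].
#' @param neighborRadius pair-inclusion radius for bin centers.
#' @param bandDeg half-width of the coherence band in degrees.
#' @param breaks histogram breaks (degrees).
#' @param edgeBuffer exclude bins whose centers lie within this distance of
#'   the domain boundary, where truncation pulls responses coherently
#'   inward under every observer model (0 = keep all bins).
#' @return list with `histogram` (a `hist` object of angular differences),
#'   `bandRatio`, and `nPairs`.
#' @export
angularCoherence <- function(field, neighborRadius = 0.05, bandDeg = 12,
                             breaks = seq(0, 180, by = 12),
                             edgeBuffer = 0) {
  P <- field@points
  V <- field@vectors
  if (edgeBuffer > 0) {
    keep <- apply(P >= edgeBuffer & P <= 1 - edgeBuffer, 1, all)
    P <- P[keep, , drop = FALSE]
    V <- V[keep, , drop = FALSE]
  }
  n <- nrow(P)
  if (n < 2) stop("input error: fewer than two occupied bins")
  D2 <- .sqDistMatrix(P, P)
  pair <- which(upper.tri(D2) & D2 <= neighborRadius^2, arr.ind = TRUE)
  if (nrow(pair) == 0) stop("input error: no bin pairs within the radius")
  ang <- atan2(V[, 2], V[, 1])
  d <- abs(ang[pair[, 1]] - ang[pair[, 2]]) * 180 / pi
  d <- ifelse(d > 180, 360 - d, d)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(histogram = h,
       bandRatio = mean(d <= bandDeg) / (bandDeg / 180),
       nPairs = nrow(pair))
}

#' Bootstrap confidence interval by resampling chains
#'
#' Resamples whole chains with replacement (respecting within-chain
#' dependence), recomputes the statistic, and returns a percentile CI.
#' Deterministic given `seed`.
#'
#' @param statisticFn function mapping a [ChainDataset-class] to a scalar.
#' @param dataset a [ChainDataset-class] with at least 2 chains.
#' @param nBoot number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper`, `level`, and the replicate vector
#'   `replicates`.
#' @export
bootstrapCI <- function(statisticFn, dataset, nBoot = 1000L, seed = 1L,
                        level = 0.95) {
  nBoot <- as.integer(nBoot)
  if (nBoot < 100L) stop("nBoot must be >= 100")
  ids <- unique(dataset@records$chain_id)
  if (length(ids) < 2) stop("input error: need at least 2 chains")
  if (!is.null(seed)) set.seed(as.integer(seed))
  r <- dataset@records
  byChain <- split(seq_len(nrow(r)), r$chain_id)
  boot <- dataset
  reps <- vapply(seq_len(nBoot), function(b) {
    take <- as.character(sample(ids, length(ids), replace = TRUE))
    rows <- byChain[take]
    rec <- r[unlist(rows, use.names = FALSE), , drop = FALSE]
    rec$chain_id <- rep.int(seq_along(rows), lengths(rows))
    boot@records <- rec
    statisticFn(boot)
  }, 0)
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  list(lower = q[1], upper = q[2], level = level, replicates = reps)
}

.mapMatrix <- function(x) {
  if (is(x, "DensityField")) return(fieldMatrix(x))
  if (is(x, "DPrimeMap")) return(dprimeMatrix(x))
  if (is.matrix(x)) return(x)
  stop("expected a DensityField, DPrimeMap, or matrix")
}

#' Pearson correlation between two maps
#'
#' Correlates two same-shape maps (density fields, d' maps on regular probe
#' grids, or plain matrices) over retained cells, optionally excluding a
#' band of edge cells where truncation artifacts concentrate. Cells that
#' are NA in either map (e.g. dropped probes) are ignored.
#'
#' @param a,b maps of identical shape.
#' @param excludeEdge number of edge cells to strip on every side.
#' @return Pearson correlation coefficient.
#' @export
correlateMaps <- function(a, b, excludeEdge = 1L) {
  A <- .mapMatrix(a); B <- .mapMatrix(b)
  if (!all(dim(A) == dim(B))) stop("maps must share the same shape")
  k <- as.integer(excludeEdge)
  if (k > 0) {
    keepR <- (k + 1):(nrow(A) - k)
    keepC <- if (ncol(A) > 2 * k) (k + 1):(ncol(A) - k) else seq_len(ncol(A))
    if (length(keepR) < 3) stop("too few cells left after edge exclusion")
    A <- A[keepR, keepC, drop = FALSE]; B <- B[keepR, keepC, drop = FALSE]
  }
  ok <- is.finite(A) & is.finite(B)
  av <- A[ok]; bv <- B[ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("undefined correlation: a map is constant over retained cells")
  stats::cor(av, bv)
}

#' Correct a correlation for measurement unreliability
#'
#' Disattenuation: \eqn{r_{corrected} = r_{obs} / \sqrt{rel_a \cdot rel_b}},
#' capped to \[-1, 1\].
#'
#' @param rObs observed correlation.
#' @param reliabilityA,reliabilityB internal reliabilities in (0, 1].
#' @return corrected correlation.
#' @export
disattenuate <- function(rObs, reliabilityA, reliabilityB) {
  if (reliabilityA <= 0 || reliabilityA > 1 ||
      reliabilityB <= 0 || reliabilityB > 1)
    stop("reliabilities must lie in (0, 1]")
  max(-1, min(1, rObs / sqrt(reliabilityA * reliabilityB)))
}

#' Chi-square test of spatial uniformity
#'
#' Bins points on a regular grid and tests the counts against the uniform
#' distribution via the chi-square goodness-of-fit test. Used to check that
#' chain seeds (and early iterations) are uniform while later iterations
#' are not.
#'
#' @param points matrix of points (1 or 2 columns) in \[0,1\].
#' @param bins number of bins per axis.
#' @return list with `statistic`, `df`, `p.value`, and the count vector.
#' @export
uniformityTest <- function(points, bins = 4L) {
  P <- as.matrix(points)
  bins <- as.integer(bins)
  nb <- bins^ncol(P)
  if (nrow(P) / nb < 5)
    stop("too few points: expected count per bin below 5; reduce bins")
  idx <- rep(1L, nrow(P))
  mult <- 1L
  for (a in seq_len(ncol(P))) {
    ia <- pmin(pmax(ceiling(P[, a] * bins), 1L), bins)
    idx <- idx + (ia - 1L) * mult
    mult <- mult * bins
  }
  counts <- tabulate(idx, nbins = nb)
  ht <- stats::chisq.test(counts)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, counts = counts)
}

#' Center-of-mass baseline prior from a segmentation mask
#'
#' The classical object-center account places perceptual attractors at the
#' centers of mass of segmented regions. This builds that baseline: one
#' isotropic Gaussian bump (equal weight per region) at each labeled
#' region's centroid, normalized on the grid.
#'
#' @param mask integer matrix of region labels (> 0; 0 = background),
#'   indexed \code{mask[i, j]} with i along x and j along y, pixel centers
#'   at \code{(i - 0.5)/nrow} etc.
#' @param bumpWidth SD of each Gaussian bump (normalized units).
#' @param grid evaluation [SpatialGrid-class] (2D).
#' @return a [DensityField-class].
#' @export
centerOfMassPrior <- function(mask, bumpWidth, grid) {
  mask <- as.matrix(mask)
  labels <- sort(unique(mask[mask > 0]))
  if (length(labels) == 0) stop("input error: mask has no labeled region")
  nx <- nrow(mask); ny <- ncol(mask)
  total <- numeric(nCells(grid))
  for (lb in labels) {
    w <- which(mask == lb, arr.ind = TRUE)
    centroid <- c(mean((w[, 1] - 0.5) / nx), mean((w[, 2] - 0.5) / ny))
    total <- total + .gaussOnGrid(centroid, bumpWidth^2, grid)
  }
  normalizeField(total, grid)
}
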