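#' @include AllClasses.R AllGenerics.R grid.R observers.R chain.R
NULL

# Per-cell mean and (co)variance of the reproduction distribution, i.e. of
# each row of the transition kernel. Returns mean (ncell x ndim) and a list
# of second-moment summaries sufficient to project onto any line.
.kernelMoments <- function(kernel) {
  X <- gridCenters(kernel@grid)
  K <- kernel@probs
  mu <- K %*% X
  ex2 <- K %*% (X^2)
  vars <- pmax(ex2 - mu^2, 0)
  cov12 <- if (ncol(X) == 2L) {
    as.numeric(K %*% (X[, 1] * X[, 2])) - mu[, 1] * mu[, 2]
  } else NULL
  list(mean = mu, vars = vars, cov12 = cov12)
}

#' Mean and covariance of the reproduction distribution at a location
#'
#' The reproduction distribution \eqn{p(R \mid S = s)} is row s of the
#' transition kernel (sensory noise followed by posterior sampling). Its
#' mean reveals the average bias at s; its covariance the reproduction
#' variability entering the d' prediction.
#'
#' @param prior a [DensityField-class].
#' @param likelihood a [LikelihoodMatrix-class] on the same grid.
#' @param s a point (snapped to its cell) or integer cell index.
#' @param kernel optionally a precomputed [TransitionKernel-class].
#' @return list with `mean` (length ndim) and `cov` (ndim x ndim matrix).
#' @export
reproductionMoments <- function(prior, likelihood, s, kernel = NULL) {
  if (is.null(kernel)) kernel <- transitionKernel(prior, likelihood)
  g <- kernel@grid
  cell <- if (is.numeric(s) && length(s) == 1 && g@ndim == 2L && s == round(s) && s >= 1)
    as.integer(s) else pointToCell(s, g)
  mom <- .kernelMoments(kernel)
  mu <- mom$mean[cell, ]
  if (g@ndim == 1L) {
    list(mean = mu, cov = matrix(mom$vars[cell, 1], 1, 1))
  } else {
    list(mean = mu,
         cov = matrix(c(mom$vars[cell, 1], mom$cov12[cell],
                        mom$cov12[cell], mom$vars[cell, 2]), 2, 2))
  }
}

# Signed d' between two cells given precomputed moments, projected onto the
# (canonically oriented) line through the two continuous points.
.dprimePair <- function(mom, c1, c2, p1, p2) {
  u <- p2 - p1
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(0)
  u <- u / nu
  # canonical orientation: first nonzero component positive, so that the
  # result is antisymmetric under swapping the two points
  if (u[1] < 0 || (u[1] == 0 && u[length(u)] < 0)) u <- -u
  m1 <- sum(mom$mean[c1, ] * u); m2 <- sum(mom$mean[c2, ] * u)
  projVar <- function(cc) {
    if (length(u) == 1L) mom$vars[cc, 1]
    else u[1]^2 * mom$vars[cc, 1] + u[2]^2 * mom$vars[cc, 2] +
      2 * u[1] * u[2] * mom$cov12[cc]
  }
  v <- (projVar(c1) + projVar(c2)) / 2
  if (v <= 0) stop("degenerate variance: pooled projected variance is zero")
  (m1 - m2) / sqrt(v)
}

#' Predicted discrimination sensitivity between two locations
#'
#' Signal-detection d' predicted from the observer's reproduction
#' distributions: both distributions are projected onto the line through
#' `s1` and `s2` (avoiding 2D signal detection theory), and
#' \deqn{d'(S_1, S_2) = \frac{\tilde\mu(S_1) - \tilde\mu(S_2)}
#'   {\sqrt{(\tilde\sigma^2(S_1) + \tilde\sigma^2(S_2))/2}}}
#' is computed from the projected means and variances. The projection axis
#' is canonically oriented, making the value antisymmetric under swapping
#' the two points; maps use the absolute value.
#'
#' @param prior a [DensityField-class].
#' @param likelihood a [LikelihoodMatrix-class] on the same grid.
#' @param s1,s2 the two points.
#' @param kernel optional precomputed [TransitionKernel-class].
#' @return signed scalar d' (0 when `s1 == s2`).
#' @export
predictDprime <- function(prior, likelihood, s1, s2, kernel = NULL) {
  if (is.null(kernel)) kernel <- transitionKernel(prior, likelihood)
  g <- kernel@grid
  p1 <- asPoints(s1, g@ndim)[1, ]; p2 <- asPoints(s2, g@ndim)[1, ]
  if (all(p1 == p2)) return(0)
  mom <- .kernelMoments(kernel)
  .dprimePair(mom, pointToCell(p1, g), pointToCell(p2, g), p1, p2)
}

#' Predicted d' map over a probe grid
#'
#' For every probe point, averages |d'| over `nDir` equally spaced offset
#' directions at the given radius. Probes for which any offset leaves the
#' domain are dropped (flagged not-retained, value NA), which excludes the
#' image edges where truncation artifacts dominate.
#'
#' @param prior a [DensityField-class].
#' @param likelihood a [LikelihoodMatrix-class] on the same grid.
#' @param radius offset distance in normalized units; must exceed one cell
#'   spacing so that offset points land in distinct cells.
#' @param probes matrix of probe points (default: all grid cell centers).
#' @param nDir number of offset directions (2 in 1D: the two sides).
#' @param kernel optional precomputed [TransitionKernel-class].
#' @return a [DPrimeMap-class].
#' @export
dprimeMapPredicted <- function(prior, likelihood, radius, probes = NULL,
                               nDir = 8L, kernel = NULL) {
  if (is.null(kernel)) kernel <- transitionKernel(prior, likelihood)
  g <- kernel@grid
  if (radius <= max(g@spacing))
    stop("radius must exceed one cell spacing (", signif(max(g@spacing), 3), ")")
  shape <- integer(0)
  if (is.null(probes)) { probes <- gridCenters(g); shape <- g@shape }
  probes <- asPoints(probes, g@ndim)
  mom <- .kernelMoments(kernel)
  offsets <- if (g@ndim == 1L) matrix(c(-radius, radius), ncol = 1)
  else {
    th <- 2 * pi * (seq_len(nDir) - 1) / nDir
    cbind(radius * cos(th), radius * sin(th))
  }
  values <- rep(NA_real_, nrow(probes))
  retained <- rep(FALSE, nrow(probes))
  cellsP <- pointToCell(probes, g)
  for (i in seq_len(nrow(probes))) {
    s2 <- sweep(offsets, 2, probes[i, ], "+")
    if (any(s2 < 0) || any(s2 > 1)) next
    c2 <- pointToCell(s2, g)
    d <- vapply(seq_len(nrow(s2)), function(k)
      abs(.dprimePair(mom, cellsP[i], c2[k], probes[i, ], s2[k, ])), 0)
    values[i] <- mean(d)
    retained[i] <- TRUE
  }
  if (!any(retained))
    stop("empty map: every probe's offset leaves the domain")
  new("DPrimeMap", points = probes, values = values, shape = shape,
      radius = radius, kernelSd = 0, interpolated = FALSE,
      retained = retained)
}

#' DPrimeMap accessors
#'
#' @param map a [DPrimeMap-class].
#' @return `dprimeValues`: the per-probe d' vector (NA at dropped probes);
#'   `dprimePoints`: the probe coordinates; `dprimeMatrix`: values reshaped
#'   to the probe grid (regular-grid maps only).
#' @export
dprimeValues <- function(map) map@values

#' @rdname dprimeValues
#' @export
dprimePoints <- function(map) map@points

#' @rdname dprimeValues
#' @export
dprimeMatrix <- function(map) {
  if (length(map@shape) == 0)
    stop("map probes do not form a regular grid")
  if (length(map@shape) == 1L) matrix(map@values, ncol = 1)
  else matrix(map@values, nrow = map@shape[1], ncol = map@shape[2])
}

setMethod("show", "DPrimeMap", function(object) {
  v <- object@values[object@retained]
  cat(sprintf("DPrimeMap: %d probes (%d retained), radius %.4g, d' in [%.3g, %.3g]%s\n",
              length(object@values), sum(object@retained), object@radius,
              min(v), max(v),
              if (object@kernelSd > 0) sprintf(", smoothed (sd %.3g)", object@kernelSd) else ""))
})

#' d' from 2AFC same/shifted counts
#'
#' Equal-variance signal-detection estimate \eqn{d' = z(\mathrm{hit\ rate})
#' - z(\mathrm{false\ alarm\ rate})}, with extreme rates corrected by the
#' 1/(2N) rule (0 becomes 1/(2N), 1 becomes 1 - 1/(2N)).
#'
#' @param hits,misses shifted-condition counts (responded "shifted" / "same").
#' @param falseAlarms,correctRejections same-condition counts
#'   (responded "shifted" / "same").
#' @return scalar d'.
#' @examples
#' dprimeFromCounts(16, 4, 4, 16)  # z(0.8) - z(0.2) ~= 1.683
#' @export
dprimeFromCounts <- function(hits, misses, falseAlarms, correctRejections) {
  counts <- c(hits, misses, falseAlarms, correctRejections)
  if (any(counts < 0)) stop("counts must be nonnegative")
  nS <- hits + misses; nN <- falseAlarms + correctRejections
  if (nS <= 0 || nN <= 0) stop("both condition totals must be positive")
  clampRate <- function(r, n) {
    if (r == 0) 1 / (2 * n) else if (r == 1) 1 - 1 / (2 * n) else r
  }
  h <- clampRate(hits / nS, nS)
  f <- clampRate(falseAlarms / nN, nN)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Empirical d' map from a 2AFC dataset
#'
#' Aggregates same/shifted responses per probe point and applies
#' [dprimeFromCounts()].
#'
#' @param dataset a [TwoAFCDataset-class].
#' @return a [DPrimeMap-class] (regular probe-grid shape inferred when the
#'   probes form a full grid).
#' @export
analyze2afc <- function(dataset) {
  d <- dataset@data
  key <- paste(d$probe_x, d$probe_y, sep = "|")
  probes <- unique(data.frame(x = d$probe_x, y = d$probe_y, key = key))
  vals <- vapply(probes$key, function(k) {
    dd <- d[key == k, ]
    sh <- dd$condition == "shifted"
    dprimeFromCounts(sum(sh & dd$response == "shifted"),
                     sum(sh & dd$response == "same"),
                     sum(!sh & dd$response == "shifted"),
                     sum(!sh & dd$response == "same"))
  }, 0)
  is1d <- all(is.na(probes$y))
  pts <- if (is1d) matrix(probes$x, ncol = 1) else cbind(probes$x, probes$y)
  ux <- sort(unique(probes$x))
  shape <- integer(0)
  if (is1d) {
    ord <- order(probes$x)
    shape <- length(ux)
  } else {
    uy <- sort(unique(probes$y))
    if (nrow(probes) == length(ux) * length(uy)) {
      ord <- order(match(probes$y, uy), match(probes$x, ux))
      shape <- c(length(ux), length(uy))
    } else ord <- seq_len(nrow(probes))
  }
  new("DPrimeMap", points = pts[ord, , drop = FALSE], values = vals[ord],
      shape = as.integer(shape), radius = dataset@radius, kernelSd = 0,
      interpolated = FALSE, retained = rep(TRUE, nrow(pts)))
}

# NA-aware separable Gaussian blur on a matrix (weights renormalized over
# observed cells).
.gaussBlur <- function(V, sdSteps) {
  if (sdSteps <= 0) return(V)
  r <- max(1L, ceiling(4 * sdSteps))
  k <- stats::dnorm(-r:r, sd = sdSteps)
  blur1 <- function(M) {
    n <- nrow(M)
    out <- matrix(NA_real_, n, ncol(M))
    W <- !is.na(M)
    M0 <- ifelse(W, M, 0)
    for (i in seq_len(n)) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
      num <- colSums(M0[lo:hi, , drop = FALSE] * kk)
      den <- colSums(W[lo:hi, , drop = FALSE] * kk)
      out[i, ] <- ifelse(den > 0, num / den, NA_real_)
    }
    out
  }
  t(blur1(t(blur1(V))))
}

#' Smooth and upsample a d' map
#'
#' Convolves regular-grid d' values with a Gaussian kernel, then (optionally)
#' computes the final map through cubic-spline interpolation to a finer
#' resolution. `kernelSd = 0` with unchanged resolution is the identity.
#'
#' @param map a regular-grid [DPrimeMap-class].
#' @param kernelSd Gaussian SD in normalized units (>= 0).
#' @param targetResolution integer per-axis resolution of the output map
#'   (NULL = keep the probe grid). Must not be coarser than the probe grid.
#' @return a [DPrimeMap-class].
#' @export
smoothDprimeMap <- function(map, kernelSd = 0, targetResolution = NULL) {
  if (kernelSd < 0) stop("kernelSd must be >= 0")
  if (length(map@shape) == 0)
    stop("smoothing requires a regular probe grid")
  shape <- map@shape
  step <- vapply(seq_along(shape), function(a)
    diff(range(map@points[, a])) / max(shape[a] - 1L, 1L), 0)
  V <- if (length(shape) == 1L) matrix(map@values, ncol = 1)
  else matrix(map@values, shape[1], shape[2])
  V <- .gaussBlur(V, kernelSd / max(step))
  if (is.null(targetResolution) || identical(as.integer(targetResolution), shape)) {
    out <- map
    out@values <- as.numeric(V)
    out@kernelSd <- kernelSd
    out@retained <- is.finite(out@values)
    validObject(out)
    return(out)
  }
  target <- as.integer(targetResolution)
  if (length(target) != length(shape) || any(target < shape))
    stop("target resolution must not be coarser than the probe grid")
  # fill dropped probes by the nearest retained probe so splines are defined
  if (anyNA(V)) {
    ok <- which(is.finite(as.numeric(V)))
    if (!length(ok)) stop("empty map: no retained probes to interpolate")
    na <- which(!is.finite(as.numeric(V)))
    near <- vapply(na, function(i) {
      d2 <- rowSums(sweep(map@points[ok, , drop = FALSE], 2,
                          map@points[i, ])^2)
      ok[which.min(d2)]
    }, 0L)
    V[na] <- as.numeric(V)[near]
  }
  if (length(shape) == 1L) {
    x <- map@points[, 1]
    xo <- (seq_len(target) - 0.5) / target
    v <- stats::spline(x, as.numeric(V), xout = xo, method = "fmm")$y
    pts <- matrix(xo, ncol = 1)
  } else {
    x <- sort(unique(map@points[, 1])); y <- sort(unique(map@points[, 2]))
    xo <- (seq_len(target[1]) - 0.5) / target[1]
    yo <- (seq_len(target[2]) - 0.5) / target[2]
    Vx <- apply(V, 2, function(col) stats::spline(x, col, xout = xo, method = "fmm")$y)
    Vxy <- t(apply(Vx, 1, function(row) stats::spline(y, row, xout = yo, method = "fmm")$y))
    v <- as.numeric(Vxy)
    pts <- as.matrix(expand.grid(xo, yo, KEEP.OUT.ATTRS = FALSE))
  }
  pts <- pmin(pmax(pts, 0), 1)
  new("DPrimeMap", points = pts, values = v, shape = target,
      radius = map@radius, kernelSd = kernelSd, interpolated = TRUE,
      retained = is.finite(v))
}
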