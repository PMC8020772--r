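#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a regular spatial grid on the unit interval or square
#'
#' Coordinates are "fractions of image size": each axis spans \[0,1\] and is
#' divided into equal half-open cells with centers at \eqn{(i+0.5)/n}.
#'
#' @param shape integer vector of cells per axis; length 1 (1D) or 2 (2D).
#' @return a [SpatialGrid-class].
#' @examples
#' spatialGrid(256)      # 1D, 256 cells
#' spatialGrid(c(64, 64))
#' @export
spatialGrid <- function(shape) {
  shape <- as.integer(shape)
  ndim <- length(shape)
  if (!ndim %in% c(1L, 2L)) stop("shape must have length 1 or 2")
  centers <- lapply(shape, function(n) (seq_len(n) - 0.5) / n)
  new("SpatialGrid", ndim = ndim, shape = shape,
      centers = centers, spacing = 1 / shape)
}

#' Number of cells in a grid
#'
#' @param x a [SpatialGrid-class], [DensityField-class], or matrix-backed
#'   probability object.
#' @return integer cell count (product of the per-axis shape).
#' @rdname nCells
#' @export
setMethod("nCells", "SpatialGrid", function(x) prod(x@shape))

#' @rdname nCells
#' @export
setMethod("nCells", "DensityField", function(x) nCells(x@grid))

#' Grid accessors
#'
#' `gridShape`, `gridSpacing` and `gridDim` return the cell counts per axis,
#' the per-axis cell widths, and the dimensionality. `gridCenters` returns
#' the coordinates of every cell center as an `nCells x ndim` matrix, in
#' cell-index order (first axis fastest, matching R's column-major array
#' layout).
#'
#' @param grid a [SpatialGrid-class].
#' @return see description.
#' @export
gridCenters <- function(grid) {
  if (grid@ndim == 1L) {
    matrix(grid@centers[[1]], ncol = 1)
  } else {
    as.matrix(expand.grid(grid@centers[[1]], grid@centers[[2]],
                          KEEP.OUT.ATTRS = FALSE))
  }
}

#' @rdname gridCenters
#' @export
gridShape <- function(grid) grid@shape

#' @rdname gridCenters
#' @export
gridSpacing <- function(grid) grid@spacing

#' @rdname gridCenters
#' @export
gridDim <- function(grid) grid@ndim

setMethod("show", "SpatialGrid", function(object) {
  cat(sprintf("SpatialGrid: %s cells over [0,1]^%d (spacing %s)\n",
              paste(object@shape, collapse = " x "), object@ndim,
              paste(signif(object@spacing, 4), collapse = ", ")))
})

#' Coerce points to a matrix with one row per point
#'
#' Accepts a numeric vector (a single point of length `ndim`) or a matrix
#' with `ndim` columns. Internal convention used across the package.
#' @noRd
asPoints <- function(p, ndim) {
  if (is.null(dim(p))) {
    if (length(p) != ndim)
      stop(sprintf("expected a point of length %d or a matrix with %d columns",
                   ndim, ndim))
    p <- matrix(p, nrow = 1)
  }
  p <- as.matrix(p)
  if (ncol(p) != ndim) stop(sprintf("points must have %d columns", ndim))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("points must lie in [0,1] on every axis")
  p
}

#' Create a density field from per-cell masses
#'
#' `densityField` wraps a vector (or 2D array) of masses that already sums
#' to 1; `normalizeField` divides nonnegative raw values by their total.
#'
#' @param mass,values numeric per-cell values in cell order (first axis
#'   fastest); a matrix of dimensions `gridShape(grid)` is also accepted.
#' @param grid a [SpatialGrid-class].
#' @return a [DensityField-class] summing to 1.
#' @examples
#' g <- spatialGrid(4)
#' normalizeField(c(1, 1, 1, 1), g)  # uniform, 0.25 per cell
#' @export
densityField <- function(mass, grid) {
  mass <- as.numeric(mass)
  new("DensityField", grid = grid, mass = mass)
}

#' @rdname densityField
#' @export
normalizeField <- function(values, grid) {
  values <- as.numeric(values)
  if (length(values) != nCells(grid))
    stop("values must have one entry per grid cell")
  if (any(!is.finite(values)) || any(values < 0))
    stop("raw values must be finite and nonnegative")
  tot <- sum(values)
  if (tot <= 0) stop("degenerate density: all raw values are zero")
  densityField(values / tot, grid)
}

#' Density-field accessors
#'
#' `fieldMass` returns the per-cell mass vector, `fieldGrid` the grid, and
#' `fieldMatrix` the mass reshaped to the grid's 2D layout (x along rows).
#'
#' @param field a [DensityField-class].
#' @return see description.
#' @export
fieldMass <- function(field) field@mass

#' @rdname fieldMass
#' @export
fieldGrid <- function(field) field@grid

#' @rdname fieldMass
#' @export
fieldMatrix <- function(field) {
  g <- field@grid
  if (g@ndim == 1L) matrix(field@mass, ncol = 1)
  else matrix(field@mass, nrow = g@shape[1], ncol = g@shape[2])
}

setMethod("show", "DensityField", function(object) {
  cat(sprintf("DensityField on %s grid; mass in [%.3g, %.3g]\n",
              paste(object@grid@shape, collapse = " x "),
              min(object@mass), max(object@mass)))
})

#' Map continuous points to grid cell indices
#'
#' Returns the (1-based) index of the nearest cell center for each point.
#' Points exactly midway between two centers (i.e. on a cell boundary) break
#' toward the lower index; boundary points 0 and 1 map to the first/last
#' cell.
#'
#' @param p a point (numeric vector of length `ndim`) or matrix of points.
#' @param grid a [SpatialGrid-class].
#' @return integer vector of cell indices into the flattened cell order.
#' @examples
#' g <- spatialGrid(4)
#' pointToCell(0, g)    # 1
#' pointToCell(0.5, g)  # 2 (tie broken toward the lower index)
#' @export
pointToCell <- function(p, grid) {
  p <- asPoints(p, grid@ndim)
  axisIdx <- function(x, n) pmin(pmax(ceiling(x * n), 1L), n)
  i1 <- axisIdx(p[, 1], grid@shape[1])
  if (grid@ndim == 1L) return(as.integer(i1))
  i2 <- axisIdx(p[, 2], grid@shape[2])
  as.integer(i1 + (i2 - 1L) * grid@shape[1])
}

#' Coordinates of cell centers for given cell indices
#'
#' @param cells integer cell indices (flattened order).
#' @param grid a [SpatialGrid-class].
#' @return matrix of cell-center coordinates, one row per index.
#' @export
cellToPoint <- function(cells, grid) {
  cells <- as.integer(cells)
  if (any(cells < 1L | cells > nCells(grid))) stop("cell index out of range")
  if (grid@ndim == 1L) {
    matrix(grid@centers[[1]][cells], ncol = 1)
  } else {
    n1 <- grid@shape[1]
    i1 <- (cells - 1L) %% n1 + 1L
    i2 <- (cells - 1L) %/% n1 + 1L
    cbind(grid@centers[[1]][i1], grid@centers[[2]][i2])
  }
}

#' Kullback-Leibler divergence between two density fields
#'
#' \eqn{KL(p \| q) = \sum_i p_i \log(p_i / q_i)} over cells where
#' \eqn{p_i > 0}. Used as a convergence diagnostic for chain iterates
#' approaching the stationary distribution.
#'
#' @param p,q [DensityField-class] objects on the same grid; `q` must be
#'   strictly positive wherever `p` is positive.
#' @return nonnegative scalar; 0 iff the fields are identical.
#' @export
klDivergence <- function(p, q) {
  if (!identical(p@grid@shape, q@grid@shape))
    stop("density fields must share the same grid")
  pm <- p@mass; qm <- q@mass
  sup <- pm > 0
  if (any(qm[sup] == 0))
    stop("support violation: q has zero mass where p is positive")
  sum(pm[sup] * log(pm[sup] / qm[sup]))
}

#' Total variation distance between two density fields
#'
#' \eqn{TV(p, q) = \frac{1}{2} \sum_i |p_i - q_i|}; companion diagnostic to
#' [klDivergence()] for comparing sampled histograms with analytic iterates.
#'
#' @param p,q [DensityField-class] objects on the same grid.
#' @return scalar in \[0, 1\].
#' @export
tvDistance <- function(p, q) {
  if (!identical(p@grid@shape, q@grid@shape))
    stop("density fields must share the same grid")
  sum(abs(p@mass - q@mass)) / 2
}
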