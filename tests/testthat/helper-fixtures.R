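# Shared fixtures: small grids, standard priors and observers used across
# the test files. All randomness in tests flows through explicit seeds.

grid1d <- function(n = 64L) spatialGrid(n)
grid2d <- function(n = 16L) spatialGrid(c(n, n))

# 1D bimodal demo prior (modes 0.3 / 0.7, sd 0.08)
bimodalPrior1d <- function(grid = grid1d()) {
  makeMixturePrior(list(
    list(center = 0.3, cov = 0.08^2, weight = 1),
    list(center = 0.7, cov = 0.08^2, weight = 1)), grid)
}

# 2D bimodal prior (modes on the diagonal, sd 0.08)
bimodalPrior2d <- function(grid = grid2d()) {
  makeMixturePrior(list(
    list(center = c(0.3, 0.3), cov = 0.08^2, weight = 1),
    list(center = c(0.7, 0.7), cov = 0.08^2, weight = 1)), grid)
}

# Three landmark modes plus a broad background component: the standard 2D
# multimodal prior for discrimination analyses.
threeModePrior2d <- function(grid = spatialGrid(c(32, 32))) {
  makeMixturePrior(list(
    list(center = c(0.25, 0.3), cov = 0.1^2, weight = 1),
    list(center = c(0.75, 0.3), cov = 0.1^2, weight = 1),
    list(center = c(0.5, 0.75), cov = 0.1^2, weight = 1),
    list(center = c(0.5, 0.5), cov = 0.35^2, weight = 1)), grid)
}

uniformPrior <- function(grid) normalizeField(rep(1, nCells(grid)), grid)

# Random strictly-positive prior for property tests
randomPrior <- function(grid, seed) {
  set.seed(seed)
  normalizeField(stats::runif(nCells(grid), 0.1, 1), grid)
}

allObservers <- function(prior, sigma = 0.05) {
  list(fixed = fixedObserver(sigma),
       efficient = efficientObserver(prior, sigma),
       symmetric = symmetricObserver(prior, sigma))
}
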