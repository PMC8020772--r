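# serialrep

Simulation and analysis of **serial-reproduction (transmission-chain)
experiments** on remembered point locations, and of the Bayesian observer
models that explain them.

In a transmission chain, one person views a point overlaid on an image,
reproduces its location from memory, and the reproduction becomes the next
person's stimulus. Under a Bayesian account — each reproduction is a sample
from the posterior $p(S \mid T) \propto p(T \mid S)\,p(S)$ given a noisy
sensory encoding $T$ — the chain is a Markov chain whose **stationary
distribution is the shared spatial prior** $p(S)$, so iterating the task
reads the prior out of behavior. The package is aimed at computational
cognitive scientists and psychophysicists who want to simulate such
experiments, analyze chain datasets, and compare encoding models.

It implements, on discrete 1D/2D grids over normalized \[0,1\] coordinates:

* **Three encoder models** as likelihood matrices $p(T = x_j \mid S = x_i)$:
  fixed precision (constant isotropic Gaussian noise), symmetric variable
  precision (location-dependent symmetric noise,
  $\sigma(x) = \sigma_0\, d(x)^{-\alpha}$), and efficient encoding
  (constant noise in a perceptually warped space in which the prior is
  uniform, realized by a triangular/Knothe–Rosenblatt transform).
* **Chain machinery**: posterior, transition kernel
  $K(r \mid s) = \sum_t p(R = r \mid T = t)\,p(T = t \mid S = s)$, analytic
  propagation, sampled chains, and stationarity / detailed-balance / KL
  convergence diagnostics.
* **Discrimination analysis**: predicted d' maps from reproduction moments
  projected on the line between two probes,
  $d' = (\tilde\mu_1 - \tilde\mu_2) / \sqrt{(\tilde\sigma_1^2 + \tilde\sigma_2^2)/2}$,
  plus empirical d' maps from 2AFC same/shifted counts
  ($z(\mathrm{hit}) - z(\mathrm{fa})$ with 1/(2N) correction), smoothing and
  interpolation.
* **Prior estimators**: the nonparametric per-chain KDE (regularized
  covariances $\Sigma_i + \lambda^2 I$) and the fixed-width parametric KDE
  on last-iteration points.
* **The category adjustment model** baseline
  $R = wS + (1-w)\sum_k v_k P_k$, $v_k \propto e^{-c\|S-P_k\|}$: prediction,
  iteration, and multi-start constrained fitting with prototype matching.
* **Bias-field statistics**: binned bias vectors, the ±12° angular-coherence
  band ratio with chain-level bootstrap CIs, map correlations with edge
  exclusion, disattenuation, chi-square uniformity tests, and the
  center-of-mass baseline prior.
* **A synthetic-experiment generator** (structured priors, shape images,
  chain and 2AFC datasets) so the full pipeline runs with no external data,
  plus plain-text I/O for every data type and a `runPipeline()` front end
  with a thin CLI script (`inst/scripts/serialrep.R`).

## Worked example

Simulate a full experiment under the efficient-encoding observer, recover
the prior from the chains, and compare the two encoding models'
discrimination predictions:

```r
library(serialrep)

g   <- spatialGrid(c(32, 32))
pri <- makeMixturePrior(list(                      # two landmarks + background
  list(center = c(0.3, 0.3), cov = 0.08^2, weight = 1),
  list(center = c(0.7, 0.7), cov = 0.08^2, weight = 1),
  list(center = c(0.5, 0.5), cov = 0.35^2, weight = 1)), g)
pri
#> DensityField on 32 x 32 grid; mass in [6.88e-05, 0.00926]

lik <- buildLikelihood(efficientObserver(pri, sigmaW = 0.05), g)
K   <- transitionKernel(pri, lik)

# the prior is the chain's stationary distribution (exact up to float error)
sum(abs(fieldMass(propagateChain(K, pri, 1)[[1]]) - fieldMass(pri)))
#> [1] 1.721035e-16

chains <- simulateExperiment(pri, lik, nChains = 500, nIter = 20, seed = 1)
chains
#> ChainDataset 'synthetic' (simulated): 500 chains, iterations 0-20, 10500 rows

# last-iteration points are draws from the prior: the parametric KDE recovers it
kde <- kdeParametric(chains, g, width = 0.04)
correlateMaps(kde, pri, excludeEdge = 1)
#> [1] 0.9630747

# predicted discrimination maps: d' is high near landmarks under efficient
# encoding and low near landmarks under fixed precision
mapE <- dprimeMapPredicted(pri, lik, radius = 0.07)
mapE
#> DPrimeMap: 1024 probes (784 retained), radius 0.07, d' in [0.165, 2.51]
mapF <- dprimeMapPredicted(pri, buildLikelihood(fixedObserver(0.05), g), radius = 0.07)
c(efficient = correlateMaps(mapE, priorToMap(pri), excludeEdge = 6),
  fixed     = correlateMaps(mapF, priorToMap(pri), excludeEdge = 6))
#>  efficient      fixed
#>  0.9593810 -0.8922524
```

The stationarity error at machine precision confirms the reproduction
chain leaves the prior invariant; the KDE correlation shows 500 chains
suffice to recover a two-landmark prior; and the opposite signs of the
d'-prior correlations are the models' distinguishing prediction — only
efficient encoding predicts *better* discrimination near landmarks.

The same workflows are available declaratively:

```r
runPipeline(list(workflow = "model-compare", grid = c(32, 32)), "out/", seed = 1)
```

See the methods vignette
(`vignettes/serial-reproduction-models.Rmd`) for the model definitions,
numerical conventions (grid discretization, boundary truncation, edge
exclusion bands, dequantization of simulated points), and the rationale for
every default parameter.

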