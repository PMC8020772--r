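---
title: "Bayesian observer models of serial reproduction: methods and design choices"
author: "serialrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian observer models of serial reproduction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialrep)
```

# The problem

In a serial-reproduction (transmission-chain) experiment on spatial memory,
a participant sees a point overlaid on an image, reproduces its location
from memory, and that reproduction becomes the stimulus for the next
participant. Iterating this "telephone game" amplifies shared perceptual
biases: under a Bayesian account, the chain of reproductions is a Markov
chain whose stationary distribution is the participants' shared spatial
prior over the image. `serialrep` implements that account end to end on a
discrete grid: observer models, the induced chain, discrimination (d')
predictions, prior estimators, the category adjustment model baseline, and
a synthetic-experiment generator so every analysis runs without human data.

# The generative model

All coordinates are normalized to the unit interval/square ("fraction of
image size"). A `SpatialGrid` divides each axis into $n$ equal cells with
centers at $(i+0.5)/n$; all probability objects are discrete masses per
cell, so integrals become sums.

The observer sees a true location $S$, encodes it into a noisy sensory
representation $T$ with likelihood $p(T \mid S)$, and reproduces a location
$R$ by sampling the posterior

$$p(R = r \mid T = t) = \frac{p(T = t \mid S = r)\,\pi(r)}
  {\sum_{r'} p(T = t \mid S = r')\,\pi(r')},$$

where $\pi$ is the spatial prior. One chain step is therefore

$$K(r \mid s) = \sum_t p(R = r \mid T = t)\, p(T = t \mid S = s),$$

implemented by `transitionKernel()`. Two exact consequences, used as
machine-precision correctness checks throughout the test suite: $\pi$ is
the stationary distribution of $K$, and $K$ satisfies detailed balance
$K(r \mid s)\pi(s) = K(s \mid r)\pi(r)$ — both hold for *any*
row-stochastic likelihood, because the posterior uses the same prior.
A corollary (the data-processing inequality) is that
$\mathrm{KL}(p_n \,\|\, \pi)$ is non-increasing along the chain, which the
package exposes as a convergence diagnostic (`klDivergence`,
`propagateChain`).

## The three encoders

`buildLikelihood()` constructs $p(T = x_j \mid S = x_i)$ for:

* **Fixed precision** (`fixedObserver`): isotropic Gaussian rows of
  constant SD $\sigma$, truncated to the domain by renormalizing over
  in-domain cells. Predicts the perceptual magnet effect: *lower*
  discriminability near prior modes.
* **Efficient encoding** (`efficientObserver`): constant isotropic noise of
  SD $\sigma_w$ in a *perceptually warped* coordinate space in which the
  prior is uniform. We realize the warp as the triangular
  (Knothe–Rosenblatt) transform (`warpForward`): axis 1 through the
  marginal CDF, axis 2 through the conditional CDF given the axis-1 cell.
  It is exact, computable, pushes the prior to the uniform distribution,
  and reduces to the classical 1D CDF warp. Each likelihood row is the
  Gaussian evaluated at the warped cell centers, renormalized over cells.
* **Symmetric variable precision** (`symmetricObserver`): symmetric
  Gaussian rows whose local SD is $\sigma_0 \cdot d(x)^{-\alpha}$, with
  $d(x)$ the prior density relative to uniform. By default $\alpha = 1$ in
  1D and $1/2$ in 2D — the linear scale factor of a volume-matching warp —
  so this model matches the efficient model's local precision and the two
  differ only in bias structure.

A mass floor of $10^{-12}$ per cell is added (and renormalized) before
warping or conditioning, so conditional CDFs never degenerate; the
perturbation is far below every tolerance used downstream.

Two subtleties of the efficient construction are worth stating because they
are easy to get backwards. First, the *encoding* rows lean toward the
sparsely coded (low-prior) side of the true location: cells there are
closely spaced in warped coordinates, so more of them fall under the warped
Gaussian. It is the *reproduction* distribution — encoding followed by
Bayesian decoding, i.e. a row of the transition kernel — that is on average
attracted toward the nearer prior mode, and this attraction holds in the
moderate-distance field around a mode while a small repulsion can appear
right at the flanks (the classic efficient-coding signature). The tests
assert the response-level attraction, which is the behaviorally observable
claim. Second, precision: the Euclidean spread of reproduction rows is
smallest near modes, which is what drives the discrimination predictions
below.

# Discrimination (d') maps

For two locations, `predictDprime()` projects both reproduction
distributions onto the line through the two points (avoiding 2D signal
detection theory) and returns

$$d'(S_1, S_2) = \frac{\tilde\mu(S_1) - \tilde\mu(S_2)}
 {\sqrt{(\tilde\sigma^2(S_1) + \tilde\sigma^2(S_2))/2}}$$

from the projected means and variances of the kernel rows. The projection
axis is canonically oriented so the value is antisymmetric under swapping
the points; maps use $|d'|$. `dprimeMapPredicted()` averages $|d'|$ over
`nDir = 8` equally spaced offset directions at a fixed radius and drops
probes whose offset leaves the domain.

Empirical maps come from 2AFC same/shifted counts:
`dprimeFromCounts()` computes $z(\mathrm{hit}) - z(\mathrm{fa})$ with the
$1/(2N)$ correction for extreme rates, `analyze2afc()` aggregates a
`TwoAFCDataset`, and `smoothDprimeMap()` applies Gaussian smoothing
followed by cubic-spline interpolation to a finer resolution.

## Edge artifacts and exclusion bands

Truncating Gaussians at the frame boundary (renormalization, no reflection)
systematically shrinks reproduction variance and compresses means near the
edges. For the fixed model this creates a strong center-high/edge-low d'
gradient that can swamp the model's genuine magnet effect in map
correlations. Analyses that correlate maps with the prior therefore exclude
an edge band of one offset radius plus the largest noise SD in play
(`correlateMaps(..., excludeEdge = )`); with that band, the predicted
d'-prior correlation is robustly positive for the efficient model and
negative for the fixed model across the noise sweep
$\sigma \in \{0.04, \dots, 0.12\}$ — the package's model-comparison
signature (`runPipeline(workflow = "model-compare")`).

# Estimating priors from chains

Two kernel density estimators mirror standard practice:

* `kdeNonparametric()`: per chain, the mean $\mu_i$ and covariance
  $\Sigma_i$ of all reproductions (iterations $\ge 1$; the uniform seed is
  excluded so it cannot bias every chain toward uniform), regularized as
  $\Sigma_i' = \Sigma_i + \lambda^2 I$ ($\lambda = 0.015$ for shape-like,
  $0.020$ for natural-image-like stimuli), mixed with equal weights.
* `kdeParametric()`: isotropic kernels of fixed width on last-iteration
  points only ($0.025$ shape-like, $0.040$ natural-image-like). Because
  last-iteration points are approximate draws from the stationary
  distribution, this estimator is the workhorse for quantitative
  comparisons.

One discretization rule matters: simulated chain points are quantized to
grid cells, so the kernel width should not be smaller than the cell
spacing. On the 32x32 grids used for the 2D studies (spacing 0.031) the
package uses width 0.040.

# The category adjustment model

The descriptive baseline reconstructs
$R = wS + (1-w)\sum_k v_k P_k$ with softmax pull
$v_k \propto e^{-c\|S - P_k\|}$ (`camPredict`). `camFit()` minimizes mean
squared prediction error over $(w, c, P_{1:M})$ with box constraints by
multi-start L-BFGS-B (k-means initialization on responses plus per-restart
jitter, 20 restarts, seeded; the optimizer tolerances are `optim`
defaults). Prototype labels are unidentifiable, so recovery is assessed
after optimal assignment (`matchPrototypes`; exhaustive over permutations
for $M \le 8$). `camIterate()` exposes the fixed-point view: with one
prototype and no noise, the distance to $P$ contracts by exactly $w$ per
step.

# Bias fields and angular coherence

`biasField()` bins single-trial biases $R_n - S_n$ by the shown location;
`angularCoherence()` compares the average bias vectors of nearby bins
(centers within 0.05; bins of 0.025) and reports the probability of
absolute angular differences within ±12° relative to the uniform
expectation (the "band ratio"). Consistent landmark-directed biases push
the ratio above 1; independent symmetric noise leaves it at 1. Confidence
intervals come from `bootstrapCI()`, which resamples whole chains (1000
replicates) to respect within-chain dependence.

Three analysis choices proved essential and are defaults or documented
options:

* **Pool all iterations** (`iteration = NULL`): a single iteration gives
  roughly one trial per bin and a noise-dominated field; pooling the ~20
  transitions per chain makes the efficient model's coherence unambiguous
  (band ratio ~4, CI excluding 1) while the symmetric model stays at 1.
* **Dequantize simulated points** (`simulateExperiment(dequantize = TRUE)`):
  cell-center snapping restricts short bias vectors to a few lattice
  directions, which *spuriously* inflates coherence for any model with
  small steps. Uniform within-cell jitter (seeded, deterministic) removes
  the artifact without changing the cell-level process.
* **Interior analysis window** (`edgeBuffer = 0.15`): boundary truncation
  pulls responses coherently inward under every model; the coherence
  statistic is computed on bins away from the frame, the same edge-exclusion
  logic as for d' maps.

The supporting statistics are `correlateMaps()` (Pearson, with edge
exclusion), `disattenuate()` (correction for attenuation
$r/\sqrt{\rho_a\rho_b}$, capped), `uniformityTest()` (chi-square on a
regular bin grid — the specific test is a package choice; seeds and first
iterations come out uniform, later iterations do not), and
`centerOfMassPrior()` (the classical object-center baseline: equal-weight
Gaussian bumps at segmentation-region centroids).

# The synthetic-experiment generator

`makeMixturePrior()` and `makeShapePrior()` build structured priors
(Gaussian mixtures; edge ridges plus vertex bumps for circle, triangle,
square, pentagon at circumradius 0.35, ridge width 0.02);
`makeShapeImage()` renders outline rasters; `simulateExperiment()` draws
uniform seeds and runs posterior-sampling chains (one child seed per chain
by a fixed splitting rule, so subsets are independently reproducible);
`simulate2afc()` draws same/shifted responses from the equal-variance
signal-detection model with unbiased criterion,
$P(\text{"shifted"} \mid \text{shifted}) = \Phi(d'/2)$ and
$P(\text{"shifted"} \mid \text{same}) = \Phi(-d'/2)$, with $d'$ the
direction-averaged predicted value at the probe (a per-trial random
direction with direction-specific $d'$ would be the finer-grained
alternative; the averaged form makes the generating map exactly
recoverable). The generator also provides controlled *violations* for
method checks: interleaved uniform dummy trials (`dummyEvery`) and a
carry-over observer that mixes the previous trial's stimulus into the
current one (`carryOver`), which `markovDummyCheck()` detects as a drop in
KDE correlation.

## Study conditions

The default conditions, chosen once to emulate the experimental scale:
500 chains of 20 iterations with uniform seeds; observer noise 0.05 (all
models, normalized units); 1D analyses on 64 cells with a bimodal prior
(modes 0.3/0.7, SD 0.08); 2D analyses on 32x32 with two or three landmark
modes (SD 0.08–0.10) over a broad background component (SD 0.35). The
background matters twice over: real spatial priors do not vanish between
landmarks, and a near-zero-density periphery both explodes the
symmetric-variable model's local noise and dominates the fixed model's d'
map. Probe offsets use radius 0.07 (the spacing-relative analogue of a
few-pixel shift; the radius must exceed one cell spacing for offset points
to land in distinct cells) with 20 trials per probe and condition, 2000
for estimator-consistency checks. The closed-form d' check uses a 250-cell
1D grid so that the probe pair (0.45, 0.55) falls exactly on cell centers —
mid-cell probes add a ~2% snapping error that belongs to the probe, not
the method.

# What passing tests do and do not show

The generator produces exactly the model class the analyses assume:
shared priors, Markov chains, posterior sampling, no reproduction noise
(reproduction noise is deliberately not modeled; adding it would not change
the qualitative bias–discriminability relation), no participant
heterogeneity, lapses, or sequential strategies, and priors that are smooth
mixtures rather than image-derived. Green tests therefore certify the
machinery — stationarity, convergence, estimator consistency, the
discrimination sign contrast, recovery of known generating structure — not
that human data obey these models. Known limitations: boundary truncation
is handled by renormalization (no reflective or toroidal option); the 2D
warp is the triangular transform, one of several constructions compatible
with "constant precision in warped coordinates" (results can depend on the
axis ordering for strongly anisotropic priors); grids are uniform and
memory for the $N^2 \times N^2$ 2D likelihood matrices limits resolution
(64x64 is practical on a laptop, 32x32 is used for the heavier sweeps);
and the CAM fit is a nonconvex optimization for which multi-start is a
mitigation, not a guarantee.
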