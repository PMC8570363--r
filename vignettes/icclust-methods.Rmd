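---
title: "Integrative generalized convex clustering: models and methods"
author: "icclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative generalized convex clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icclust)
```

## The model

`icclust` clusters samples that are measured in one or several *data views*
-- sample-by-feature matrices sharing rows but differing in feature type:
continuous expression values, sequencing counts, binary indicators,
methylation proportions. Each view $X^{(k)} \in \mathbb{R}^{n \times p_k}$
gets a convex loss $\ell_k$ appropriate to its type, and a centroid matrix
$U^{(k)}$ of the same shape. The estimator solves

$$\min_{U^{(1)},\dots,U^{(K)}}\;
  \sum_k \pi_k\,\ell_k(X^{(k)}, U^{(k)})
  \;+\; \gamma \sum_{i<i'} w_{ii'}\,
        \big\lVert (U^{(1)}_{i\cdot},\dots,U^{(K)}_{i\cdot}) -
                   (U^{(1)}_{i'\cdot},\dots,U^{(K)}_{i'\cdot})
        \big\rVert_2
  \;+\; \alpha \sum_k \sum_j \zeta_j^{(k)}\,
        \lVert U^{(k)}_{\cdot j} - \tilde{x}_j^{(k)} \mathbf{1}_n \rVert_2 .$$

The **fusion penalty** (level $\gamma$) is a group norm on the pairwise
differences of *concatenated* centroid rows, so samples merge into the same
cluster simultaneously in every view; two samples are in one cluster when
their centroid rows coincide. The **shifted group-lasso penalty** (level
$\alpha$) shrinks whole centroid columns towards the feature's
*loss-specific center* $\tilde{x}_j$ -- the minimizer of the loss for that
column (the mean for squared error, the median for absolute error, the
log-mean for the Poisson log-likelihood). A column shrunk exactly to its
center carries no cluster information and is *unselected*; feature
selection and clustering are performed jointly. With one view and $\alpha =
0$ the problem is generalized convex clustering; with the Euclidean loss on
centered data and $\alpha > 0$ it is sparse convex clustering.

Both penalties shrink towards the same loss-specific centers, which is what
makes selection coherent for non-Gaussian losses: with an $\ell_1$ loss,
"irrelevant" means "equal to the median", not "equal to zero".

### Losses

The implemented families (`lossFamilies()`) split into

* distances: `euclidean` ($\tfrac12\lVert x-u\rVert_2^2$), `manhattan`,
  `minkowski` ($q \ge 1$), `chebychev`, `mahalanobis` (positive-definite
  $C$);
* log-likelihood losses on the natural-parameter scale: `poisson_ll`,
  `bernoulli_ll`, `negbin_ll` (dispersion $\theta$ supplied by the user;
  the package does not estimate it);
* deviances on the mean scale: `poisson_dev`, `binomial_dev`, `negbin_dev`,
  with $x\log(x/u)$ defined as $0$ at $x = 0$ and means clamped away from
  the boundary at $10^{-8}$ before logs and logits.

The two parameterizations are never mixed within a view: `*_ll` centroids
live on the link scale (center = log or logit of the column mean), `*_dev`
centroids on the mean scale. The hinge, Kullback–Leibler, Hamming and
Canberra names are recognized but not implemented (the latter two are not
convex).

### Loss weights

$\pi_k$ puts heterogeneous views on a common scale. We set it to the
reciprocal of the view's *null deviance*: the loss at the loss-specific
centers minus the loss at saturation ($u = \mathrm{link}(x)$). For distance
and deviance losses the saturated loss is zero and this is literally the
loss at the centers; for log-likelihood losses the subtraction is required
for positivity (the raw log-likelihood value at the center can be negative,
e.g. the Poisson term $-x\log\bar{x} + \bar{x}$ whenever $\bar{x} > e$),
and it is the quantity that the likelihood-ratio argument behind the
weighting actually refers to. `nullDevianceWeight()` implements this;
constant views are rejected as degenerate.

## Fusion weights

Sparse, data-adaptive weights $w_{ii'}$ determine which sample pairs can
fuse. `ccWeights()` builds the dissimilarity -- the view's own loss as a
pairwise metric for a single view (deviance-based losses symmetrized as
$\ell(x_i, c(x_j)) + \ell(x_j, c(x_i))$, a choice we document because no
standard symmetrization exists), or the range-normalized mixed-type Gower
distance pooled over views -- and passes it to `kernelWeights()`:
a $\kappa$-nearest-neighbor mask (union rule: $i$ in $j$'s neighborhood *or
vice versa*; ties broken towards the lower index) combined with either a
Gaussian kernel $e^{-\phi d}$ or symmetrized stochastic-neighbor-embedding
probabilities $p_{ij} = (p_{j|i} + p_{i|j})/2n$. Defaults: $\kappa = 5$ and
$\phi$ such that $\phi \cdot \mathrm{median}(d) = 1$; both are exposed, and
the SNE scheme is preferred in high dimensions or with outliers because row
normalization keeps outlying samples connected at workable weights.

## The solver

`ccFit()` runs a multi-block ADMM on the consensus form with stacked
fusion variable $V = D[U^{(1)} \cdots U^{(K)}]$, where $D$ is the signed
edge incidence matrix of the weight graph. Each outer iteration takes *one*
inexact sub-problem update per view, then the joint fusion update
(rowwise block soft-threshold of $DU + \Lambda$ at $\gamma w_l / \rho$) and
dual ascent:

* **smooth views** get a majorized quadratic update: solve in the metric
  $\pi_k L_k I + \rho D^\top D\,(+\,\rho I$ when $\alpha > 0)$ with a
  per-view curvature bound $L_k$ maintained by doubling whenever the
  quadratic bound fails ($L = 1$ exactly for the Euclidean loss, whose
  update is therefore the exact sub-problem solution; $1/4$ initial for
  Bernoulli). The feature penalty enters through an $R$-splitting
  ($R = U - \tilde{X}$) with its own dual, so selected/unselected columns
  are read off exactly;
* **non-differentiable distance views** ($f(X - U)$ with $f$ convex) get
  one sweep of a four-variable splitting: a linear solve with the cached
  Cholesky factor of $D^\top D + 2I$, the loss prox
  $Z = \mathrm{prox}_{\pi_k f/\rho}$ (elementwise soft-threshold for
  $\ell_1$; an $\ell_1$-ball projection residual for $\ell_\infty$), the
  columnwise feature prox, and the two dual updates.

The pure-R engine (`engine = "r"`) instead implements the textbook
per-column proximal-gradient step with backtracking line search for all
smooth losses (and supports Minkowski/Mahalanobis views); it reaches the
same objective and serves as a cross-check, as does `fitFullADMM()`, which
iterates every sub-problem to an inner tolerance. By convexity all routes
agree; the test suite verifies this and compares against an independent
smoothed-objective BFGS solver on small problems.

Numerical choices: stopping on Boyd-style relative primal/dual residuals at
$10^{-5}$ (primal scaled by the larger of $\lVert DU\rVert$,
$\lVert V\rVert$ and 1% of the data norm so that the fully fused regime is
reachable; dual scaled by the dual-variable magnitude); residual balancing
that doubles or halves $\rho$ when the residuals drift more than a decade
apart, rescaling the scaled duals; warm starts carry $U$, $V$, all duals
and the adapted $\rho$. Mean-scale deviance centroids are clamped into
their open domains as a safeguard. Cluster labels are the connected
components of the exactly-zero rows of $V$ (with a threshold relative to
both the largest difference and the centroid scale, so numerically-zero
patterns in fully fused regimes do not fragment); feature masks are read
from the splitting variable that carries the exact zeros.

## Choosing the penalties

`fitForClusters()` searches $\gamma$ for a target number of clusters by a
warm-started multiplicative ladder plus bisection. Counting is by *bulk*
clusters -- components with at least `min_size` (default 2) members --
because on data with outliers the path routinely carries a few unfused
singleton stragglers long after the bulk structure has formed; an exact
component count then often has *no* attaining $\gamma$ at all (we verified
this against an exact reference solver on the benchmark scenarios).
Stragglers keep their own labels. Among attaining fits we prefer the fewest
stragglers, then the tightest partition (total loss with every sample at
its cluster's loss-specific center), then the smallest $\gamma$ (least
regularization). `fitForTargets()` adds a log-scale bisection on $\alpha$
for a target number of selected features, re-targeting $\gamma$ at every
probe. `bicSelect()` scores a solved `solvePath()` grid by
$2\sum_k \pi_k \ell_k + \log(n)\,\mathrm{df}$ with
$\mathrm{df} = (\#\text{clusters})\times(\#\text{selected features})$ --
an information-criterion variant in the standard convex-clustering/
group-lasso accounting, not a reproduction of any published formula.

## The adaptive scheme

Uninformative features corrupt both the selection path and the fusion
weights. `adaptiveFit()` therefore iterates a reweighting loop
(`rounds = 2` by default, keeping the best-ranked candidate across rounds):

1. an initial partition at the target cluster count;
2. feature importances $\mathrm{imp}_j = \lVert \hat{U}_{\cdot j} -
   \tilde{x}_j \mathbf{1} \rVert_2$ evaluated at the partition's
   loss-specific cluster centers, feature weights
   $\zeta_j = g_j \,(\max_j \mathrm{imp}_j + \epsilon) / (\mathrm{imp}_j +
   \epsilon)$ with $\epsilon$ at 1% of the view's largest importance and
   $g_j = \pi_k \lVert \nabla_j \ell_k \rVert$ the column's stationary
   gradient scale at the loss-specific centers (see below), and fusion
   weights rebuilt from the importance-weighted Gower distance (each
   feature scaled by $\mathrm{imp}_j / \max_j \mathrm{imp}_j$ and each
   view by $1/\pi_k$);
3. a refit at the cluster target (and, in the final round, the joint
   $(\gamma, \alpha)$ search when a feature target is given).

Four of these choices deserve justification because the design was
genuinely open:

* **Initial partition.** We take Ward clustering on the same Gower
  distances that drive the fusion weights rather than an initial convex
  fit. On noise-dominated views the unit-weight convex path has no
  intermediate structure -- it collapses from all-singletons to one
  cluster, which is also what the plain integrative fit's near-zero
  accuracy on the high-dimensional benchmarks reflects -- and a
  with-penalty initial fit either leaves every feature selected or
  collapses all of them for distance losses, whose unit-weight selection
  thresholds are identical across columns. Initializing the weights from a
  cheap consistent clustering parallels initializing the adaptive lasso
  from an unpenalized estimator; every subsequent fit, including the
  reported one, is a convex clustering fit. The initializer is itself
  iterated to self-consistency: two further Ward passes on distances
  reweighted by the previous partition's importances. With hundreds of
  noise features against ten informative ones, a single unweighted pass is
  dominated by the noise mass (linear importance weights still leave it
  several times the signal mass), and the reweighted passes suppress it
  at negligible cost -- no model fitting is involved.
* **Cross-view scale of $\zeta$.** At the solution, column $j$ of view
  $k$ collapses to its center exactly when $\alpha\,\zeta_j$ exceeds
  $\lVert \pi_k \nabla_j \ell_k \rVert_2$ there. Because
  $\pi_k \sim 1/\text{(null deviance)}$ shrinks with the view's width,
  a common $\alpha$ with purely rank-based weights systematically
  under-shrinks small views and over-shrinks wide ones. Folding the
  stationary gradient scale $g_j$ (the $\sqrt{n}$ subgradient bound for
  non-smooth losses) into $\zeta_j$ makes one $\alpha$ an approximately
  uniform relative-importance cutoff across views; $\zeta$ is then
  rescaled to a global minimum of 1, which only reparametrizes $\alpha$.
  For a single view with a distance loss this reduces to the rank-based
  weights exactly.
* **Importances at partition centers.** The raw ADMM centroids contract
  towards the global center as $\gamma$ grows, washing out the importance
  ranking at exactly the consolidated fits one wants to learn from;
  evaluating at the partition's own loss-specific cluster centers removes
  this contraction bias (the analogue of refitting after selection).
* **Scale of $\epsilon$.** A fixed $\epsilon$ (0.01 in the original
  formulation) silently dominates whenever fitted deviations are small;
  making it relative to the view's largest importance keeps the intended
  ~100:1 penalty ratio between noise and informative features regardless
  of the scale the fitted deviations happen to live on.

## Synthetic benchmarks

`simSingleView()` and `simMultiView()` generate the evaluation scenarios:
$n = 120$ samples in three equal clusters, 10 informative features per
view. Spherical single-view data draws informative features from
$N(\mu_k, I_{10})$ with class means $(-2.5\cdot\mathbf{1}_5, \mathbf{0}_5)$,
$(\mathbf{0}_5, 2.5\cdot\mathbf{1}_5)$, $(2.5\cdot\mathbf{1}_5,
\mathbf{0}_5)$ and replaces 5% of each class with $N(\mu_k, 25 I_{10})$
outliers; count data uses Poisson classes with means 1/4/7 and noise
features with random integer means in 1..10. Multi-view scenarios pair a
Gaussian view ($N(\mu_k, 3I)$), a Poisson view (class means 2/4/6) and a
Bernoulli view (class rates 0.5/0.2/0.8), with view dimensions up to
(200, 100, 50); noise features come from the null form of each
distribution ($N(0,1)$; Poisson with per-feature random integer means;
Bernoulli with per-feature rates uniform on $(0.2, 0.8)$ -- the latter two
are our choices, as the source conditions only fix the single-view noise).

The three-interlocking-half-moons geometry uses unit-radius arcs at
horizontal offsets 0, 1, 2 with the middle arc inverted and vertically
shifted by 0.5, five independent coordinate pairs forming the 10
informative features, and Gaussian jitter (sd 0.1 single-view, 0.2
multi-view; outlier rows get five-fold jitter). Count and proportion moon
views are rank-based copula transforms of independent moon draws through
Poisson(4) and Beta(2, 2) quantile functions. All of these geometry and
copula parameters are our documented choices -- the source describes the
constructions but not their constants -- so benchmark results on the moon
scenarios are comparable up to those choices; we checked that standard
baselines (k-means, hierarchical clustering on Gower distances) perform on
these generators in the same range as the reference report.

What the generators do *not* emulate: correlated noise, batch effects,
view-specific sample subsets (block missingness), zero inflation, or
overdispersion beyond the negative binomial -- passing tests on these
benchmarks says nothing about such complications.

## Problem sizes and runtime choices

The package's own test and reproduction scripts run everything at the
benchmark size $n = 120$ with total dimension up to 350, a ~400-edge
5-NN graph, solver tolerance $10^{-5}$, and an iteration cap of 3000 for
scripted searches (10000 interactively). At this size one penalized fit
takes a fraction of a second; a cluster-count search a few seconds; a full
adaptive run with feature targets under a minute. Replicate counts in the
reproduction script (20 for the cheap low-dimensional scenarios, 5 for
adaptive high-dimensional ones) were chosen to keep the whole script in the
tens of minutes on one core; reported means are therefore subject to
Monte-Carlo error of a few hundredths.

## Known limitations

* Multinomial losses and the non-convex Hamming/Canberra distances are out
  of scope; hinge and KL rows of the loss table are recognized names only.
* The negative-binomial dispersion is a required user input.
* No missing-data support: views must be complete and share all rows.
* The fusion graph must be connected for full fusion to the loss-specific
  centers to be attainable; `kernelWeights()` warns otherwise.
* Cluster counts along the path are not strictly monotone in $\gamma$, and
  on noise-dominated data the unweighted path can jump from all-singletons
  to a single cluster; the bulk-count search and the adaptive scheme exist
  precisely to cope with this, but an exact component count remains
  unattainable on such paths.
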