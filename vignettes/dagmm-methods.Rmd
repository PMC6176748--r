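---
title: "Learning subject-specific DAGs with mixed-effects structural equation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning subject-specific DAGs with mixed-effects structural equation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagmm)
```

## The model

`dagmm` learns a directed acyclic graph (DAG) over $p$ observed, centered
node variables $M_{i1}, \dots, M_{ip}$ from $n$ independent subjects,
while letting the *strength* of every causal link vary across subjects.
Each node obeys a structural equation with mixed effects:

$$
M_{ij} \;=\; \sum_{k \in \mathrm{pa}(j)}
  \big(\beta_{jk}^{\top} X_i + \gamma_{ijk}\big)\, M_{ik} + \varepsilon_{ij},
\qquad
\gamma_{ijk} \sim N(0, \sigma^2_{jk}),\quad
\varepsilon_{ij} \sim N(0, \sigma^2_{\varepsilon j}),
$$

where $X_i$ is a vector of $d$ exogenous covariates. An edge
$k \to j$ exists when $\beta_{jk} \neq 0$ or $\sigma^2_{jk} > 0$: the
fixed effect $\beta_{jk}^{\top}X_i$ is the covariate-driven average
causal effect, and the random effect $\gamma_{ijk}$ absorbs latent,
subject-level effect modification. The direction of every edge is shared
across subjects; only magnitudes differ.

Because the joint distribution of the nodes is non-Gaussian (random
slopes multiply other nodes), the model carries asymmetric distributional
information, and — under a heterogeneity condition on the fixed effects
(for every node with children, the summed squared child-edge effects
$\sum_j (\beta_{jk}^{\top}X)^2$ must not be constant in $X$) — the DAG
and all parameters are identifiable from purely observational data. The
package's test suite exercises this as an orientation-asymmetry property:
on two-node data with heterogeneous effects, the true orientation attains
the strictly smaller minimized objective, and the fitted direction
matches the generating one in at least 90% of seeds at $n = 2000$.

For a DAG-compatible coefficient matrix, $\det(I - B(X_i) - \Gamma_i) = 1$
(the matrix is permutation-triangular), and integrating the random
effects out yields a closed-form marginal likelihood. Its negative
logarithm, dropping $2\pi$ constants, is the package's central objective:

$$
\ell_n = \sum_{i=1}^n \sum_{j=1}^p \left[
 \frac{\big(M_{ij} - \sum_{k\neq j}(\beta_{jk}^{\top}X_i) M_{ik}\big)^2}
      {w_{ij}}
 + \log w_{ij} \right],
 \qquad
 w_{ij} = \sum_{k \neq j} \sigma^2_{jk} M_{ik}^2
          + \sigma^2_{\varepsilon j}.
$$

Two facts about $\ell_n$ shape the whole implementation:

* it **separates across nodes**, so each node can be estimated on its own;
* each per-observation term is exactly $-2\log$-density up to a constant,
  i.e. $\ell_n$ lives on the **deviance scale**. Model-selection criteria
  therefore use $\ell_n + k\log n$, *not* $2\ell_n + k\log n$; doubling
  the term would silently halve the effective BIC penalty (we measured
  exactly this failure mode: overfit skeleton edges with deviance gains
  of 16–33 survived a halved penalty of 13.8 at $n = 500$ and produced
  spurious final edges).

The correctness of $\ell_n$ itself is guarded by an independent
quadrature oracle (`marginal_density_oracle()`): tensor-product
Gauss–Hermite integration of the conditional Gaussian density over up to
three random effects, which must reproduce
$\ell_n = -2\sum_i \log f_i - np\log 2\pi$ to $10^{-4}$ relative error.

## Estimation for a fixed graph

`fit_node()` minimises one node's term of $\ell_n$ by alternating

1. weighted least squares for the stacked coefficients
   $\{\beta_{jk}\}_{k \in \mathrm{pa}(j)}$ with weights $1/w_{ij}$, and
2. Newton–Raphson steps on the *log* variances
   $(\log\sigma^2_{jk}, \log\sigma^2_{\varepsilon j})$, with backtracking
   halving when a step fails to decrease the objective and a ridge
   fallback when the Hessian is indefinite,

until the relative change of the node objective falls below `rel_tol`
($10^{-6}$ by default, at most 100 outer iterations; non-convergence is a
warning, not an error). Optimizing variances on the log scale keeps them
positive; all variances are additionally floored at
`variance_floor = 1e-8` so the objective stays finite for degenerate
data (a constant node column, for instance, gets the floor as its error
variance). With no parents the minimiser is the closed form
$\hat\sigma^2_{\varepsilon j} = n^{-1}\sum_i M_{ij}^2$. The fit is
checked in the tests against a general-purpose quasi-Newton optimizer
started at the truth, and against its parameter-recovery behaviour at
$n = 5000$.

These kernels (and the two coordinate-descent solvers below) are written
in C++ via Rcpp/RcppArmadillo: the procedure refits single nodes
thousands of times during a study, and the alternating scheme is exactly
the kind of tight numerical loop the field's packages compile.

## Step 1 — the sparse skeleton

With all $p(p-1)$ ordered pairs as candidates, unpenalized likelihood
fitting would return a complete graph. The skeleton stage therefore
solves two $\ell_1$-penalized moment problems per node, sharing one
penalty per stage across nodes:

* **Fixed effects.** The node column is regressed on the
  $(p-1)\,d$ interaction features $X_{il} M_{ik}$ with an $\ell_1$
  penalty $\lambda_1$ on all coefficients (including any intercept
  column of $X$). Solved by coordinate descent with soft-thresholding
  (exact zeros); convergence is declared on the KKT residual
  ($10^{-7}$ relative to $\lambda_{\max}$), which the tests verify
  directly and against an independent lasso implementation.
* **Random-effect variances.** With $\tilde R_{ij}$ the residual at the
  current $\tilde\beta$, the squared residuals are regressed on the
  squared candidate-parent columns $M_{ik}^2$ plus an unpenalized
  positive intercept ($\sigma^2_{\varepsilon j}$), subject to
  $\sigma^2_{jk} \ge 0$, with penalty $\lambda_2 \sum_k \sigma^2_{jk}$
  (linear, because of the sign constraint). Projected coordinate descent
  gives exact zeros on the boundary; this exploits the model's marginal
  moment identity
  $\operatorname{Var}(M_{ij} \mid \text{rest}) = \sigma^2_{\varepsilon j}
   + \sum_k \sigma^2_{jk} M_{ik}^2$.

An edge enters the skeleton when either its fixed-effect block or its
variance estimate is nonzero; the skeleton parameters are then refit
without penalty by `fit_node()` on the selected support.

Three design choices here were genuinely open and deserve their
rationale:

* **Sweep count.** The description of the two objectives suggests
  alternating them; but the fixed-effect objective does not involve the
  variance estimates at all, so a second sweep solves an identical
  problem. One $\beta$-sweep followed by one $\sigma^2$-sweep is a fixed
  point of the alternation and is what the package runs.
* **Penalty grids.** Each stage uses 50 log-spaced values from
  $\lambda_{\max}$ (the KKT-derived smallest penalty with an all-zero
  solution) down to $10^{-6}\lambda_{\max}$. The deep floor matters: on
  the benchmark designs the last true pairs enter the lasso path around
  $10^{-3}$–$10^{-4}\,\lambda_{\max}$, so the conventional
  $0.01\lambda_{\max}$ floor would cap skeleton recovery at roughly
  half the true edges. Grids are scanned from sparse to dense with early
  stopping after eight consecutive BIC increases, and the lasso paths are
  computed lazily in warm-started chunks so the (expensive) dense end of
  the path is only touched when the criterion is still improving.
* **Tuning criterion.** $(\lambda_1, \lambda_2)$ are selected
  sequentially, each by a BIC evaluated on the *penalized* estimates with
  degrees of freedom equal to the nonzero-coefficient count — the
  standard lasso-BIC, in its Gaussian profile form
  $n\log(\mathrm{RSS}/n) + \mathrm{df}\log n$ per node and stage. A
  joint two-dimensional refit-based search would cost
  $O(\text{grid}^2)$ rounds of full refits and, more importantly,
  refit-based scoring charges every candidate edge $d+1$ parameters and
  tunes the skeleton *conservative* — whereas the skeleton's only job is
  to **contain** the truth, because the subsequent search deletes edges
  and never adds them. Tuning on the shrunken estimates lands the
  skeleton in the intended liberal regime (tens of false positives at
  $p = 20$, all 12 true pairs present), which the downstream search then
  cleans up.

## Steps 2 and 3 — orientation and hard-thresholded DAG search

The skeleton is direction-agnostic in spirit: both $(j,k)$ and $(k,j)$
frequently survive. Every edge carries the strength

$$ c_{jk} = \lVert \hat\beta_{jk}\rVert_2^2 / d + \hat\sigma^2_{jk}, $$

an average squared coefficient plus the latent-effect variance (the
divisor is the actual length of $\beta_{jk}$, so the term stays an
average when an intercept column is present). While bidirected pairs
remain, the direction with the smallest ratio $r_{jk} = c_{jk}/c_{kj}$
is removed (lexicographic tie-break) and the affected child refit — the
correct direction tends to carry the larger strength, which is the
finite-sample face of the identifiability result.

The oriented graph is then pruned greedily: at each step the weakest
edge (smallest $c_{jk}$) is deleted and only its child node refit
(separability makes this exact), the support is checked for acyclicity,
and BIC $= \ell_n + k\log n$ is recorded whenever the support is a DAG,
with $k$ = one coefficient vector and one variance per edge plus $p$
error variances. Acyclicity is decided by Kahn's algorithm (iterative
removal of parentless vertices, $O(p + |E|)$), which returns a
topological order or a witnessing cycle; the tests check it exhaustively
against a brute-force search over vertex orderings on graphs of up to
six nodes. Since the empty graph is a DAG, at least one candidate is
always recorded; the BIC-minimising candidate is returned. The whole
search is deletion-only, so the final support is nested in the oriented
support, which is nested in the skeleton — an invariant the tests assert
on every trace.

## The synthetic benchmark

`make_setting()` reproduces a five-design benchmark on a fixed 12-edge
DAG over nodes 1–15 (`truth_graph12()`); any further nodes are
independent noise. Error variances alternate $1.0$ (odd nodes) and
$0.5$ (even nodes). Designs 1–4 use three covariates — two standard
normal, one Bernoulli(0.5) — and no intercept column; on the true edges
they place, respectively: fixed effects $\beta = (-0.5, 1.0, -1.5)$
only; random effects $\sigma^2 = 0.5$ only; both; and a mixed design
with fixed effects on one 8-edge subset and random effects on another
(their union is the full graph). Design 5 prepends a constant column to
$X$ and puts all effect in it ($\beta_{jk,1} = \pm 1$ on two 6-edge
subsets, all covariate coefficients and variances zero) — the
homogeneous-SEM special case. The generator draws nodes in topological
order, can expose its latent draws (`return_latent = TRUE`) so tests can
reconstruct the structural errors exactly, and is bit-reproducible from
its seed; studies spawn per-replicate sub-seeds from one master seed.

What the generator does *not* emulate about real data: non-Gaussian
errors, measurement error in the covariates, unfaithful or near-canceling
pathways, and feedback loops. Passing the benchmark therefore
demonstrates correctness of the estimator and search under the model's
own assumptions, not robustness beyond them.

Scoring is directional: a reversed edge counts as one false positive
plus one false negative. Parameter accuracy is summarized by root
summed squared errors over all ordered pairs (zeros imputed off the
support), computed per replicate and then averaged.

## Study sizes and numerical choices

The shipped study runs (`scripts/acceptance.R`) use 100 replicates per
cell at $p = 20$, matching the benchmark's replication; the test suite
runs 25-replicate versions of the same cells with correspondingly wider
Monte-Carlo bands, plus two scaled-down replicates at $p = 100$ as a
regime check. On the $p = 20$ designs one full fit takes roughly one
second; $p = 100$ runs take ~15 s each.

Degenerate inputs are handled conservatively: all-zero feature columns
are dropped from the lasso with a warning; a singular weighted design is
ridge-stabilised; a candidate node model whose free-parameter count
approaches $n$ is never selectable during tuning; variances sit on a
$10^{-8}$ floor. Ties — in orientation ratios and pruning strengths —
break lexicographically by (child, parent), making every fit
deterministic given the data.

## Known limitations

* Estimation error of the freely-estimated coefficient vectors is at the
  information bound of this model; with $d = 4$ covariate columns of
  which three are null (design 5), the summed fixed-effect error is
  correspondingly larger than in designs whose null coefficients do not
  exist. No within-edge coefficient selection is attempted after the
  support is chosen.
* Random-effect-only edges into nodes that already have strong
  mixed-effect parents carry little marginal likelihood — their deviance
  gain can fall below any penalty that still removes selection-inflated
  false edges — and are the typical false negatives in the mixed
  benchmark design.
* The search is backward-only (deletion); it cannot recover an edge the
  skeleton missed. Multiple skeleton restarts, inference on edge
  strengths (bootstrap), and time-varying networks are out of scope.
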