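---
title: "Multi-objective effect trees: model, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective effect trees: model, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hettree)
```

## The estimation problem

Each sample in a two-arm study carries covariates $x \in \mathbb{R}^p$, a
binary treatment $W$ and an outcome $Y$. Under the potential-outcomes
model, $Y = W\,Y^{(1)} + (1-W)\,Y^{(0)}$ and only one potential outcome is
ever observed, so the conditional average treatment effect
$\tau(x) = E[Y^{(1)} - Y^{(0)} \mid x]$ is a counterfactual quantity. Two
assumptions make it estimable: *unconfoundedness*
($Y^{(0)}, Y^{(1)} \perp W \mid x$; automatic in randomized experiments)
and *overlap* (the propensity score $e(x) = \Pr(W = 1 \mid x)$ strictly
inside $(0,1)$ — the package rejects propensity values of exactly 0 or 1
at validation, since the inverse weights $1/e$ and $1/(1-e)$ would be
undefined).

`hettree` partitions the covariate space with a binary tree and estimates
$\tau$ within each node by the inverse-propensity-weighted (IPW)
ratio-of-sums contrast implemented in `node_cate()`. With a constant
propensity this reduces algebraically to the difference of treated and
control means, which the tests exploit as an exact identity. A node
containing a single treatment arm is *inestimable*; such nodes are never
created by splitting (candidates producing them are filtered out) and the
root must contain both arms.

## Split scoring and the multi-objective criterion

Every candidate split is scored on two axes at once:

* **fitness** $C^{fit} = n_L \hat\tau_L^2 + n_R \hat\tau_R^2$, the
  maximization surrogate for the (unobservable) mean squared error of the
  leaf estimates — larger is better because, at fixed total variance,
  pushing the child estimates away from zero is what a true effect
  difference does;
* **heterogeneity** $C^{hete} = (\hat\tau_L - \hat\tau_R)^2$, which
  directly rewards splits that separate subpopulations with different
  effects.

Maximizing either alone has a failure mode: pure fitness (`ct`) can
prefer splits into near-homogeneous children, spending samples without
revealing heterogeneity, while pure heterogeneity (`mh`) will happily
accept a split with enormous estimation error if its effect contrast is
large. The multi-objective criterion (`mo`) treats each candidate as the
score pair $s = (C^{fit}, C^{hete})$ and resolves the trade-off with
$\varepsilon$-dominance: $s_i \succ_\varepsilon s_j$ iff
$(1+\varepsilon_1) C^{fit}_i \ge C^{fit}_j$ and
$(1+\varepsilon_2) C^{hete}_i \ge C^{hete}_j$. The
$\varepsilon$-optimal set of candidates — every candidate
$\varepsilon$-dominated by some member, no member Pareto-dominated by any
candidate — is maintained online by a box archive: scores are binned at
indices $\lfloor \log C / \log(1+\varepsilon) \rfloor$, at most one
representative is kept per box, and only mutually non-dominated boxes
survive. Over a bounded score range the occupied boxes form an antichain
on a fixed grid, so the archive size is bounded by a constant,
$0.48 / (\log_{10}(1+\varepsilon_1)\log_{10}(1+\varepsilon_2))$,
independent of how many thousands of candidate thresholds a node has.
The final split is the archive entry with the largest $C^{hete}$
(`select_rule = "max_hete"`, the default) or largest $C^{fit}$.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `eps` | `c(0.1, 0.1)` | dominance slack per objective (dimensionless, useful range $(0, 1]$; 0.05–0.2 works well — smaller keeps more candidates) |
| `max_splits` | 10 | number of internal nodes; growth is best-first, so trees are comparable across criteria at equal split counts |
| `min_node` | 10 | minimum samples per child |
| `min_arm` | 2 | minimum treated and control samples per child |
| `honest` | `FALSE` | 50/50 sample split between split selection and leaf estimation |
| `clip` | 0.01 | propensity clamp $[\delta, 1-\delta]$, bounding IPW weights |

## Numerical and tie-breaking choices

* **Box indices.** Computed as
  $\lfloor \log C / \log(1+\varepsilon) + 10^{-9} \rfloor$; the tiny
  tolerance keeps exact powers $(1+\varepsilon)^k$ in box $k$ despite
  floating-point log round-off, and being monotone it cannot break any
  archive invariant. Scores at or below $10^{-12}$ have no logarithm;
  they map to a sentinel box ($-\infty$) lower than every real index, so
  a zero-score candidate can never displace a positive-score one.
* **Within-box replacement.** An incumbent representative is replaced
  only when the newcomer *Pareto*-dominates it. Any two points inside one
  box mutually $\varepsilon$-dominate by construction (their coordinates
  differ by less than a factor $1+\varepsilon$), so a replacement rule
  phrased in terms of $\varepsilon$-dominance alone cannot discriminate
  within a box; Pareto replacement is the rule that provably preserves
  both clauses of the $\varepsilon$-optimal-set definition, and it keeps
  exact duplicates first-wins, hence order-stable.
* **Box-level dominance** mirrors Pareto dominance on the index pair
  (both indices at least as large, one strictly).
* **Tie-breaks.** Among equal-score candidates: lower feature index, then
  lower threshold, then earlier insertion. Among frontier nodes with
  equal best scores: earlier node id. Trees are therefore byte-for-byte
  reproducible from data + configuration + seed, which the serialization
  tests assert literally.
* **Split direction.** "Value $\le$ threshold goes left", recorded in the
  serialized model document.
* **Squared t-statistic variance.** The within-child $\sigma^2$ is taken
  as $\mathrm{Var}(Y \mid W{=}1) + \mathrm{Var}(Y \mid W{=}0)$ (sample
  variances within the child); a floor of $10^{-12}$ guards the
  denominator when an arm's outcome is constant. Other poolings are
  defensible; this one is the simplest that keeps the statistic finite
  and scale-correct, and the variances are exposed to `ts_score()` so a
  user can supply an alternative.
* **Honest leaves.** When the estimation half of a leaf lacks one arm,
  the leaf inherits its parent's estimate rather than reporting NaN.

## The synthetic benchmark designs

`sim_design()` generates the four data-generating processes used
throughout the tests, all randomized at $P(W{=}1) = 0.5$ with i.i.d.
standard normal covariates (the conventional choice for this benchmark
family; configurable) and outcome

$$Y = m_k(x) + \alpha\,(2w-1)\,\tau_k(x) + \sigma,
\qquad \sigma \sim N(0, \texttt{noise\_sd}^2),$$

with `noise_sd = 1` by default. The designs differ in the effect surface
$\tau_k$, the nuisance surface $m_k$, the magnitude $\alpha$
(0.5, 1, 1, 1) and the number of pure-noise covariates (0, 12, 50, 12).
Note a structural point documented once here: writing the outcome with
the $(2w-1)$ contrast means the individual-level effect implied by the
generator is $Y^{(1)} - Y^{(0)} = 2\alpha\,\tau_k(x)$. The `true_tau`
element of a simulated dataset is therefore $2\alpha\,\tau_k(x)$ — the
actual CATE of the generated data and the only reference against which
RMSE of an estimator is meaningful. (Had we stored the unscaled surface
instead, the partition-dependent part of the error would cancel
algebraically — a fitted tree's leaf means converge to
$2\alpha E[\tau_k \mid \text{leaf}]$, and
$E[(2\alpha\mu_{leaf} - \tau_k)^2]$ decomposes into terms whose sum does
not depend on the partition when $2\alpha = 2$ — making every criterion
look identical.) The unscaled surface remains available as `tau_basis`,
and `true_tau(design, x)` evaluates the per-design formulas directly.

Two error measures are provided: `rmse()`, and `wrmse()` which weights a
squared error by 0.1 when estimate and truth share a sign and by 1 when
they disagree, so directional mistakes — the costly ones in clinical
use — dominate. A product of exactly zero shows no sign disagreement and
takes the 0.1 weight.

What the generator does *not* emulate: correlated or non-Gaussian
covariates, confounded treatment assignment (the propensity is constant,
so IPW weighting is exercised only lightly), heteroscedastic or
heavy-tailed noise, and censored outcomes. Tests passing on these designs
show the machinery is correct under clean randomized conditions, not that
the estimator is robust to observational pathologies.

## Scale of the shipped checks

The packaged test-and-acceptance runs use deliberately moderate problem
sizes chosen to exercise every property at full fidelity: archive-bound
streams of $200 \times 10{,}000$ pairs, oracle comparisons on up to 500
pairs per instance, estimator checks at $n = 10^4$, and criterion
benchmarks at $n = 1000$ with 20 replicates. The `run_benchmark()`
function scales to larger grids (more designs, sizes up to $5 \times
10^4$, split budgets to 15, 100 replicates) for users who want
full-resolution comparison curves.

## Design choices where the design was open

* **Best-first growth.** Nodes are expanded in order of their best
  candidate's criterion score. This makes "compare criteria at the same
  number of splits" well-defined; depth-first growth would conflate split
  count with tree shape.
* **Fixed split budget, no pruning or cross-validation.** Because the
  target $\tau$ is unobservable, standard CV on prediction error does not
  apply directly; the package follows the benchmark protocol of comparing
  at fixed split counts and leaves effect-aware CV out of scope.
* **Propensity default.** `known` when a propensity column exists, else
  the empirical treated fraction — all shipped benchmark designs are
  randomized; `logistic` is available for observational data.
* **Missing values** are rejected at validation rather than imputed.
* **Test-set size** in benchmarks defaults to the training size, drawn
  independently per replicate.

## Known limitations

* The archive provably never discards the globally most heterogeneous
  candidate (no box can dominate the maximal $C^{hete}$ index), so the
  `max_hete` selection rule coincides with pure heterogeneity
  maximization up to one $(1+\varepsilon_2)$ band. With exhaustive
  midpoint thresholds, unbounded-support covariates and a small
  `min_node`, the heterogeneity maximizer of a node is typically a
  boundary split (conditional means of a truncated normal diverge in the
  tail), so both `mh` and `mo` tend to shave small extreme leaves at
  shallow depths instead of structuring the bulk of the sample. Users
  who want the multi-objective machinery with a fitness-first temperament
  can set `select_rule = "max_fit"`, raise `min_node`, or restrict
  thresholds by preprocessing; the package deliberately does not change
  the published defaults.
* Only binary treatments, numeric covariates and uncensored numeric
  outcomes are supported; no ensembling, no confidence intervals for
  leaf effects.
* IPW estimates are clipped-weight estimates; with strongly informative
  propensities the usual caveats about weight variance apply.
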