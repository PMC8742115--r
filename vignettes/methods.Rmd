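---
title: "Methods: presence-only maximum entropy, variable selection, and threshold-free change accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only maximum entropy, variable selection, and threshold-free change accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxsuit)
```

## The estimation problem

Presence-only species distribution modelling asks: given cells where a
species was observed and a sample of what the landscape offers, which
distribution over cells is most consistent with the observations while
assuming as little as possible? The maximum-entropy answer constrains
the fitted distribution's feature expectations toward the presence
sample's feature means and otherwise keeps the distribution as uniform
as the constraints allow. With L1 regularization the constraints become
boxes rather than equalities, which both prevents overfitting and
performs feature selection.

`maxent()` maximizes the concave regularized gain

$$G(\lambda) = \frac{1}{m}\sum_{i \in \text{pres}} \lambda^\top f(x_i)
 \;-\; \log\!\Big(\tfrac{1}{N}\sum_{x \in \text{land}} e^{\lambda^\top f(x)}\Big)
 \;-\; \sum_j \beta_j |\lambda_j|,$$

where the landscape sample is the union of the presence and background
cells. The gain is zero for the null model and, at the optimum, equals
the average log ratio between the fitted probability of a presence
cell and the uniform probability $1/N$ — an interpretable measure of
how concentrated the species is relative to availability.

Assumptions worth keeping in mind:

* presences are an unbiased (or at least exchangeable) sample of where
  the species occurs within the study area;
* the background sample represents availability — we draw it uniformly
  over unmasked cells;
* one record per grid cell (`dedup_to_grid()`) is enough to blunt
  spatial pseudo-replication. This is thinning, not a spatial error
  model.

## Features and their regularization

Raw variables are min-max scaled to $[0,1]$ on the training data and
clamped to that range at projection time, so extrapolated cells can
never produce features outside what the optimizer saw. Feature classes:

| class | form | default |
|---|---|---|
| linear | $v'$ | on |
| quadratic | $v'^2$ | on |
| product | $v'_a v'_b$ | off |
| hinge | $\max(0, v'-k)/(1-k)$ and reversed | on (8 knots/orientation) |
| threshold | $\mathbf{1}(v' > k)$ | off |

Linear + quadratic + hinge is the default because it reproduces the
smooth-but-flexible response shapes the large-sample automatic setting
of the classic software produces, while keeping the feature count at
$2p + 16p$ — small enough that desk-scale fits converge in seconds.
Products and thresholds are switchable on.

Hinge knots sit at equal quantiles of the training values (8 per
orientation), so knot placement adapts to the variable's distribution
rather than its range. Zero-variance variables are skipped with a
warning.

Penalties follow $\beta_j = r \cdot c_{\text{class}} \cdot s_j/\sqrt{m}$:
features that vary more across presences are allowed more freedom, and
everything tightens as $1/\sqrt{m}$. The class constants default to 1
(0.5 for hinge, which comes in many correlated copies per variable).
The global multiplier $r$ defaults to 1, the conventional setting; set
`reg_multiplier = 0` to remove the penalty entirely (used by the
moment-matching tests).

## Optimization

The objective is concave and non-smooth only through the L1 term, so we
use cyclic coordinate-wise proximal Newton ascent: for feature $j$ with
fitted expectation $E_q[f_j]$ and variance $V_q[f_j]$, propose the
soft-thresholded Newton step and accept it after exact backtracking on
the true objective (halving toward the current value until the gain
does not decrease). Consequences:

* the gain path is monotone non-decreasing by construction — asserted
  in the tests;
* L1 shrinkage is handled exactly (weights hit zero, no subgradient
  heuristics);
* the algorithm is deterministic given the data: no stochastic steps.

Convergence is declared when the relative gain change over one full
cycle falls below `tol` ($10^{-5}$ by default) or after `max_iter`
cycles (2,500, the conventional cap). On the synthetic benchmark the
default fit converges in ~30 cycles. Degenerate situations are handled
explicitly: a feature whose fitted variance collapses uses a floored
curvature; a landscape that is all presences yields an `NA` training
AUC rather than an error; identical score sets give AUC 0.5 with a
warning.

The fitted distribution is normalized over the landscape sample
(`raw` scores sum to 1 within $10^{-9}$); `cloglog` suitability is
$1 - \exp(-e^H q(x))$, a monotone transform of `raw`, so any rank-based
quantity (AUC, orderings) is identical under either output.

## Two-stage variable selection

**Stage 1 (RM criterion).** From a background sample's correlation
matrix, `select_subset()` finds the $k$ variables whose span best
reproduces the full correlation structure. The RM coefficient of a
subset $K$ reduces to the root mean squared multiple correlation of
every variable on $K$, computed from the correlation matrix alone:
$\mathrm{RM}(K) = \sqrt{\operatorname{tr}(R_{\cdot K} R_{KK}^{-1} R_{K \cdot})/p}$.
It is 1 for the full set and monotone under subset growth. Search is
exhaustive up to $10^6$ enumerated subsets and greedy beyond that; the
tests verify greedy against exhaustive on small instances.
Near-singular $R_{KK}$ (collinear climate layers are the norm) is
ridge-regularized with $10^{-10}$ on the diagonal rather than rejected.

**Stage 2 (importance-driven elimination).** Four per-variable metrics
are ranked: percent contribution (higher = better), permutation
importance (higher = better), jackknife gain *without* the variable
(lower = better: the model suffers more from losing it), jackknife gain
*with only* the variable (higher = better). The aggregate rank is their
unweighted mean — the published two-step procedure states the metrics
but not the combination rule, so the equal-weight mean is this
package's choice, made once and documented here; ties break by
permutation importance then name. Elimination then drops the
worst-ranked variable, refits, and continues while the refit training
AUC stays at or above `auc_floor` (default 0.995) times the full
model's AUC. The ranking is frozen from the full model — metrics are
not recomputed between drops — mirroring a two-step "rank, then
reduce" design and keeping the audit trail interpretable.

Permutation importance is measured as the drop in training AUC after
jointly permuting a variable's column across presence and background
rows (one shared permutation, seeded). The gain drop is an equally
defensible statistic; the AUC drop is used because it is the quantity
the elimination's stopping rule is phrased in.

## Scenario change analysis

Projection onto a scenario stack uses the frozen feature
specification — training normalization, clamping — so only the raster
values change. The change analysis is deliberately threshold-free:
rather than binarizing suitability at an arbitrary cutoff, every cell
with current suitability ≥ 0.03 is binned by its current class
(breaks 0.03, 0.1, 0.2, 0.4, 0.6, 1; left-closed right-open, last
closed) and its area counts as contraction if its signed delta is
negative, expansion if positive. The direction convention is
`current − past` for palaeo comparisons and `future − current` for
projections, so positive always means improving over time. Exact
conservation (C + E + unchanged = eligible area) and antisymmetry
(swapping the pair swaps C and E) are asserted on random pairs.

The packaged fixture `arbutus_change_areas.csv` stores a published
per-scenario accounting of this exact form for the strawberry tree,
including its stated totals. One row (LGM expansion) is internally
inconsistent in the source — the five class entries sum to 1,841
against a stated total of 2,441 · 10³ km²; the fixture stores both
values as printed, `check_change_consistency()` reports the gap, and
net changes always use the stated totals. We do not guess which entry
is the typo.

Cell areas come from `cell_areas()`: constant $\Delta x \Delta y$ for
equal-area/planar grids, the spherical approximation
$R^2 \Delta\lambda \Delta\varphi \cos\varphi$ (R = 6371 km) for
geographic grids — accurate to well under a percent at the 1-km scales
this analysis targets. Coarser palaeoclimate inputs are expected to be
resampled onto the analysis grid upstream; sea-level masking for past
scenarios is treated as an input mask, not derived.

## The synthetic generator, and what passing its tests means

`simulate_env()` builds each layer by smoothing white noise with a
Gaussian kernel (width in cells; edge-renormalized), standardizing, and
mixing layers through the Cholesky factor of a target correlation
matrix, then mapping affinely onto climate-like units. It emulates the
two properties that make real climate stacks hard: spatial smoothness
and strong cross-variable correlation. It does **not** emulate
coastlines, elevation-driven anisotropy, realistic marginal
distributions, or observation bias — so passing the recovery benchmark
shows the estimator works when its assumptions hold, not that any real
dataset satisfies them.

The standard benchmark (`synthetic_benchmark()`) fixes the study
conditions used throughout the tests: a 64 × 64 geographic grid of
0.01° cells, six variables — three informative (BIO1, BIO9, BIO16,
unimodal niche with optima 14 °C, 22 °C, 450 mm and tolerances 4, 5,
180), one decoy correlated 0.85 with BIO1 but absent from the niche
(BIO11), two pure-noise fields (BIO15, slope) — a niche intercept
calibrated so mean true suitability is 0.15, 500 presence cells drawn
without replacement proportional to true suitability, and a 2,000-cell
background sample. Presence sampling proportional to suitability is a
simple documented stand-in for real detection processes; there is no
detection/effort model. The default scenario shifts move temperatures
up and wet-season precipitation down for futures (reversed for pasts),
matching the direction of change such studies report.

These sizes (2,500-cell landscapes, ~100 features) were chosen so a
full fit takes under a second and the complete pipeline — including
2p jackknife refits and the backward elimination — runs in a few
seconds, which keeps the whole suite comfortably interactive while
leaving the estimator's behaviour qualitatively identical to
full-scale runs.

## Interfaces

This is an analysis package: the exported stage functions
(`dedup_to_grid()`, `select_subset()`, `maxent()`,
`variable_metrics()`, `rank_and_reduce()`, `predict()`,
`change_accounting()`, …) are the programmatic interface, and
`run_pipeline()` orchestrates them from a single config (R list, JSON
or YAML), writing CSV reports, ASCII rasters, JSON models and a
manifest sufficient to reproduce every number. Raster IO supports the
ESRI ASCII grid format; values are plain text, nodata honored, which
covers exchange with any GIS. Reruns of the same config are
byte-identical.

## Known limitations

* Training AUC only: no cross-validation, no spatially blocked
  evaluation (the motivating study reports training-data evaluation).
* Presence-only scores are relative: cloglog suitability is not a
  probability of presence, which is exactly why the change analysis
  avoids thresholds.
* Percent contribution is path-dependent by definition; use the
  permutation and jackknife metrics when a path-free statistic is
  needed.
* The greedy RM search is a heuristic above the enumeration guard; it
  is exact only when exhaustive search is feasible.
* Geographic cell areas use the spherical cosine approximation, not an
  ellipsoidal model.
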