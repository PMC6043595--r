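---
title: "Modelling tidal-marsh retreat probability from Holocene sea-level tendencies"
author: "marshretreat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tidal-marsh retreat probability from Holocene sea-level tendencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshretreat)
```

## The scientific problem

Tidal marshes survive rising sea levels only while they can accrete sediment
fast enough to keep pace. When the local rate of relative sea-level rise
(RSLR, mm/yr, including vertical land motion) exceeds that capacity, the
marsh surface is drowned and replaced by tidal flat — the marsh *retreats*.
Stratigraphic archives record exactly this process: a *transgressive*
contact, where tidal-flat deposits gradually overlie marsh deposits, marks a
retreat (a *positive* sea-level tendency, increasing marine influence); a
*regressive* contact, marsh over tidal flat, marks expansion (*negative*
tendency); marsh peat that simply continues marks a marsh keeping pace
(*no* tendency).

A dated contact of this kind is a *sea-level index point*. Databases of
Holocene index points span RSLR rates far outside the instrumental era —
from rapid glacio-isostatic uplift (falling RSL) to early-Holocene rises
above 10 mm/yr — so the relationship between the rate of RSLR and the
probability of retreat can be estimated empirically and then applied to
projected future rates.

This package implements that inference chain end to end:

1. **`database_io`** — ingest, validate and filter index-point tables;
   encode tendencies as a binary response; binned descriptive summaries.
2. **`gia_rates`** — assign each point an RSLR rate from a coarse
   glacial-isostatic-adjustment (GIA) RSL curve by centered differencing.
3. **`monotone_pspline`** — the core model: a Bayesian monotone cubic
   penalized B-spline Bernoulli regression of tendency on rate.
4. **`projection_coupling`** — convert Monte Carlo sea-level projection
   ensembles into retreat-probability timelines and threshold-crossing
   years.
5. **`synthetic_data`** — seed-deterministic generators for every input, so
   the full chain is testable without access to the compiled (request-only)
   Great British database or an external projection framework.

## Rate assignment

GIA model output has 1000-yr temporal resolution, so RSL at an index
point's median calibrated age is obtained by linear interpolation between
nodes, and the rate is a centered finite difference over a 200-yr
(±100-yr) window:

$$\dot{z}(a) = \frac{z(a - 100) - z(a + 100)}{200}\ \textrm{(m/yr)},$$

converted to mm/yr, with positive values meaning RSL rising toward the
present. Two consequences of this definition are tested exactly: on a
window inside a single linear segment the rate equals the segment slope to
machine precision, and a window straddling a node averages the two segment
slopes in proportion to overlap. Points whose window extends beyond the
curve support (ages within 100 yr of either end) are flagged and excluded
rather than one-sided differenced; one-sided rates would have different
variance and a different meaning at the support edge. No smoothing is
applied beyond the native piecewise-linear curve.

## The monotone penalized B-spline Bernoulli model

Tendencies are coded $y_i = 1$ for positive (retreat) and $y_i = 0$ for
negative *and* no tendency — a marsh keeping pace is, like an expanding
marsh, evidence against retreat at that rate. (A switch drops the
no-tendency class instead, for sensitivity analysis.) The model is

$$y_i \sim \mathrm{Bernoulli}(p_i), \qquad
\mathrm{logit}(p_i) = \sum_{k=1}^{K} b_k(x_i)\,\alpha_k,$$

where $b_k$ are cubic B-splines on equally spaced knots spanning the
observed rate range and $\alpha_k$ are spline coefficients. Smoothness
comes from a first-order difference penalty, expressed as a prior:

$$\alpha_k - \alpha_{k-1} \sim \mathrm{N}(0, \sigma^2), \qquad k = 2, \dots, K,$$

with the differences additionally constrained non-negative, so every
posterior draw of the probability curve is monotone non-decreasing in the
rate — the substantive assumption that faster sea-level rise can never make
retreat *less* likely. Internally the model is reparameterized as
$(\alpha_1, \delta_2, \dots, \delta_K)$ with $\delta_k = \alpha_k -
\alpha_{k-1} \ge 0$, giving the increments half-normal priors with common
scale $\sigma$.

Priors where a choice had to be made (none of these is dictated by the
underlying method, and all are configurable through `model_config()`):

* $\alpha_1 \sim \mathrm{N}(0, 10^2)$ — weakly informative on the logit
  scale; the implied prior probability at the left boundary covers (0, 1)
  essentially uniformly in its tails, which a prior-predictive test checks.
* $\sigma \sim \textrm{half-Cauchy}(1)$ — the usual weakly informative
  choice for a hierarchical scale; small $\sigma$ means a smoother (flatter
  increment) curve.
* $K = 12$ cubic basis functions. Penalized splines are insensitive to $K$
  once it is generous relative to the curvature the data can support; the
  penalty, not the basis dimension, controls the effective degrees of
  freedom.

### Sampling

The posterior is explored with an adaptive random-walk
Metropolis-within-Gibbs sampler written in C++ (via Rcpp):

* componentwise random-walk updates of $\alpha_1$ and each increment
  $\delta_k$ (proposals below zero are rejected under monotonicity, which
  is exact Metropolis because the prior density there is zero);
* a *seesaw* joint move proposing $\alpha_1 \mathrel{+}= e$, $\delta_j
  \mathrel{-}= e$ for one random $j$, which follows the posterior ridge
  between the curve's left-boundary level and the increments (without it,
  left-tail coefficients — where index points are sparse — mix an order of
  magnitude more slowly);
* a conjugate Gibbs draw of $\sigma^2$, using the inverse-gamma
  scale-mixture representation of the half-Cauchy prior.

Because the basis is a partition of unity, the linear predictor is
$\eta = \alpha_1 + C\delta$ with $C_{ij} = \sum_{k \ge j} B_{ik}$, so every
componentwise update changes $\eta$ by a single scaled column — an $O(n)$
operation that keeps the default run (4 chains × 20,000 iterations, 10,000
burn-in, thinning 10) under ~15 s for $n \approx 800$ on one CPU. Step
sizes adapt toward 0.44 acceptance during burn-in only, so the post-burn-in
chain is a fixed Markov kernel. Convergence is summarized by split R-hat
and a Geyer initial-positive-sequence effective sample size per parameter;
R-hat above 1.05 triggers a warning, never silent acceptance.

With all-one-class data the fit proceeds but is flagged
boundary-degenerate: the likelihood pushes the whole curve toward 0 or 1
and only the priors keep it finite.

### Summaries and extrapolation

`probability_curve()` returns the pointwise posterior mean and equal-tailed
95% credible band of $p(x)$ on a grid. The posterior mean of $p$ (not $p$
at the posterior-mean coefficients) is used, and is also the curve used for
projection coupling; the full draw matrix is retained in the posterior
object for any other functional. Outside the fitted support the curve is
held flat at its boundary value: the data cannot inform shape beyond the
observed Holocene rate range, and a monotone curve admits no principled
extrapolation other than its boundary level. Projected future rates that
exceed the Holocene maximum therefore saturate at the highest estimated
retreat probability — a conservative choice in the sense that it never
extrapolates the curve upward.

`rate_at_probability()` inverts the mean curve (smallest rate reaching a
target probability, linearly interpolated between grid points); an
unattained target returns a sentinel with the direction of the miss rather
than an extrapolated number.

## Coupling with projection ensembles

Future marsh vulnerability is dated by composing the fitted curve with
Monte Carlo ensembles of local RSL projections (decadal grid, cm relative
to 2000). Per sample:

1. trailing 20-year average rates, $(z_t - z_{t-20})/20$ — trailing rather
   than centered so that the value at year $t$ uses no future information,
   matching how "rates between 2080 and 2100" are reported;
2. the running (cumulative) maximum of those rates — a marsh that has
   already been pushed past its threshold does not recover merely because
   the rate later slackens;
3. the posterior-mean retreat probability at that running maximum.

The timeline is the expectation of these probabilities across samples, and
the threshold year is the first decadal year whose probability *strictly*
exceeds the threshold (default 0.8), with no sub-decadal interpolation.
Because the curve is monotone and the running maximum non-decreasing, every
timeline is non-decreasing in time — tested for every generated ensemble. A
variance-propagating mode (pushing every posterior draw, not just the mean
curve, through the ensemble) is deliberately not the default: the package
mirrors the mean-curve composition, and the posterior object contains
everything needed to do otherwise.

## What the synthetic generators emulate

The generators reproduce the study conditions the pipeline is designed
for, so that every stage is exercised under realistic structure:

* **RSL curves** (`gen_rsl_curve()`): 1000-yr nodes over 0–12,000 cal yr
  BP in three glacio-isostatic regimes — near-field (early-Holocene
  deglacial RSL fall, mid-Holocene rise to a highstand above present, fall
  to present), margin (same pattern, small highstand), and far-field
  (decelerating monotone rise). Emitted segment rates are envelope-checked
  per regime (near-field within −7.7 to 6.0 mm/yr; far-field early
  Holocene within 3.1–15.2 mm/yr decelerating to ≤ 4.6 mm/yr), spanning
  overall the −7.7 to 15.2 mm/yr range that makes the Holocene record
  informative about rates beyond the instrumental era.
* **Index points** (`gen_index_points()`): ages concentrated at 3000–8000
  cal yr BP (70% of mass), which deliberately reproduces the age–rate
  confounding of real databases (moderate rates over-represented
  mid-Holocene); tendencies drawn Bernoulli from a known truth curve
  (default logistic with intercept −1.5, slope 0.5 per mm/yr, so p ≈ 0.9
  near 7 mm/yr and ≈ 0.1 near −2 mm/yr, echoing the shape reported for
  Great Britain without claiming its fitted values); a small no-tendency
  class (default 19/1097) and an erosional-contact contamination fraction
  (default 316/1097, leaving ~781 gradual points) matching the composition
  of the compiled Great British database.
* **Projection ensembles** (`gen_projection_ensemble()`): a stylized
  two-term model — deterministic background land motion plus a stochastic
  climate term with linear and quadratic components — calibrated so the
  5th–95th percentile of the 2100 rise hits a target range (default 23–123
  cm, the high-emission Thames-estuary benchmark). The realized range is
  verified within 10% of the target width, widened by the analytic Monte
  Carlo error of a sample quantile at the configured sample count.

What they do **not** emulate: spatial fingerprints and per-component
projection budgets, tidal-range change, sediment compaction, age
uncertainty in the index points, or the true joint spatial distribution of
the Great British regions. Passing tests therefore demonstrate that the
statistical machinery recovers known truth under realistic sampling
structure — not that the package reproduces the published fitted values,
which depend on a request-only database and an external projection
framework.

## Numerical choices and degenerate inputs

* Rate bins are half-open $[a, a + 0.5)$ mm/yr anchored at integer
  multiples of the width, so a point exactly on an edge belongs to the bin
  it opens.
* B-spline evaluation delegates to `splines::splineDesign`; the test suite
  checks it term by term against an independently coded Cox–de Boor
  recursion, and checks non-negativity and partition of unity on 10,000
  random points.
* Basis evaluation clamps inputs to the support, implementing the flat
  extrapolation rule everywhere consistently.
* `cumulative_max()` is base `cummax()` behind a validated interface,
  tested against a brute-force prefix maximum.
* Empty databases, single-class responses, zero-sample ensembles,
  non-decadal grids, out-of-support ages and mixed-threshold tables all
  fail loudly with specific errors; parse errors carry file line numbers
  and exclusions carry machine-readable reasons.
* All generators and the sampler are seed-deterministic: the same seed and
  configuration reproduce byte-identical files and draw sequences.

## Problem sizes used in the checks

The shipped checks run the chain at sizes chosen to make the statistical
assertions sharp while staying comfortably interactive: parameter recovery
at $n = 800$ with the default MCMC settings; the linear-limit comparison
against a maximum-likelihood logistic fit at $n = 5000$ (where the
asymptotic agreement the check relies on holds well); interval calibration
over 50 replicates of $n = 400$ at reduced iteration counts (2 chains ×
2,000); ensembles of 1,000 samples. Covariate (rate) uncertainty is not
propagated into the model — a known limitation shared with the approach
the package implements.
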