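---
title: "Fast EVPPI estimation: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast EVPPI estimation: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evppi)
```

This vignette explains what the package computes, the statistical models
behind its two regression engines, the numerical choices that make them
reliable, and the limits of what the synthetic test models can show.

## The estimand and the combiner

The expected value of partial perfect information for a focal parameter
subset $\phi \subset \theta$ is

$$\mathrm{EVPPI}(\phi) \;=\; \mathbb{E}_\phi\!\Big[\max_t
\mathbb{E}_{\psi\mid\phi}\,\mathrm{NB}_t(\phi,\psi)\Big] \;-\; \max_t\,
\mathbb{E}_\theta\,\mathrm{NB}_t(\theta),$$

a non-negative quantity, non-decreasing in $\phi$, bounded above by the
EVPI. Every estimator in the package ends in the same plug-in combiner
(`evppi_from_fitted()`): mean of row maxima minus maximum of column means,
applied either to raw net benefits (EVPI), to analytic conditional
expectations (single-loop), to inner Monte Carlo means (nested MC), or to
regression fitted values. The baseline term is always recomputed on the
same values being maximized; mixing baselines across sources would break
the algebraic guarantees (e.g. invariance to subtracting a common function
of $\phi$ from all arms) that the tests rely on.

Estimates can come out marginally negative through estimation noise. They
are reported as computed with a diagnostics flag, never silently clipped:
a visibly negative estimate is evidence about the fit, and hiding it would
hide estimator failure.

## Dense GP regression

Writing $\mathrm{NB}_t(\theta_s) = g_t(\phi_s) + \varepsilon_s$, the
conditional-expectation surface $g_t$ gets a GP prior with linear mean
$H\beta$ ($H = [1, \phi]$) and squared-exponential covariance
$\sigma^2\exp\{-\sum_p((\phi_{rp}-\phi_{sp})/\delta_p)^2\}$, plus nugget
$\sigma_\varepsilon^2$. With a flat prior on $\beta$ and
$p(\sigma^2)\propto 1/\sigma^2$, both integrate out analytically, leaving a
marginal posterior in $(\log\delta, \log\eta)$,
$\eta = \sigma_\varepsilon^2/\sigma^2$, whose mode we locate by L-BFGS
with an analytic gradient in the REML projected-precision form
$\tfrac12\,\mathrm{tr}(P\,d\Sigma) - c\,(u^\top d\Sigma\,u)/S^2$. Numerical
gradients would need $2(P{+}1)$ objective evaluations per step — the
analytic form is what keeps 19-dimensional focal sets affordable.

Choices that matter:

* **Subsampling.** Hyperparameters are estimated on a seeded random
  subsample (default 500 draws), then the fitted values use every draw —
  the optimisation is the $O(n^3)$ bottleneck, prediction is a single
  solve. A full-sample option exists because subsampled hyperparameters
  can occasionally be distorted; if a monotonicity audit fails, refitting
  with `subsample_size = Inf` is the first remedy.
* **Incremental reparameterization.** Only the $T-1$ contrasts
  $\mathrm{NB}_t - \mathrm{NB}_0$ are fitted, with $\hat g_0 \equiv 0$; the
  combiner is invariant to subtracting any common function of $\phi$, so
  this halves the work for two-arm models at no cost in the estimate.
* **Starts and bounds.** Three seeded random starts plus one moment start
  ($\delta_p$ = column range, the flattest plausible kernel); box bounds
  $\delta \in [10^{-2}, 10^4]$, $\eta \in [10^{-9}, 10^3]$ on standardized
  inputs; ties broken by lowest objective.
* **Degenerate responses.** If the response is numerically in the span of
  the linear trend, the marginal posterior is flat in the kernel
  parameters; the fit short-circuits to least squares, which is the exact
  posterior mean in that limit. Constant focal columns standardize to zero
  and are dropped with a warning (they carry no information and would make
  $H^\top\Sigma^{-1}H$ singular).
* **Jitter.** Cholesky factorizations retry with diagonal jitter from
  $10^{-10}$ escalating tenfold to $10^{-6}$ (relative), then fail loudly.

## The 2-D route: PFC projection, then a Matérn field by SPDE

For large focal sets the dense GP is the bottleneck, so the second engine
re-expresses the regression as a spatial problem: find a two-dimensional
*sufficient reduction* $R(\phi)$ with
$\mathrm{NB} \perp\!\!\!\perp \phi \mid R(\phi)$, treat the net benefit as
observed at the projected points, and fit a Matérn Gaussian field there.

### Principal fitted components

PFC is inverse regression: model $\phi = \mu + \Upsilon f(y) + \varepsilon$
with a centred polynomial basis $f(y) = (y, y^2, \dots, y^h)$ and Gaussian
errors. The maximum-likelihood reduction is
$R(\phi) = \Upsilon^\top\Delta^{-1}\phi$. Three error structures are
offered, and the choice is consequential:

* *isotropic* ($\Delta = \sigma^2 I$) and *diagonal* are cheap, but their
  reductions ignore correlation among the parameters. On correlated PSA
  draws this is not a small loss: on the package's own AR(1)-correlated
  fixture with an exactly linear net benefit, the isotropic reduction
  captures only $R^2 \approx 0.71$ of the response — enough to bias the
  EVPPI down by over 20%.
* *unstructured* (the default) estimates the full $\Delta$ by the
  closed-form maximum-likelihood solution (eigendecomposition of the
  fitted covariance in the residual-covariance metric). It is exactly
  sufficient for linear signals under any parameter correlation, at the
  price of $P(P+1)/2$ covariance parameters — a price that is negligible
  while $P$ is small compared with $S$ (here $P \le$ a few dozen against
  $S$ in the thousands). This is why it is the default; the cheap
  structures remain available for the near-independent case. The direction
  estimate converges more slowly in $n$ than the structured variants, as
  the subspace-recovery tests reflect.

Dimension $d$ and degree $h$ are selected by AIC over a grid (default
$d, h \in 1..4$, all three structures), with the likelihood maximized in
closed form per candidate and parameters counted as $P$ for $\mu$,
$d(P-d)$ for the direction span (its Grassmann dimension — the count AIC
comparability across $d$ hinges on), $dh$ basis coefficients, and the
error-structure count. The projection always returns two coordinates: if
$d^\ast = 1$ the second eigenvector can only add information, while if the
AIC prefers $d^\ast > 2$ the two-dimensional projection may genuinely lose
information — the estimate is still produced (the AIC tends to
overestimate $d$, and the projection is often usable), but with a
prominent warning and `sufficiency_ok = FALSE`, at which point residual
checking and interaction terms (below) are the remedies. The basis
coefficients the inverse-regression literature sometimes writes inside
$f(\cdot)$ are absorbed into $\Upsilon$, the standard identification.

One projection is fitted per incremental contrast, consistent with the
per-contrast regressions: each contrast's sufficiency is then
self-contained. When the focal set already has $\le 2$ members the
identity projection is used directly — a fitted projection could only
discard information there.

### Mesh, finite elements, sparse precision

A Matérn field with smoothness $\nu = 1$ solves
$\tau(\kappa^2 - \Delta)\,g = W$; discretizing with piecewise-linear finite
elements on a triangulation makes the vertex weights a Gauss-Markov field
with sparse precision $Q = \tau^2(\kappa^4 C + 2\kappa^2 G + G C^{-1} G)$.
The lumped (diagonal) mass matrix is what keeps $GC^{-1}G$ sparse. The
assembly is validated against hand-computed single-triangle matrices and
against the closed-form Matérn covariance: on a fine unit-square mesh the
implied interior covariances match to within a few percent and the
marginal variance matches the identity
$\sigma^2 = \Gamma(\nu)/(\Gamma(\alpha)4\pi)\,\kappa^{-2\nu}\tau^{-2}$.

The mesh itself is a graded tensor-product triangulation built in-package:
a fine uniform grid over the data bounding box dilated by 10% of the data
range (the inner boundary), then geometrically coarsening rings (growth
1.5, capped at three times the inner spacing) out to a 35% dilation (the
outer boundary). Natural boundary conditions from the FEM assembly distort
the field near the triangulation edge; the coarse outer annulus exists to
push that distortion away from the data. The inner spacing defaults to
whatever makes the vertex count at least the data count. Points are
located exactly by grid-cell lookup, vertices are ordered
lexicographically, and the whole construction is deterministic, so runs
are bit-reproducible. Projected coordinates are standardized first — on a
common scale the fixed spacing spends vertices where the data are. A
rectangular inner boundary (rather than a hull that hugs the cloud) wastes
some vertices in empty corners but can never isolate an outlier outside
the boundary; points within one edge length of the inner boundary trigger
an outlier warning instead.

### Empirical-Bayes latent Gaussian fit

The observation model is $y \sim N(H\beta + A\omega, \sigma_\varepsilon^2 I)$
with $\omega \sim N(0, Q^{-1})$, $\beta$ given a zero-mean Gaussian prior
with precision $10^{-6}$ (effectively flat, keeps the joint precision
positive definite). With a Gaussian likelihood the latent posterior is
exactly Gaussian, so integrating $(\omega, \beta)$ is two sparse Cholesky
factorizations per hyperparameter evaluation, and the only approximation
relative to a full hyperparameter integration is plugging in the marginal
posterior mode of $(\kappa, \sigma, \sigma_\varepsilon^2)$ — the estimate
uses the posterior-mean surface at fixed hyperparameters, forgoing
hyperparameter-uncertainty propagation, which affects interval statements
(not produced here) far more than the point estimate. The marginal
likelihood is verified against a dense Gaussian evaluation on a tiny mesh.

Numerics: optimization is on $(\log\kappa, \log\sigma, \log\sigma_\varepsilon^2)$
with $\sigma$ mapped to $\tau$ through the variance identity, so bounds are
interpretable — the spatial range $\sqrt8/\kappa$ is confined between twice
the minimal edge (below which the mesh cannot resolve the field) and twice
the domain diameter (above which the field is confounded with the linear
trend), and the scale parameters between $10^{-3}$ and $10$ times the
response scale (the response is standardized per contrast before fitting).
Diagonal jitter is proportional ($10^{-12}$ per entry), preserving each
block's scale. $\alpha = 2$ ($\nu = 1$) is the default — the standard
choice in spatial practice, and the one with a closed-form sparse $Q$;
$\alpha = 1$ is available for sensitivity analysis.

The linear predictor is intercept plus the two coordinates by default
(`interaction_order = 1`); orders 2 and 3 add polynomial interaction terms
of the coordinates, which recover flexibility lost to projection when
residual checks indicate structure.

## Monte Carlo reference estimators

`evppi_nested_mc()` is the general fallback: outer draws of $\phi$, inner
conditional draws of $\psi$, inner means into the combiner. Inner streams
derive deterministically from the outer index
($(\text{seed}\cdot 1000003 + s) \bmod (2^{31}-1)$), so the outer loop
could be parallelized without changing results. `evppi_single_loop()` is
exact (no inner error) whenever the model supplies closed-form conditional
expectations; both synthetic models do — the influenza model through
independence and the multilinear ("sum-product") net benefit, where the
conditional expectation is the formula with nuisance parameters replaced
by prior means, and the Gaussian-linear model through Gaussian
conditioning (bilinear terms via conditional second moments). The
single-loop estimator at $10^7$ draws is the oracle the regression
estimates are judged against.

## Synthetic study conditions

The defaults of the generators are the package's study conditions and are
deliberately fixed:

* **Influenza model**: $\pi \sim \mathrm{Beta}(2,18)$,
  $\rho \sim \mathrm{Beta}(4,12)$, $\lambda \sim \Gamma(8,1)$ days,
  $\gamma \sim \Gamma(4,5)$, $\xi \sim \mathrm{LogNormal}(\log 12000, 0.3)$,
  $k = 20000$. The implementation-cost scale is the binding choice: it is
  set so the prior mean incremental net benefit ($\approx -500$) is small
  against its spread ($\approx 9{,}700$), i.e. the two arms are genuinely
  competitive at the default willingness-to-pay and the value of
  information is non-trivial. A much cheaper intervention would dominate
  in every draw and make every EVPPI trivially zero.
* **Frozen 19-parameter fixture** (`savi_like_spec()`): AR(1) correlation
  0.6, parameter scales spread over an order of magnitude, linear net
  benefits whose contrast has prior mean 250 and standard deviation 1000
  (closed-form two-arm EVPI $\approx 286$), with the first six parameters
  carrying about 85% of the contrast variance — emulating the shape of
  applied decision-tree models, where a handful of inputs drives the
  incremental value. All constants are frozen literals; nothing about the
  fixture is re-drawn at run time.
* **Problem sizes**: regression estimators are exercised at $S = 1000$
  PSA draws with 500-draw hyperparameter subsamples; oracles at $10^6$ to
  $10^7$ draws; subspace recovery at $n = 1000$; dimension selection over
  50 replicates. These sizes put Monte Carlo noise well below the
  tolerances being checked while keeping the full suite a few minutes on
  one CPU.

What the synthetic models do *not* emulate: posterior draws from real
evidence syntheses are neither Gaussian nor multilinear, can be skewed,
heavy-tailed and nonlinearly dependent, and real net benefits come from
simulation with their own noise. Passing tests show the estimators are
correct where truth is computable — linear-Gaussian and sum-product worlds
and smooth low-dimensional surfaces — not that the 2-D projection is
sufficient for every real model. The sufficiency flag, the residual
checks, and the monotonicity audit are the instruments carried to real
data, precisely because the guarantees do not carry.

## Known limitations

* EVPPI point estimates carry no standard errors; at $S = 1000$ the
  sampling noise of any regression-based estimate is a few percent and is
  the dominant error for well-fitting models.
* When the AIC-optimal structural dimension exceeds two, the SPDE estimate
  can be biased low; the package warns rather than refuses, and the dense
  GP is the fallback.
* The mesh is rectangular-domain; extremely anisotropic point clouds
  spend vertices on empty corners (standardization mitigates this).
* Hyperparameter-uncertainty propagation is deliberately out of scope for
  the latent model (posterior-mode plug-in).
* The unstructured PFC needs $P \ll S$; for $P$ approaching $S$ the
  diagonal structure is the sensible fallback.
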