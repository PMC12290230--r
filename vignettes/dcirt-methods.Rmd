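---
title: "Davidian-curve IRT: model, estimation and study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Davidian-curve IRT: model, estimation and study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dcirt)
```

This vignette is the package's own account of its methods: the latent
density family and item model, the EM estimator and its numerical choices,
what the synthetic-data generator emulates (and what it does not), and the
design decisions that were genuinely open.

## The model

A person's ordinal responses $X_{ij} \in \{0,1,2,3\}$ to $J$ items are
driven by one continuous latent trait $\theta$.  Items follow the graded
response model with cumulative logistic boundaries

$$P(X_j \ge c \mid \theta) = \operatorname{logistic}(a_j\,\theta + d_{jc}),
\qquad d_{j1} > d_{j2} > d_{j3},$$

and category probabilities by adjacent differences.  No scaling constant is
used inside the logistic; the constant $D = 1.702$ appears only in the
reporting transform $a/\sqrt{D^2 + a^2}$ that maps a logistic slope onto the
normal-ogive/common-factor loading metric.  This convention is pinned by the
published PHQ-9 severity indices: with item parameters on the
slope/intercept logistic metric, the latent value where the expected score
of the anhedonia item reaches $m/2 = 1.5$ reproduces the published 1.34 at
two decimals (`generalized_severity(3.13, c(-2.43, -4.41, -5.59))`), and the
suicidality item gives 2.17; a $D$ inside the logistic would not.

Instead of fixing the latent density at $\varphi$, DC-IRT estimates it as a
Davidian curve of order $k$:

$$h(\theta) = P_k(\theta)^2\,\varphi(\theta), \qquad
P_k(\theta) = \sum_{\lambda=0}^{k} m_\lambda \theta^\lambda, \qquad
E[P_k(Z)^2] = 1 .$$

Nonnegativity is automatic (a square times a density) and the constraint
makes $h$ integrate to one exactly.  Orders $k \le 1$ reduce to the
traditional normal-latent model once location and scale are absorbed by the
items, so the contesting family is $k \in \{0, 2, \dots, 10\}$; orders above
10 invite overfitting.

**Constraint enforcement.**  With $A_{ij} = E[Z^{i+j}]$ the standard-normal
moment matrix (double factorials, computed exactly in integer arithmetic up
to degree 24) and $A = R^\top R$ its Cholesky factorization, any unit vector
$u$ gives a valid coefficient vector $m = R^{-1}u$ with $m^\top A m = 1$
exactly.  The unit vector is parameterized by $k$ spherical angles, so the
curve contributes exactly $k$ free parameters and the M step is
unconstrained.  The sign twin ($\pm m$ give the same density) is removed by
forcing the last spherical coordinate nonnegative.  The all-$\pi/2$ angle
configuration is exactly the standard normal curve and is the starting point
of every curve update.

## Estimation

Marginal maximum likelihood by the usual fixed-quadrature EM:

* **Quadrature:** 101 equally spaced nodes on $[-6, 6]$ with rectangular
  weights, normalized to a discrete prior.  Both counts and bounds are
  configurable (`make_quadrature()`); the defaults cover more than six
  standard deviations of every latent shape used here.
* **E step** (compiled): posterior node weights per response pattern
  $\propto$ prior mass $\times$ product of category probabilities, with a
  log-sum-exp underflow guard; persons are collapsed to unique response
  patterns first, so the cost scales with distinct patterns, not persons.
  Missing responses drop out of the product (listwise deletion is the
  default at fit level; `include_incomplete = TRUE` keeps partial rows).
* **M step:** per-item weighted logistic-ordinal likelihoods maximized by
  BFGS with analytic gradients; intercept monotonicity is enforced by
  parameterizing the gaps on the log scale.  The curve angles are updated by
  BFGS (analytic gradient through the spherical map and the Cholesky
  back-substitution) on the multinomial node-count likelihood
  $\sum_q n_q \log h(\theta_q)$.  Both updates start from the current
  parameters, so every cycle is an ascent step up to optimizer tolerance;
  the observed-data log-likelihood trace is stored and asserted
  nondecreasing (tolerance $10^{-8}$) in the tests.
* **Convergence:** largest absolute change across all item parameters and
  angles below `tol` ($10^{-3}$ by default).  A fit that has not converged
  after `max_iter` cycles is continued once at $10\times$ the tolerance and
  flagged (`retried`), mirroring how occasional stubborn high-order fits are
  handled in practice.
* **Identification:** no location/scale constraint during estimation — the
  family is anchored by its Gaussian base and is not closed under affine
  maps, so the metric is identified.  Reporting happens after the change of
  variables to mean 0, variance 1 (`standardized_density()`, closed-form
  curve moments) with items rescaled compatibly (`rescale_items()`:
  $a^* = a\,s$, $d^* = d + a\,\mu$).
* **Degenerate inputs:** empty item categories are collapsed with a warning
  and the parameter count adjusted; constant items are an error; zero
  likelihood at all nodes cannot occur because of the log-sum-exp guard.

**Model selection.** Each order in $\{0, 2..10\}$ is fitted (the normal fit
first; its item parameters seed every higher order — warm starts stabilize
high-$k$ fits), and the model minimizing the chosen criterion wins, ties
toward smaller $k$.  The Hannan–Quinn penalty is $2\,c\,p\log\log n$ with
$c = 1$ as commonly printed; $c$ is exposed (`hq_c`) because values above 1
are what the original consistency argument requires.  $p$ counts 4
parameters per (4-category) item plus $k$ curve angles; the normal model
counts no density parameters.

## The synthetic-data generator

The generator emulates a general-population depression screener:

* **Latent trait:** mean 0, variance $1/\sqrt2$, in three shapes — Gaussian;
  a skew-normal affinely standardized to skewness $+0.8$ (clearly
  right-skewed, configurable); and a two-component Gaussian mixture
  (weights 0.4/0.6, pre-standardization means $-1.2/0.8$, common SD 0.5)
  standardized to the same mean and variance, giving two well-separated
  modes with the minor mode on the left.  The skewed and bimodal shapes are
  only qualitatively constrained by prior work (they appear there as
  figures, not formulas); the defaults were chosen once to match those
  qualitative features and are exposed in `latent_spec()`.
* **Indicators:** nine continuous variables $\theta + e_j$,
  $e_j \sim N(0,\,1 - 1/\sqrt2)$, so each indicator has variance exactly 1
  and inter-item correlation $1/\sqrt2$.  (Stated latent and unique
  variances of $1/\sqrt2$ each would sum to $\sqrt2$, not 1; the package
  resolves the arithmetic by keeping the latent variance at $1/\sqrt2$ and
  choosing the unique variance as the complement to unit item variance.
  `unique_variance` is an argument, so the alternative both-are-SDs reading
  (variance $1/2$ each) is available for sensitivity analysis.)
* **Ordinalization:** per-item thresholds at the empirical quantiles of the
  continuous indicator at target cumulative category frequencies.  The
  default frequency table (`default_category_freqs()`) is zero-inflated —
  the lowest category holds 55–90% per item — which places every threshold
  on the right tail: all latent values below zero land in the lowest
  category, as in real PHQ-9 data.  These frequencies are package fixtures
  approximating general-population endorsement rates, not estimates;
  item-specific tables can be supplied.
* **Determinism:** one master seed; per-stage child seeds derived by a fixed
  splitting rule (`make_child_seeds()`), so every dataset is reproducible
  bit-for-bit.

What passing recovery tests on these data do **not** show: the generator
draws independent persons with complete responses from a stationary
population — no survey design, no cohort effects, no missingness mechanism,
no differential item functioning.  Real-data conclusions inherit those
caveats.

**Accuracy metric.**  Density estimates are compared by integrated squared
error $\int (\hat g - g)^2\,d\theta$ on a common grid, both densities on the
standardized metric.  The default export grid is 1,001 points on $[-6,6]$;
oracle computations in the tests use wider, denser grids so that the
quadrature error of the check is orders of magnitude below the tolerance
being asserted.  An optional multiplicative scaling hook on reported ISE
exists but is off by default (plots elsewhere sometimes scale the axis; raw
ISE is the defensible default).

## Study harnesses and problem sizes

`run_sim_study()` crosses latent shapes, sample sizes and selection
criteria; all orders are fitted once per replicate and shared across
criteria.  The package's own test battery runs, per shape, 10 replicates at
$n = 3000$ (recovery: Gaussian ISE $< 0.01$ and discriminations within
±15%; positive recovered skewness; two detected modes with the minor mode's
height underestimated), 6 replicates at $n = 1000$ (accuracy improves with
$n$ for the non-Gaussian shapes), and 6 replicates at $n = 10{,}000$
(BIC-selected mean ISE no worse than HQ-selected).  These sizes are the
package's choice of a desk-scale battery; the harness accepts the full
13-point sample-size grid and 50–200 replicates unchanged.

`subsample_density_analysis()` implements the pooled-data procedure: one
seeded permutation chunked into disjoint subsamples (12 × 3,000 by
default), a criterion-best fit per subsample, the pointwise mean density
with a 95% Wald band ($\pm 1.96\,\mathrm{SD}/\sqrt{B}$), and density
skewness/kurtosis by trapezoid integration with the same Wald summary.  The
chunked-permutation draw is one reasonable reading of "random subsamples
without replacement"; sequential draws would differ only in the seed
bookkeeping.  Grid-integrated moments are cross-checked against the
closed-form curve moments and a warning is raised if they disagree beyond
$10^{-3}$ (grid truncation).

**Mode counting** (`count_modes()`) declares a local maximum a mode when its
prominence — height above the higher flanking minimum — exceeds 5% of the
global maximum.  Eyeballing modality is the common practice; the threshold
makes it auditable and is exposed.

**Generating-truth definition.** The generator's items are probit by
construction (continuous indicator plus Gaussian noise, thresholded), while
the model fits logistic curves.  The logistic-metric "generating values"
reported in `true_items` are therefore the population-level projection of
the exact probit category curves onto the logistic graded-response family
(a weighted fit to the exact conditional probabilities under the latent
density) — the quantity a correctly specified logistic fit converges to.
The familiar $1.702$ rule understates that projection by several percent
for extreme zero-inflated thresholds and is used only as its starting
value.

## Known limitations

* The EM is first-order and deliberately unaccelerated (monotonicity is an
  asserted invariant); high orders on large samples can take a few hundred
  cycles at the default tolerance.
* Standard errors for item parameters are not computed (the reporting
  focuses on the density and derived indices).
* The bimodal recovery exhibits the known systematic underestimate of the
  minor mode's height; tests check the direction of that bias rather than
  pretending it is absent.
* Survey weights are not supported in the likelihood; pooled analyses treat
  cohorts as exchangeable samples.
* With the default generator shapes, the curve family approximates the
  bimodal mixture about as well as the near-maximal-skewness skew-normal
  (mean ISE ~0.004 vs ~0.006 at $n = 3000$), so the package's own battery
  reproduces the Gaussian ≪ non-Gaussian accuracy gap but not a strict
  skewed < bimodal ordering; a sharper or more separated mixture behaves
  differently, and both shapes are fully configurable.
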