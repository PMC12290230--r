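# dcirt

Semi-nonparametric latent density estimation for ordinal symptom
questionnaires: **Davidian-Curve Item Response Theory (DC-IRT)** in R.

## The problem

Symptom questionnaires such as the PHQ-9 measure a presumed continuous
liability (e.g., depression risk) with a handful of 4-category ordinal items
whose responses are heavily zero-inflated in the general population.
Standard item response theory assumes the latent trait is standard normal;
if the true population density is skewed or multimodal, that assumption
biases both the density and the item parameters. `dcirt` drops it: the
latent density is estimated *jointly* with the item parameters, as a
**Davidian curve** — a squared polynomial times a standard-normal base,

```
h(θ) = P_k(θ)² φ(θ),   P_k(θ) = Σ_{λ=0..k} m_λ θ^λ,   E[P_k(Z)²] = 1,
```

which is nonnegative by construction, integrates to one under the moment
constraint, and spans shapes from the exact Gaussian (k ≤ 1) to heavily
skewed and multimodal densities (k up to 10).  Items follow a graded
response model: cumulative category probabilities
`P(X ≥ c | θ) = logistic(a·θ + d_c)` with discrimination `a` and decreasing
intercepts `d₁ > d₂ > d₃`.

Estimation is marginal maximum likelihood via EM on a fixed quadrature grid
(E step: expected category-by-node counts; M step: per-item weighted
logistic-ordinal fits plus a multinomial update of the curve).  The
polynomial order `k` is chosen by information criteria

```
HQ  = −2 logL + 2 p log(log n)     AIC = −2 logL + 2p     BIC = −2 logL + p log n
```

and fitted densities are reported after a change of variables to the mean-0,
variance-1 metric, with item parameters rescaled compatibly
(`a* = a·sd`, `d* = d + a·mean`).

The package also ships the surrounding study machinery: a synthetic-data
generator for Gaussian / right-skewed / bimodal latent traits ordinalized to
PHQ-9-like zero-inflated category frequencies, integrated-squared-error
(ISE) accuracy studies across sample sizes and selection criteria, EAP
person scoring, and a subsample-averaging pipeline for pooled survey data
(disjoint subsamples → per-subsample fits → pointwise mean density with 95%
Wald bands and moment summaries).

## Worked example

Simulate a bimodal latent trait that is invisible in the sum scores, fit
DC-IRT across orders, and inspect the selected density:

```r
library(dcirt)

sim <- simulate_dataset(latent_spec("bimodal"), n = 3000, seed = 2)
sel <- select_model(sim$responses, criterion = "HQ")
sel
#> DC-IRT model selection by HQ: selected k = 3
#> # A tibble: 10 × 9   (order, loglik, n_params, HQ, AIC, BIC, converged, ...)

count_modes(standardized_density(sel$fit))
#> [1] 2
ise(standardized_density(sel$fit), sim$density_std)
#> [1] 0.0069
grid_moments(standardized_density(sel$fit))$skewness
#> [1] -0.43

tidy(sel$fit)     # item table: a, d1..d3, severity, loading
glance(sel$fit)   # k, loglik, n_params, HQ/AIC/BIC, convergence
autoplot(sel$fit) # standardized latent density
```

The selected order-3 curve recovers both modes (the sum-score histogram of
these data is unimodal and right-skewed), its ISE against the generating
density is below 0.01, and the fitted density is left-skewed — the minor
mode sits on the low end of the trait.

Published PHQ-9 item parameters are bundled for convenience:

```r
item_summary(phq9_reference_items())
#> label  a  d1  d2  d3  severity  loading
#> Loss of pleasure 3.13 -2.43 -4.41 -5.59  1.34  0.88
#> ...
#> Self-harm/death thoughts 3.23 -5.69 -7.20 -8.08  2.17  0.88
```

`severity` is the latent value where an item's expected score reaches half
its maximum (`m/2 = 1.5`); `loading` is the implied factor loading
`a/√(1.702² + a²)`.

For pooled survey data, the empirical pipeline is:

```r
pooled <- pool_cohorts(c("DPQ_D.xpt", ..., "DPQ_J.xpt"))   # or CSV files
sum_score_descriptives(pooled[nhanes_items()])              # n, mean, SEM, skew, kurtosis
sub <- subsample_density_analysis(pooled[nhanes_items()],   # 12 x 3000 disjoint
                                  criterion = "HQ", seed = 1)
full <- full_data_fit(pooled[nhanes_items()], criterion = "BIC")
autoplot(sub)
```

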