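# Shared fixtures, built once per test run and cached across files.
fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# A small skewed-latent dataset and its normal / order-2 fits, reused by the
# EM, tidier and IO tests.
small_sim <- function() cached("small_sim", {
  simulate_dataset(latent_spec("skewed"), 600, seed = 7)
})

small_fit0 <- function() cached("small_fit0", {
  fit_dcirt(small_sim()$responses, k = 0)
})

small_fit2 <- function() cached("small_fit2", {
  fit_dcirt(small_sim()$responses, k = 2, start = small_fit0())
})

# Random valid Davidian curve of a given order.
random_curve <- function(k, seed) {
  angles <- with_seed(seed, runif(k, 0, pi))
  angles_to_coefficients(k, angles)
}

# Independent naive marginal log-likelihood evaluator (plain loops; no reuse
# of the package's E-step path).
naive_marginal_loglik <- function(resp, items, quad, curve = NULL) {
  h <- if (is.null(curve)) dnorm(quad$nodes) else dc_density(curve, quad$nodes)
  prior <- h * quad$weights
  prior <- prior / sum(prior)
  ll <- 0
  for (i in seq_len(nrow(resp))) {
    lik_q <- prior
    for (j in seq_len(ncol(resp))) {
      x <- resp[i, j]
      if (is.na(x)) next
      d <- as.numeric(items[j, grep("^d[0-9]+$", names(items))])
      d <- d[!is.na(d)]
      p <- grm_probs(items$a[j], d, quad$nodes)
      lik_q <- lik_q * p[, x + 1]
    }
    ll <- ll + log(sum(lik_q))
  }
  ll
}
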