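test_that("latent draws hit the target mean and variance", {
  spec <- latent_spec("gaussian")
  lat <- draw_latent(spec, 100000, seed = 2)
  v <- var(lat$theta)
  expect_gt(v, 0.69)
  expect_lt(v, 0.72)
  expect_lt(abs(mean(lat$theta)), 3 * sqrt(1 / sqrt(2) / 100000))
})

test_that("generating densities integrate to one and have the advertised shapes", {
  th <- seq(-8, 8, length.out = 4001)
  for (shape in c("gaussian", "skewed", "bimodal")) {
    spec <- latent_spec(shape)
    g <- density_grid(th, spec$pdf(th))
    mom <- grid_moments(g)
    expect_lt(abs(mom$mass - 1), 1e-6)
    expect_lt(abs(mom$mean), 1e-8)
    expect_lt(abs(mom$variance - 1 / sqrt(2)), 1e-6)
  }
  expect_identical(count_modes(draw_latent(latent_spec("bimodal"), 10)$density), 2L)
  expect_identical(count_modes(draw_latent(latent_spec("gaussian"), 10)$density), 1L)
  # standardized version has unit variance
  lat <- draw_latent(latent_spec("skewed"), 10)
  mom_std <- grid_moments(lat$density_std)
  expect_lt(abs(mom_std$variance - 1), 1e-3)
})

test_that("skewed draws match the analytic skew-normal skewness", {
  spec <- latent_spec("skewed", skewness = 0.8)
  lat <- draw_latent(spec, 200000, seed = 13)
  s <- lat$theta
  g1 <- mean((s - mean(s))^3) / var(s)^1.5
  expect_gt(g1, 0)
  expect_lt(abs(g1 - 0.8), 0.05)
  expect_lt(abs(grid_moments(lat$density_std)$skewness - 0.8), 1e-3)
})

test_that("indicators carry the latent signal with unit total variance", {
  lat <- draw_latent(latent_spec("gaussian"), 50000, seed = 4)
  it <- make_items(lat$theta, n_items = 3, seed = 5)
  v <- apply(it, 2, var)
  expect_true(all(abs(v - 1) < 3 * sqrt(2 / 50000)))
  cors <- cor(it)[upper.tri(diag(3))]
  expect_true(all(abs(cors - 1 / sqrt(2)) < 0.02))
  # zero noise reproduces the latent values exactly
  expect_equal(unname(make_items(lat$theta[1:10], 2, unique_variance = 0)[, 1]),
               lat$theta[1:10])
})

test_that("ordinalization matches target frequencies and preserves order", {
  x <- matrix(rnorm(4000), ncol = 1)
  q <- ordinalize(x, c(0.25, 0.25, 0.25, 0.25))
  thr <- attr(q, "thresholds")
  expect_equal(as.numeric(thr), quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
  # zero-inflated targets: realized counts within rounding of the targets
  freqs <- c(0.76, 0.14, 0.06, 0.04)
  qz <- ordinalize(x, freqs)
  counts <- tabulate(qz[[1]] + 1, 4)
  expect_true(all(abs(counts - freqs * 4000) <= 1))
  # monotone: a higher continuous value never gets a lower category
  ord <- order(x[, 1])
  expect_true(all(diff(qz[[1]][ord]) >= 0))
  # degenerate target puts everything in the lowest category, with a warning
  expect_warning(q1 <- ordinalize(x, c(1, 0, 0, 0)), "empty")
  expect_true(all(q1[[1]] == 0))
})

test_that("implied generating items reproduce the exact probit category curves", {
  sim <- simulate_dataset(latent_spec("gaussian"), 500, seed = 3)
  z <- seq(-3, 3, length.out = 61)
  s <- sqrt(sim$spec$variance)
  se <- sqrt(1 - 1 / sqrt(2))
  for (j in c(1, 9)) {
    d <- as.numeric(sim$true_items[j, c("d1", "d2", "d3")])
    logit_cum <- dcirt:::grm_cumulative(sim$true_items$a[j], d, z)
    probit_cum <- sapply(sim$thresholds[j, ], function(t) pnorm((s * z - t) / se))
    # agreement at the logistic/probit family-mismatch scale
    expect_lt(max(abs(logit_cum - probit_cum)), 0.05)
    # the projected slope sits above the 1.702 rule of thumb for these
    # right-tail thresholds
    expect_gt(sim$true_items$a[j], 1.702 * s / se)
  }
})

test_that("dataset simulation is deterministic in the master seed", {
  s1 <- simulate_dataset(latent_spec("skewed"), 200, seed = 31)
  s2 <- simulate_dataset(latent_spec("skewed"), 200, seed = 31)
  s3 <- simulate_dataset(latent_spec("skewed"), 200, seed = 32)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$theta, s2$theta)
  expect_false(identical(s1$responses, s3$responses))
})

test_that("bimodality is invisible in the sum scores", {
  sim <- simulate_dataset(latent_spec("bimodal"), 20000, seed = 8)
  s <- rowSums(as_response_matrix(sim$responses))
  m <- mean(s)
  expect_gt(mean((s - m)^3) / mean((s - m)^2)^1.5, 0)
  expect_identical(count_modes(sim$density_std), 2L)
})

test_that("generator guards reject invalid settings", {
  expect_error(latent_spec("bimodal", mixture_weights = c(1.2, -0.2)), "weights")
  expect_error(latent_spec("gaussian", variance = -1))
  expect_error(latent_spec("skewed", skewness = 1.2), "0.995")
  expect_error(ordinalize(matrix(rnorm(10)), c(0.5, 0.3, 0.3, -0.1)), "sum to 1")
})
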