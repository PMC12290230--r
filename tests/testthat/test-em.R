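toy_items <- function() {
  tibble::tibble(label = c("i1", "i2"), a = c(1.2, 0.8),
                 d1 = c(0.5, 1.0), d2 = c(-0.5, 0.0), d3 = c(-1.5, -1.0))
}

test_that("E step matches a hand-enumerated Bayes computation on a tiny toy", {
  items <- toy_items()
  resp <- rbind(c(0L, 3L), c(2L, NA))
  quad <- make_quadrature(5, c(-2, 2))
  es <- e_step(resp, items, curve = NULL, quad = quad)

  # brute force with explicit loops
  prior <- dnorm(quad$nodes) * quad$weights
  prior <- prior / sum(prior)
  pj <- lapply(1:2, function(j) {
    grm_probs(items$a[j], as.numeric(items[j, c("d1", "d2", "d3")]), quad$nodes)
  })
  nq <- numeric(5)
  r <- list(matrix(0, 5, 4), matrix(0, 5, 4))
  ll <- 0
  for (i in 1:2) {
    lik <- prior
    for (j in 1:2) if (!is.na(resp[i, j])) lik <- lik * pj[[j]][, resp[i, j] + 1]
    ll <- ll + log(sum(lik))
    post <- lik / sum(lik)
    nq <- nq + post
    for (j in 1:2) if (!is.na(resp[i, j])) {
      r[[j]][, resp[i, j] + 1] <- r[[j]][, resp[i, j] + 1] + post
    }
  }
  expect_equal(es$loglik, ll, tolerance = 1e-12)
  expect_equal(es$nq, nq, tolerance = 1e-12)
  expect_equal(es$r[[1]], r[[1]], tolerance = 1e-12)
  expect_equal(es$r[[2]], r[[2]], tolerance = 1e-12)
})

test_that("with zero discrimination the posterior equals the prior", {
  items <- tibble::tibble(a = 1e-12, d1 = 0.5, d2 = -0.5, d3 = -1.5)
  quad <- make_quadrature(31, c(-4, 4))
  prior <- dnorm(quad$nodes) * quad$weights
  prior <- prior / sum(prior)
  es <- e_step(matrix(2L, nrow = 1), items, quad = quad)
  expect_equal(es$nq, prior, tolerance = 1e-8)
})

test_that("E-step log-likelihood equals an independent quadrature evaluation", {
  sim <- small_sim()
  resp <- as_response_matrix(sim$responses)[1:50, ]
  items <- small_fit0()$items
  quad <- make_quadrature(41, c(-5, 5))
  es <- e_step(resp, items, quad = quad)
  expect_equal(es$loglik, naive_marginal_loglik(resp, items, quad),
               tolerance = 1e-10)
  cv <- random_curve(3, seed = 2)
  es2 <- e_step(resp, items, curve = cv, quad = quad)
  expect_equal(es2$loglik, naive_marginal_loglik(resp, items, quad, curve = cv),
               tolerance = 1e-10)
})

test_that("M step recovers generating parameters from exact expected counts", {
  quad <- make_quadrature(101, c(-6, 6))
  nq <- dnorm(quad$nodes)
  nq <- 5000 * nq / sum(nq)
  a_true <- 2.2
  d_true <- c(-1, -2.5, -3.4)
  r_exact <- grm_probs(a_true, d_true, quad$nodes) * nq
  counts <- list(nq = nq, r = list(r_exact))
  start <- tibble::tibble(a = 1.4, d1 = -0.5, d2 = -1.8, d3 = -2.8)
  upd <- m_step(counts, start, k = 0, quad = quad)
  expect_equal(upd$items$a, a_true, tolerance = 1e-4)
  expect_equal(as.numeric(upd$items[1, c("d1", "d2", "d3")]), d_true,
               tolerance = 1e-4)
})

test_that("curve update keeps the normal model when node counts are exactly normal", {
  quad <- make_quadrature(101, c(-6, 6))
  nq <- dnorm(quad$nodes)
  nq <- 3000 * nq / sum(nq)
  counts <- list(nq = nq, r = list(grm_probs(2, c(-1, -2, -3), quad$nodes) * nq))
  upd <- m_step(counts, tibble::tibble(a = 2, d1 = -1, d2 = -2, d3 = -3),
                k = 4, angles = rep(pi / 2, 4), quad = quad)
  h <- dc_density(upd$curve, quad$nodes)
  expect_lt(max(abs(h / sum(h) - dnorm(quad$nodes) / sum(dnorm(quad$nodes)))),
            1e-8)
})

test_that("EM log-likelihood is nondecreasing and nested orders do not lose likelihood", {
  sim <- cached("em_ascent_sim", simulate_dataset(latent_spec("bimodal"), 500, seed = 11))
  f0 <- cached("em_ascent_f0", fit_dcirt(sim$responses, k = 0))
  f3 <- cached("em_ascent_f3", fit_dcirt(sim$responses, k = 3, start = f0))
  expect_true(all(diff(f0$loglik_trace) >= -1e-8))
  expect_true(all(diff(f3$loglik_trace) >= -1e-8))
  expect_gte(f3$loglik, f0$loglik - 1e-6)
  expect_true(all(diff(small_fit0()$loglik_trace) >= -1e-8))
  expect_true(all(diff(small_fit2()$loglik_trace) >= -1e-8))
  expect_gte(small_fit2()$loglik, small_fit0()$loglik - 1e-6)
})

test_that("information criteria follow their closed forms", {
  ic <- information_criteria(0, 1, exp(exp(1)))
  expect_equal(ic$HQ, 2, tolerance = 1e-12)
  ic0 <- information_criteria(-123.4, 0, 50)
  expect_equal(as.numeric(ic0), rep(246.8, 3))
  ic2 <- information_criteria(-1000, 40, 3000)
  expect_equal(ic2$AIC, 2080)
  expect_equal(ic2$BIC, 2000 + 40 * log(3000))
  expect_equal(ic2$HQ, 2000 + 80 * log(log(3000)))
  # AIC penalty < HQ penalty < BIC penalty for realistic n
  expect_lt(ic2$AIC, ic2$HQ)
  expect_lt(ic2$HQ, ic2$BIC)
  expect_error(information_criteria(0, 1, 2), "at least 3")
})

test_that("parameter counting includes curve angles only for k >= 2", {
  expect_identical(small_fit0()$n_params, 36L)
  expect_identical(small_fit2()$n_params, 38L)
})

test_that("model selection honors the order set and breaks ties toward smaller k", {
  sel0 <- select_model(small_sim()$responses, criterion = "HQ", orders = 0)
  expect_identical(sel0$fit$k, 0L)
  tab <- tibble::tibble(order = c(0L, 2L), HQ = c(5, 5))
  expect_identical(tab$order[which.min(tab$HQ)], 0L)
})

test_that("missing responses drop out item-wise when incomplete rows are kept", {
  resp <- as.data.frame(as_response_matrix(small_sim()$responses))
  resp[1:30, 2] <- NA
  f <- fit_dcirt(resp, k = 0, include_incomplete = TRUE, max_iter = 200)
  expect_identical(f$n_obs, nrow(resp))
  f_lw <- fit_dcirt(resp, k = 0)
  expect_identical(f_lw$n_obs, nrow(resp) - 30L)
  expect_identical(f_lw$n_dropped, 30L)
})

test_that("empty categories collapse with a warning and an adjusted parameter count", {
  resp <- as.data.frame(as_response_matrix(small_sim()$responses))
  resp[[1]][resp[[1]] == 3L] <- 2L # empty the top category of item 1
  expect_warning(f <- fit_dcirt(resp, k = 0, max_iter = 150), "collapsed")
  expect_identical(f$n_params, 35L)
  expect_true(is.na(f$items$d3[1]))
})

test_that("EAP scores match a hand-computed posterior mean on a one-item toy", {
  items <- tibble::tibble(a = 1.5, d1 = 0.8, d2 = -0.4, d3 = -1.6)
  quad5 <- make_quadrature(5, c(-2, 2))
  f <- list(items = items, curve = dc_curve(0, 1), k = 0L, quad = quad5)
  class(f) <- "dcirt_fit"
  resp <- matrix(c(1L, 3L), ncol = 1)
  sc <- eap_scores(resp, f)
  prior <- dnorm(quad5$nodes) * quad5$weights
  prior <- prior / sum(prior)
  p <- grm_probs(1.5, c(0.8, -0.4, -1.6), quad5$nodes)
  for (i in 1:2) {
    post <- prior * p[, resp[i, 1] + 1]
    post <- post / sum(post)
    expect_equal(sc$eap[i], sum(post * quad5$nodes), tolerance = 1e-12)
    expect_equal(sc$eap_sd[i],
                 sqrt(sum(post * quad5$nodes^2) - sum(post * quad5$nodes)^2),
                 tolerance = 1e-10)
  }
  # a severe item bank puts an all-zero responder below the density mean
  sc0 <- eap_scores(matrix(0L, 1, 9), structure(
    list(items = phq9_reference_items(), curve = dc_curve(0, 1), k = 0L,
         quad = make_quadrature()), class = "dcirt_fit"))
  expect_lt(sc0$eap, 0)
})

test_that("fitted models round-trip through the JSON model file", {
  f <- small_fit2()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(f, path)
  g <- read_model(path)
  expect_equal(g$items, f$items, tolerance = 1e-12)
  expect_equal(g$curve$m, f$curve$m, tolerance = 1e-12)
  expect_equal(g$loglik, f$loglik, tolerance = 1e-12)
  expect_equal(g$criteria, f$criteria, tolerance = 1e-12)
  expect_equal(standardized_density(g), standardized_density(f),
               tolerance = 1e-12)
})

test_that("standardized fits have unit-variance densities and compatible items", {
  f <- small_fit2()
  mom <- grid_moments(standardized_density(f))
  expect_lt(abs(mom$mean), 1e-3)
  expect_lt(abs(mom$variance - 1), 1e-3)
  # probability invariance between raw and standardized parameterizations
  cm <- dc_moments(f$curve, 2)
  raw <- f$items
  std <- standardized_items(f)
  z <- 0.7
  d0 <- as.numeric(raw[1, c("d1", "d2", "d3")])
  d1 <- as.numeric(std[1, c("d1", "d2", "d3")])
  expect_equal(grm_probs(std$a[1], d1, z),
               grm_probs(raw$a[1], d0, cm$sd * z + cm$mean), tolerance = 1e-12)
})
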