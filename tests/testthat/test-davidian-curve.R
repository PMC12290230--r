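test_that("orders 0 and the normal angle configuration reproduce the standard normal", {
  th <- default_theta_grid()
  expect_lt(max(abs(dc_density(dc_curve(0, 1), th) - dnorm(th))), 1e-12)
  c1 <- angles_to_coefficients(1, pi / 2)
  expect_lt(max(abs(dc_density(c1, th) - dnorm(th))), 1e-12)
  c3 <- angles_to_coefficients(3, rep(pi / 2, 3))
  expect_lt(max(abs(dc_density(c3, th) - dnorm(th))), 1e-12)
})

test_that("spherical construction satisfies the moment constraint and unit mass", {
  # oracle grid wide and dense enough that its own truncation error is far
  # below the 1e-6 agreement bound even for degree-20 polynomials
  th <- seq(-12, 12, length.out = 24001)
  for (k in 2:10) {
    A <- dcirt:::normal_moment_matrix(k)
    angles <- with_seed(100 + k, matrix(runif(20 * k, 0, pi), ncol = k))
    for (i in seq_len(nrow(angles))) {
      cv <- angles_to_coefficients(k, angles[i, ])
      expect_lt(abs(drop(crossprod(cv$m, A %*% cv$m)) - 1), 1e-10)
      expect_lt(abs(dcirt:::trapz(th, dc_density(cv, th)) - 1), 1e-6)
      expect_gte(min(dc_density(cv, th)), 0)
    }
  }
})

test_that("density evaluation matches a brute-force squared-polynomial oracle", {
  cv <- random_curve(2, seed = 1)
  th <- default_theta_grid()
  brute <- sapply(th, function(t) {
    sum(cv$m * t^(0:2))^2 * exp(-t^2 / 2) / sqrt(2 * pi)
  })
  expect_equal(dc_density(cv, th), brute, tolerance = 1e-12)
})

test_that("angle map agrees with numeric projection of the same ray onto the constraint set", {
  k <- 3
  angles <- with_seed(3, runif(k, 0, pi))
  cv <- angles_to_coefficients(k, angles)
  # oracle: scale an arbitrary vector along the same ray to satisfy m'Am = 1
  u <- dcirt:::spherical_unit(angles)
  ray <- backsolve(chol(dcirt:::normal_moment_matrix(k)), 2.37 * u)
  A <- dcirt:::normal_moment_matrix(k)
  proj <- ray / sqrt(drop(crossprod(ray, A %*% ray)))
  if (sign(proj[1]) != sign(cv$m[1])) proj <- -proj
  expect_equal(cv$m, proj, tolerance = 1e-12)
})

test_that("closed-form moments agree with quadrature on a wide grid", {
  th <- seq(-12, 12, length.out = 24001)
  for (k in c(2, 4, 7, 10)) {
    for (seed in 1:5) {
      cv <- random_curve(k, seed = 1000 * k + seed)
      mom <- dc_moments(cv)
      g <- density_grid(th, dc_density(cv, th))
      q <- grid_moments(g)
      expect_lt(abs(mom$mean - q$mean), 1e-6)
      expect_lt(abs(mom$variance - q$variance), 1e-6)
      expect_lt(abs(mom$skewness - q$skewness), 1e-6)
      expect_lt(abs(mom$ex_kurtosis - q$ex_kurtosis), 1e-6)
    }
  }
  norm_mom <- dc_moments(dc_curve(0, 1))
  expect_equal(norm_mom$mean, 0)
  expect_equal(norm_mom$variance, 1)
  expect_equal(norm_mom$skewness, 0)
  expect_equal(norm_mom$ex_kurtosis, 0)
})

test_that("standardization yields mean 0, variance 1 and is shift invariant", {
  # identity on the standard normal
  std <- standardize_density(dc_curve(0, 1))
  expect_lt(max(abs(std$density - dnorm(std$theta))), 1e-12)
  # arbitrary curves: unit mass and unit variance after the transform
  for (k in c(2, 5)) {
    cv <- random_curve(k, seed = 11 * k)
    g <- standardize_density(cv)
    mom <- grid_moments(g)
    expect_lt(abs(mom$mass - 1), 1e-3)
    expect_lt(abs(mom$mean), 1e-3)
    expect_lt(abs(mom$variance - 1), 1e-3)
  }
  # shifting the input density does not change the standardized shape
  cv <- random_curve(3, seed = 5)
  wide <- seq(-10, 10, length.out = 8001)
  g0 <- density_grid(wide, dc_density(cv, wide))
  g_shift <- density_grid(wide, dc_density(cv, wide - 0.7))
  s0 <- standardize_density(g0)
  s1 <- standardize_density(g_shift)
  expect_lt(max(abs(s0$density - s1$density)), 1e-3)
})

test_that("integrated squared error matches the two-Gaussian closed form and is a metric-like form", {
  th <- default_theta_grid()
  a <- density_grid(th, dnorm(th))
  expect_identical(ise(a, a), 0)
  delta <- 0.1
  b <- density_grid(th, dnorm(th - delta))
  expect_lt(abs(ise(a, b) - (1 - exp(-delta^2 / 4)) / sqrt(pi)), 1e-5)
  for (seed in 1:5) {
    g1 <- dc_density_grid(random_curve(2, seed))
    g2 <- dc_density_grid(random_curve(4, seed + 50))
    expect_gte(ise(g1, g2), 0)
    expect_equal(ise(g1, g2), ise(g2, g1))
  }
})

test_that("invalid inputs are rejected", {
  expect_error(dc_curve(2, c(1, 1, 1)), "invalid Davidian curve")
  expect_error(angles_to_coefficients(2, c(NaN, 1)), "finite")
  expect_error(standardize_density(dc_curve(0, 1), mean = 0, sd = -1), "positive")
  expect_error(standardize_density(dc_curve(0, 1), mean = 0), "both")
  th <- default_theta_grid()
  expect_error(ise(density_grid(th, dnorm(th)),
                   density_grid(th + 0.5, dnorm(th))), "same theta grid")
  expect_error(density_grid(c(1, 1, 2), c(1, 1, 1)), "strictly increasing")
})
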