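#' Tabulated density on a latent-trait grid
#'
#' A density grid is a tibble with a strictly increasing `theta` column and a
#' nonnegative `density` column; it is the common currency for integrated
#' squared error, pointwise averaging across fits, and moment integration.
#'
#' @param theta Strictly increasing numeric grid.
#' @param density Nonnegative density values at `theta`.
#' @return A tibble with columns `theta`, `density`.
#' @export
density_grid <- function(theta, density) {
  stopifnot(length(theta) == length(density), length(theta) >= 2)
  if (any(diff(theta) <= 0)) stop("theta grid must be strictly increasing")
  if (any(!is.finite(density)) || any(density < -1e-12)) {
    stop("density values must be finite and nonnegative")
  }
  tibble::tibble(theta = as.numeric(theta), density = pmax(as.numeric(density), 0))
}

#' Default latent-trait evaluation grid
#'
#' 1,001 equally spaced points on \[-6, 6\]; wide enough to cover more than
#' six standard deviations of every latent shape used here.
#'
#' @param n Number of grid points.
#' @param bounds Length-2 interval.
#' @return Numeric vector.
#' @export
default_theta_grid <- function(n = 1001, bounds = c(-6, 6)) {
  seq(bounds[1], bounds[2], length.out = n)
}

# Wide oracle grid used by quadrature cross-checks.
oracle_theta_grid <- function() seq(-8, 8, length.out = 4001)

#' Tabulate a Davidian curve on a grid
#'
#' @param curve A [dc_curve()] object.
#' @param theta Evaluation grid.
#' @return A [density_grid()] tibble.
#' @export
dc_density_grid <- function(curve, theta = default_theta_grid()) {
  density_grid(theta, dc_density(curve, theta))
}

#' Standardize a density to mean 0 and variance 1
#'
#' Change of variables: if `theta` has density `h` with mean `mu` and
#' standard deviation `s`, then `z = (theta - mu)/s` has density
#' `h*(z) = s * h(s z + mu)`.  For a Davidian curve, `mu` and `s` come from
#' its closed-form moments; for a tabulated grid they are computed by
#' trapezoid integration unless supplied.  Values requested outside a
#' tabulated grid's range are treated as zero density.
#'
#' @param x A [dc_curve()] object or a [density_grid()] tibble.
#' @param mean,sd Optional location/scale to standardize by (both or neither);
#'   `sd` must be positive.
#' @param theta Output grid for the standardized density.
#' @return A [density_grid()] tibble with mean 0 and variance 1 (up to
#'   integration tolerance).
#' @export
standardize_density <- function(x, mean = NULL, sd = NULL,
                                theta = default_theta_grid()) {
  if (is.null(mean) != is.null(sd)) {
    stop("supply both `mean` and `sd`, or neither")
  }
  if (inherits(x, "davidian_curve")) {
    if (is.null(mean)) {
      mom <- dc_moments(x, 2)
      mean <- mom$mean
      sd <- mom$sd
    }
    if (sd <= 0) stop("`sd` must be positive")
    return(density_grid(theta, sd * dc_density(x, sd * theta + mean)))
  }
  stopifnot(is.data.frame(x), all(c("theta", "density") %in% names(x)))
  if (is.null(mean)) {
    mom <- grid_moments(x)
    mean <- mom$mean
    sd <- mom$sd
  }
  if (sd <= 0) stop("`sd` must be positive")
  y <- approx(x$theta, x$density, xout = sd * theta + mean,
              yleft = 0, yright = 0)$y
  density_grid(theta, sd * y)
}

#' Moments of a tabulated density by trapezoid integration
#'
#' @param grid A [density_grid()] tibble.
#' @return One-row tibble with `mass` (the integral of the density itself),
#'   `mean`, `variance`, `sd`, `skewness`, `ex_kurtosis`.
#' @export
grid_moments <- function(grid) {
  stopifnot(is.data.frame(grid), all(c("theta", "density") %in% names(grid)))
  th <- grid$theta
  de <- grid$density
  mass <- trapz(th, de)
  mu <- trapz(th, th * de) / mass
  v <- trapz(th, (th - mu)^2 * de) / mass
  c3 <- trapz(th, (th - mu)^3 * de) / mass
  c4 <- trapz(th, (th - mu)^4 * de) / mass
  tibble::tibble(mass = mass, mean = mu, variance = v, sd = sqrt(v),
                 skewness = c3 / v^1.5, ex_kurtosis = c4 / v^2 - 3)
}

#' Integrated squared error between two densities
#'
#' Trapezoid approximation of `integral (ghat - g)^2 dtheta` over the shared
#' grid.  Symmetric in its arguments and zero exactly when the tabulated
#' values coincide.
#'
#' @param estimate,target [density_grid()] tibbles on the same `theta` axis.
#' @return Nonnegative scalar.
#' @export
ise <- function(estimate, target) {
  stopifnot(is.data.frame(estimate), is.data.frame(target))
  if (nrow(estimate) != nrow(target) ||
      max(abs(estimate$theta - target$theta)) > 1e-10) {
    stop("`estimate` and `target` must share the same theta grid")
  }
  trapz(estimate$theta, (estimate$density - target$density)^2)
}

#' Count modes of a tabulated density
#'
#' A mode is a local maximum whose prominence — its height above the higher
#' of the two flanking minima (the grid boundary counts as a minimum) —
#' exceeds `min_prominence` times the global maximum.  The threshold keeps
#' quadrature ripple and vanishing bumps from counting as modes.
#'
#' @param grid A [density_grid()] tibble.
#' @param min_prominence Fraction of the global maximum a peak must rise
#'   above its flanking minima to count.
#' @return Integer mode count.
#' @export
count_modes <- function(grid, min_prominence = 0.05) {
  d <- grid$density
  n <- length(d)
  s <- sign(diff(d))
  # carry signs through flat stretches so plateaus are single extrema
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  peaks <- which(diff(s) < 0) + 1L
  if (d[1] > d[2]) peaks <- c(1L, peaks)
  if (d[n] > d[n - 1]) peaks <- c(peaks, n)
  if (length(peaks) == 0) return(0L)
  cuts <- c(1L, vapply(seq_len(length(peaks) - 1), function(i) {
    lo <- peaks[i]
    hi <- peaks[i + 1]
    lo + which.min(d[lo:hi]) - 1L
  }, integer(1)), n)
  thr <- min_prominence * max(d)
  count <- 0L
  for (i in seq_along(peaks)) {
    left_min <- min(d[cuts[i]:peaks[i]])
    right_min <- min(d[peaks[i]:cuts[i + 1]])
    if (d[peaks[i]] - max(left_min, right_min) > thr) count <- count + 1L
  }
  count
}
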