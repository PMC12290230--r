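#' Standard-normal raw moments
#'
#' Exact raw moments `E[Z^d]` of a standard normal variate for degrees
#' `0..max_degree`: zero for odd degrees and the double factorial
#' `(d - 1)!!` for even degrees, accumulated in exact integer arithmetic
#' (all values needed here, up to degree 24, are exactly representable as
#' doubles).
#'
#' @param max_degree Highest degree required.
#' @return Numeric vector of length `max_degree + 1`; element `d + 1` is
#'   `E[Z^d]`.
#' @export
normal_moments <- function(max_degree) {
  stopifnot(max_degree >= 0)
  out <- numeric(max_degree + 1)
  out[1] <- 1
  for (d in seq_len(max_degree)) {
    out[d + 1] <- if (d %% 2 == 1) 0 else (d - 1) * out[d - 1]
  }
  out
}

# Moment matrix A with A[i+1, j+1] = E[Z^(i+j)], i, j = 0..k.
normal_moment_matrix <- function(k) {
  nm <- normal_moments(2 * k)
  outer(0:k, 0:k, function(i, j) nm[i + j + 1])
}

# Upper Cholesky factor R with A = R'R, cached per order.
chol_cache <- new.env(parent = emptyenv())
moment_chol <- function(k) {
  key <- as.character(k)
  if (is.null(chol_cache[[key]])) chol_cache[[key]] <- chol(normal_moment_matrix(k))
  chol_cache[[key]]
}

# Map k spherical angles to a unit vector of length k + 1:
#   u_j    = sin(phi_j) * prod_{i<j} cos(phi_i),  j = 1..k
#   u_{k+1} = prod_i cos(phi_i)
# With all angles at pi/2 this gives e_1, i.e. the standard normal curve.
spherical_unit <- function(angles) {
  k <- length(angles)
  u <- numeric(k + 1)
  cum <- 1
  for (j in seq_len(k)) {
    u[j] <- sin(angles[j]) * cum
    cum <- cum * cos(angles[j])
  }
  u[k + 1] <- cum
  u
}

#' Davidian curve from coefficients
#'
#' A Davidian curve of order `k` is the density
#' `h(theta) = P_k(theta)^2 * phi(theta)` with `P_k(theta) = sum m_l theta^l`
#' and `phi` the standard normal density, normalized by the constraint
#' `E[P_k(Z)^2] = 1` (equivalently `m' A m = 1` with `A` the standard-normal
#' moment matrix).  Orders 0 and 1 reduce to the standard normal density
#' itself once the latent location/scale is identified through the items.
#'
#' @param k Polynomial order, 0 to 10.
#' @param m Coefficient vector `m_0..m_k`.
#' @param angles Optional unconstrained spherical angles that generated `m`
#'   (kept for refitting; not validated against `m`).
#' @param tol Tolerance for the normalization constraint check.
#' @return An object of class `davidian_curve`.
#' @seealso [angles_to_coefficients()], [dc_density()], [dc_moments()]
#' @export
dc_curve <- function(k, m, angles = NULL, tol = 1e-6) {
  stopifnot(length(k) == 1, k >= 0, k <= 10, length(m) == k + 1)
  if (!all(is.finite(m))) stop("Davidian-curve coefficients must be finite.")
  A <- normal_moment_matrix(k)
  q <- drop(crossprod(m, A %*% m))
  if (abs(q - 1) > tol) {
    stop(sprintf(
      "invalid Davidian curve: E[P_k(Z)^2] = %.8f, not 1 (tolerance %g)", q, tol
    ))
  }
  structure(list(k = as.integer(k), m = as.numeric(m), angles = angles),
            class = "davidian_curve")
}

#' @export
print.davidian_curve <- function(x, ...) {
  cat("Davidian curve, order k =", x$k, "\n")
  cat("coefficients:", signif(x$m, 5), "\n")
  invisible(x)
}

#' Build a valid Davidian curve from unconstrained angles
#'
#' The normalization `m' A m = 1` is enforced by construction: with the
#' Cholesky factorization `A = R'R`, any unit vector `u` yields a valid
#' coefficient vector `m = R^{-1} u`.  The unit vector comes from spherical
#' coordinates of `k` free angles, so optimization over the curve is
#' unconstrained.  The sign ambiguity (`m` and `-m` give the same density) is
#' resolved by forcing the last spherical coordinate to be nonnegative.
#'
#' @param k Polynomial order (>= 1).
#' @param angles Numeric vector of `k` angles.
#' @return A [dc_curve()] object carrying the angles.
#' @examples
#' angles_to_coefficients(1, pi / 2) # the standard normal curve
#' @export
angles_to_coefficients <- function(k, angles) {
  stopifnot(k >= 1, length(angles) == k)
  if (!all(is.finite(angles))) stop("angles must be finite")
  u <- spherical_unit(angles)
  if (u[k + 1] < 0) u <- -u
  m <- backsolve(moment_chol(k), u)
  dc_curve(k, m, angles = angles)
}

# Unvalidated fast path used inside optimization loops.
dc_coef <- function(k, angles) {
  backsolve(moment_chol(k), spherical_unit(angles))
}

#' Evaluate a Davidian-curve density
#'
#' @param curve A [dc_curve()] object.
#' @param theta Numeric vector of latent values.
#' @return Density values `P_k(theta)^2 * dnorm(theta)`.
#' @export
dc_density <- function(curve, theta) {
  stopifnot(inherits(curve, "davidian_curve"))
  poly_eval(curve$m, theta)^2 * dnorm(theta)
}

#' Closed-form moments of a Davidian curve
#'
#' Raw moments `E[theta^r]` follow from expanding
#' `theta^r * P_k(theta)^2` and taking standard-normal moments of each
#' monomial; no numeric integration is involved.  Central moments, skewness
#' (third standardized moment) and excess kurtosis (fourth standardized
#' moment minus 3) are derived from the raw moments.
#'
#' @param curve A [dc_curve()] object.
#' @param max_order Highest raw moment required (the derived summaries need 4).
#' @return One-row tibble with columns `m1..m<max_order>`, `mean`, `variance`,
#'   `sd`, `skewness`, `ex_kurtosis`.
#' @export
dc_moments <- function(curve, max_order = 4) {
  stopifnot(inherits(curve, "davidian_curve"), max_order >= 1)
  m <- curve$m
  deg <- outer(seq_along(m), seq_along(m), `+`) - 2L
  cc <- as.numeric(tapply(outer(m, m), deg, sum)) # coefficients of P_k^2
  nm <- normal_moments(2 * curve$k + max_order)
  raw <- vapply(seq_len(max_order), function(r) {
    sum(cc * nm[seq_along(cc) + r])
  }, numeric(1))
  mu <- raw[1]
  out <- tibble::as_tibble(as.list(stats::setNames(raw, paste0("m", seq_len(max_order)))))
  out$mean <- mu
  if (max_order >= 2) {
    v <- raw[2] - mu^2
    out$variance <- v
    out$sd <- sqrt(v)
  }
  if (max_order >= 3) {
    c3 <- raw[3] - 3 * mu * raw[2] + 2 * mu^3
    out$skewness <- c3 / out$variance^1.5
  }
  if (max_order >= 4) {
    c4 <- raw[4] - 4 * mu * raw[3] + 6 * mu^2 * raw[2] - 3 * mu^4
    out$ex_kurtosis <- c4 / out$variance^2 - 3
  }
  out
}
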