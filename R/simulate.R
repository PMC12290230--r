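# Skew-normal helpers (location 0, scale 1, slant alpha):
#   density 2 phi(x) Phi(alpha x); draws via delta |Z0| + sqrt(1-delta^2) Z1.
sn_delta_for_skewness <- function(g1) {
  stopifnot(g1 >= 0)
  if (g1 >= 0.995) stop("skew-normal skewness must be below 0.995")
  if (g1 == 0) return(0)
  f <- function(delta) {
    b <- delta * sqrt(2 / pi)
    (4 - pi) / 2 * b^3 / (1 - b^2)^1.5 - g1
  }
  uniroot(f, c(1e-8, 1 - 1e-10), tol = 1e-12)$root
}

#' Latent-trait distribution specification
#'
#' The three latent shapes used in the simulation study, each affinely
#' standardized to a target mean and variance (defaults: mean 0, variance
#' `1/sqrt(2)`, the scale at which nine unit-variance indicators arise from
#' the trait plus independent Gaussian noise):
#'
#' * `"gaussian"`: a normal distribution.
#' * `"skewed"`: a skew-normal with slant set so the skewness equals
#'   `skewness` (default +0.8, a clearly right-skewed shape).
#' * `"bimodal"`: a two-component Gaussian mixture with the minor mode on
#'   the left (default weights 0.4/0.6, component means -1.2/0.8 and common
#'   SD 0.5 before standardization — two well separated modes).
#'
#' @param shape One of `"gaussian"`, `"skewed"`, `"bimodal"`.
#' @param mean,variance Target mean and variance of the trait.
#' @param skewness Target skewness for the skewed shape.
#' @param mixture_weights,mixture_means,mixture_sd Mixture settings (before
#'   standardization) for the bimodal shape.
#' @return Object of class `latent_spec` with a `pdf` and a `sampler` on the
#'   standardized-to-target scale.
#' @export
latent_spec <- function(shape = c("gaussian", "skewed", "bimodal"),
                        mean = 0, variance = 1 / sqrt(2), skewness = 0.8,
                        mixture_weights = c(0.4, 0.6),
                        mixture_means = c(-1.2, 0.8), mixture_sd = 0.5) {
  shape <- match.arg(shape)
  stopifnot(variance > 0)
  if (shape == "bimodal") {
    if (length(mixture_weights) != 2 || any(mixture_weights <= 0) ||
        any(mixture_weights >= 1) || abs(sum(mixture_weights) - 1) > 1e-8) {
      stop("mixture weights must be two values in (0, 1) summing to 1")
    }
    if (mixture_sd <= 0) stop("mixture component SD must be positive")
  }
  # raw-scale pdf/sampler plus raw mean/var for the affine map
  if (shape == "gaussian") {
    raw <- list(pdf = dnorm, rng = rnorm, mean = 0, var = 1)
  } else if (shape == "skewed") {
    delta <- sn_delta_for_skewness(skewness)
    alpha <- delta / sqrt(1 - delta^2)
    raw <- list(
      pdf = function(x) 2 * dnorm(x) * pnorm(alpha * x),
      rng = function(n) delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n),
      mean = delta * sqrt(2 / pi),
      var = 1 - 2 * delta^2 / pi
    )
  } else {
    w <- mixture_weights
    mu <- mixture_means
    s <- mixture_sd
    m0 <- sum(w * mu)
    raw <- list(
      pdf = function(x) w[1] * dnorm(x, mu[1], s) + w[2] * dnorm(x, mu[2], s),
      rng = function(n) {
        z <- stats::rbinom(n, 1, w[2])
        rnorm(n, mu[1] + z * (mu[2] - mu[1]), s)
      },
      mean = m0,
      var = sum(w * (s^2 + mu^2)) - m0^2
    )
  }
  scl <- sqrt(variance / raw$var)
  structure(list(
    shape = shape, mean = mean, variance = variance, skewness = skewness,
    mixture = if (shape == "bimodal") list(weights = mixture_weights,
                                           means = mixture_means,
                                           sd = mixture_sd),
    # density/sampler of the trait on its target (mean, variance) scale
    pdf = function(x) raw$pdf((x - mean) / scl + raw$mean) / scl,
    sampler = function(n) (raw$rng(n) - raw$mean) * scl + mean
  ), class = "latent_spec")
}

#' Draw a latent sample together with its exact generating density
#'
#' @param spec A [latent_spec()].
#' @param n Sample size.
#' @param seed RNG seed.
#' @param theta Grid on which to tabulate the generating density.
#' @return List with `theta` (the draws), `density` (generating density on
#'   the grid, at the spec's own mean/variance) and `density_std` (the same
#'   density standardized to mean 0, variance 1 — the target for integrated
#'   squared error against standardized fits).
#' @export
draw_latent <- function(spec, n, seed = 1, theta = default_theta_grid()) {
  stopifnot(inherits(spec, "latent_spec"), n >= 1)
  draws <- with_seed(seed, spec$sampler(n))
  s <- sqrt(spec$variance)
  list(
    theta = draws,
    density = density_grid(theta, spec$pdf(theta)),
    density_std = density_grid(theta, s * spec$pdf(s * theta + spec$mean))
  )
}

#' Continuous indicators from a latent sample
#'
#' Each indicator is the latent value plus independent Gaussian noise:
#' `item_j = theta + e_j`, `e_j ~ N(0, unique_variance)`.  With the default
#' latent variance `1/sqrt(2)` the default unique variance `1 - 1/sqrt(2)`
#' makes every indicator's total variance exactly 1.
#'
#' @param theta Latent sample.
#' @param n_items Number of indicators.
#' @param unique_variance Variance of the item-specific noise.
#' @param seed RNG seed.
#' @return Numeric matrix `length(theta) x n_items`.
#' @export
make_items <- function(theta, n_items = 9, unique_variance = 1 - 1 / sqrt(2),
                       seed = 1) {
  stopifnot(length(theta) >= 1, n_items >= 1, unique_variance >= 0)
  e <- with_seed(seed,
                 matrix(rnorm(length(theta) * n_items, 0, sqrt(unique_variance)),
                        ncol = n_items))
  out <- theta + e
  colnames(out) <- sprintf("item%02d", seq_len(n_items))
  out
}

#' Default zero-inflated category frequencies
#'
#' Per-item 4-category target endorsement frequencies emulating the
#' zero-inflated profile of PHQ-9 items in general-population samples (the
#' lowest category dominates; small variation across items).  These are
#' package fixtures, overridable per item.
#'
#' @param n_items Number of items.
#' @return `n_items x 4` matrix of frequencies, rows summing to 1.
#' @export
default_category_freqs <- function(n_items = 9) {
  base <- matrix(c(
    0.72, 0.17, 0.06, 0.05,
    0.78, 0.13, 0.05, 0.04,
    0.60, 0.24, 0.09, 0.07,
    0.55, 0.28, 0.10, 0.07,
    0.70, 0.18, 0.07, 0.05,
    0.80, 0.12, 0.05, 0.03,
    0.76, 0.14, 0.06, 0.04,
    0.86, 0.09, 0.03, 0.02,
    0.90, 0.06, 0.025, 0.015
  ), ncol = 4, byrow = TRUE)
  base[rep_len(seq_len(nrow(base)), n_items), , drop = FALSE]
}

#' Ordinalize continuous items by target category frequencies
#'
#' Thresholds per item are the empirical quantiles of that item's continuous
#' values at the cumulative target frequencies, so realized category counts
#' match the targets up to rounding.  With a dominant lowest category all
#' thresholds land on the right tail of the item distribution.
#'
#' @param items Continuous matrix from [make_items()].
#' @param freqs Target frequencies: a length-4 vector (recycled across items)
#'   or an `n_items x 4` matrix; rows must be nonnegative and sum to 1.
#' @return Tibble of integer codes `0..3` with attribute `thresholds`
#'   (`n_items x 3` matrix, on the continuous item scale).
#' @export
ordinalize <- function(items, freqs = default_category_freqs(ncol(items))) {
  items <- as.matrix(items)
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = ncol(items),
                                           ncol = length(freqs), byrow = TRUE)
  stopifnot(nrow(freqs) == ncol(items), ncol(freqs) >= 2)
  if (any(freqs < 0) || any(abs(rowSums(freqs) - 1) > 1e-8)) {
    stop("target frequencies must be nonnegative and sum to 1 per item")
  }
  if (any(freqs == 0)) {
    warning("zero target frequency: the affected categories will be empty and ",
            "collapse during fitting", call. = FALSE)
  }
  nb <- ncol(freqs) - 1L
  thr <- matrix(NA_real_, nrow = ncol(items), ncol = nb)
  codes <- matrix(0L, nrow = nrow(items), ncol = ncol(items))
  for (j in seq_len(ncol(items))) {
    cum <- cumsum(freqs[j, seq_len(nb)])
    thr[j, ] <- quantile(items[, j], probs = pmin(cum, 1), names = FALSE)
    codes[, j] <- rowSums(outer(items[, j], thr[j, ], `>`))
  }
  colnames(codes) <- if (is.null(colnames(items))) {
    sprintf("item%02d", seq_len(ncol(items)))
  } else {
    colnames(items)
  }
  out <- tibble::as_tibble(codes)
  attr(out, "thresholds") <- thr
  out
}

# Implied graded-response parameters of the generating process on the
# standardized latent metric.  Conditional on the trait the exceedance
# probability is probit: P(item_j >= c | theta) = pnorm((theta - tau_jc)/sd_e).
# The logistic-metric "truth" is the population-level projection of those
# probit curves onto the logistic graded-response family: the weighted
# logistic-ordinal fit to the exact conditional probabilities under the
# standardized latent density.  (The 1.702 rule of thumb serves as the
# starting value; for extreme thresholds the projected slope sits a few
# percent above it, and the projection — not the rule — is what a
# correctly specified logistic fit converges to as n grows.)
implied_items <- function(thresholds, latent_var, unique_variance, pdf_std,
                          D = 1.702) {
  stopifnot(unique_variance > 0)
  s <- sqrt(latent_var)
  se <- sqrt(unique_variance)
  quad <- make_quadrature(101, c(-6, 6))
  wq <- pdf_std(quad$nodes)
  wq <- 1000 * wq / sum(wq)
  fits <- lapply(seq_len(nrow(thresholds)), function(j) {
    tau <- thresholds[j, ]
    Pge <- vapply(tau, function(t) pnorm((s * quad$nodes - t) / se),
                  numeric(length(quad$nodes)))
    P <- cbind(1, Pge) - cbind(Pge, 0)
    update_item(P * wq, quad$nodes, D * s / se, -D * tau / se)
  })
  item_tibble(fits, labels = sprintf("item%02d", seq_len(nrow(thresholds))))
}

#' Simulate a full ordinal dataset with known truth
#'
#' Bundles [draw_latent()], [make_items()] and [ordinalize()] into one
#' deterministic pipeline (child seeds are split from the master seed with
#' [make_child_seeds()]).  Everything a recovery experiment needs is
#' returned: the observed ordinals, the exact generating density (raw and
#' standardized) for integrated-squared-error targets, the true latent values
#' for scoring error, and the implied graded-response item parameters of the
#' generating process on the standardized metric.
#'
#' @param spec A [latent_spec()].
#' @param n Number of persons.
#' @param seed Master seed.
#' @param n_items Number of items.
#' @param unique_variance Item noise variance (see [make_items()]).
#' @param freqs Target category frequencies (see [ordinalize()]).
#' @return Object of class `dcirt_simulation`: a list with `responses`,
#'   `theta`, `density`, `density_std`, `true_items`, `thresholds`, `spec`,
#'   `seed`.
#' @export
simulate_dataset <- function(spec, n, seed = 1, n_items = 9,
                             unique_variance = 1 - 1 / sqrt(2),
                             freqs = default_category_freqs(n_items)) {
  cs <- make_child_seeds(seed, 2)
  lat <- draw_latent(spec, n, seed = cs[1])
  cont <- make_items(lat$theta, n_items = n_items,
                     unique_variance = unique_variance, seed = cs[2])
  resp <- ordinalize(cont, freqs)
  thr <- attr(resp, "thresholds")
  structure(list(
    responses = resp,
    theta = lat$theta,
    density = lat$density,
    density_std = lat$density_std,
    true_items = implied_items(thr, spec$variance, unique_variance,
                               pdf_std = function(z) {
                                 sqrt(spec$variance) *
                                   spec$pdf(sqrt(spec$variance) * z + spec$mean)
                               }),
    thresholds = thr,
    spec = spec,
    seed = seed
  ), class = "dcirt_simulation")
}

#' @export
print.dcirt_simulation <- function(x, ...) {
  cat(sprintf("Simulated DC-IRT dataset: %d persons x %d items, %s latent shape, seed %d\n",
              nrow(x$responses), ncol(x$responses), x$spec$shape, x$seed))
  invisible(x)
}
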