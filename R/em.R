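#' Coerce ordinal response data to an integer matrix
#'
#' Accepts a data frame or matrix of integer category codes (`0..3` for
#' 4-category items, `NA` for missing) and validates the codes.
#'
#' @param data Persons x items data frame or matrix.
#' @param max_code Largest admissible category code.
#' @return Integer matrix with item columns; attribute `labels` holds item
#'   names.
#' @export
as_response_matrix <- function(data, max_code = 3L) {
  m <- as.matrix(data)
  labels <- colnames(m)
  if (is.null(labels)) labels <- paste0("item", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  bad <- which(!is.na(m) & (m < 0L | m > max_code))
  if (length(bad) > 0) {
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("response codes must be in 0..%d or NA; column '%s' has value %s",
                 max_code, labels[j], m[bad[1]]))
  }
  dimnames(m) <- NULL
  attr(m, "labels") <- labels
  m
}

#' Quadrature grid for marginal likelihood integration
#'
#' Equally spaced nodes with rectangular weights; the latent density is
#' evaluated at the nodes and normalized to a discrete prior, the standard
#' fixed-grid construction for EM-based item response models.
#'
#' @param n Number of nodes.
#' @param bounds Interval covered.
#' @return List with `nodes` and `weights`.
#' @export
make_quadrature <- function(n = 101, bounds = c(-6, 6)) {
  nodes <- seq(bounds[1], bounds[2], length.out = n)
  list(nodes = nodes, weights = rep(diff(bounds) / (n - 1), n))
}

# Discrete log prior at the nodes for a curve (NULL = standard normal).
log_prior_at <- function(quad, curve = NULL) {
  h <- if (is.null(curve)) dnorm(quad$nodes) else dc_density(curve, quad$nodes)
  p <- h * quad$weights
  log(p / sum(p))
}

log_item_probs <- function(items_l, nodes) {
  lapply(items_l, function(it) log(pmax(grm_probs(it$a, it$d, nodes), 1e-300)))
}

#' E step: expected counts and marginal log-likelihood
#'
#' For each person, posterior weights over the quadrature nodes are
#' proportional to the prior mass times the product of category probabilities
#' of the observed responses (missing responses drop out of the product).
#' Accumulated over persons these give expected node counts `nq` and, per
#' item, expected category-by-node counts.  The marginal log-likelihood is
#' summed with a log-sum-exp underflow guard.
#'
#' @param data Response data (see [as_response_matrix()]).
#' @param items Item tibble with columns `a`, `d1`, `d2`, ... .
#' @param curve Latent density as a [dc_curve()]; `NULL` means standard
#'   normal.
#' @param quad Quadrature from [make_quadrature()].
#' @return List with `loglik`, `nq` (length-Q vector) and `r` (list of
#'   Q x ncat expected count matrices, one per item).
#' @export
e_step <- function(data, items, curve = NULL, quad = make_quadrature()) {
  resp <- as_response_matrix(data)
  items_l <- item_list(items)
  stopifnot(ncol(resp) == length(items_l))
  logp <- log_item_probs(items_l, quad$nodes)
  estep_cpp(resp, logp, log_prior_at(quad, curve))
}

# The per-item weighted graded-response likelihood (r_mat is Q x ncat of
# expected counts) is maximized in the (a, d1, log gaps) parameterization so
# intercept monotonicity is free; objective and analytic gradient live in
# compiled code (src/estep.cpp).
update_item <- function(r_mat, nodes, a0, d0) {
  nb <- length(d0)
  par0 <- c(a0, d0[1], if (nb > 1) log(pmax(-diff(d0), 1e-6)))
  opt <- optim(par0, item_negll_cpp, item_grad_cpp, r = r_mat, nodes = nodes,
               method = "BFGS", control = list(maxit = 100, reltol = 1e-10))
  if (!is.finite(opt$value) ||
      opt$value > item_negll_cpp(par0, r_mat, nodes) + 1e-8) {
    stop("item M-step failed to improve the complete-data likelihood")
  }
  a <- opt$par[1]
  d <- opt$par[2] - c(0, cumsum(exp(opt$par[seq_len(nb - 1) + 2])))
  list(a = a, d = d)
}

curve_negll <- function(angles, k, nq, nodes) {
  m <- dc_coef(k, angles)
  h <- poly_eval(m, nodes)^2 * dnorm(nodes)
  p <- pmax(h / sum(h), 1e-300)
  -sum(nq * log(p))
}

# Jacobian d u / d angles of the spherical map (k+1) x k; k is small, so the
# exclusion products are computed directly rather than by division (which
# breaks down at angles of pi/2).
spherical_jacobian <- function(angles) {
  k <- length(angles)
  cosv <- cos(angles)
  sinv <- sin(angles)
  J <- matrix(0, k + 1, k)
  for (j in seq_len(k)) {
    for (i in seq_len(j)) {
      J[j, i] <- if (i == j) {
        cosv[j] * prod(cosv[seq_len(j - 1)])
      } else {
        -sinv[i] * sinv[j] * prod(cosv[setdiff(seq_len(j - 1), i)])
      }
    }
  }
  for (i in seq_len(k)) J[k + 1, i] <- -sinv[i] * prod(cosv[-i])
  J
}

curve_negll_grad <- function(angles, k, nq, nodes) {
  R <- moment_chol(k)
  u <- spherical_unit(angles)
  m <- backsolve(R, u)
  P <- poly_eval(m, nodes)
  h <- P^2 * dnorm(nodes)
  w <- sum(nq) * h / sum(h) - nq
  # d f / d m_l = 2 sum_q w_q theta_q^l / P_q; nodes sitting on a polynomial
  # root contribute nothing (the objective is clamped there)
  base <- 2 * w * ifelse(abs(P) < 1e-12, 0, 1 / P)
  dfdm <- drop(crossprod(outer(nodes, 0:k, `^`), base))
  dfdu <- forwardsolve(t(R), dfdm)
  drop(crossprod(spherical_jacobian(angles), dfdu))
}

update_curve <- function(nq, nodes, k, angles0) {
  R <- moment_chol(k)
  Tmat <- outer(nodes, 0:k, `^`)
  phi <- dnorm(nodes)
  N <- sum(nq)
  fn <- function(angles) {
    u <- spherical_unit(angles)
    h <- drop(Tmat %*% backsolve(R, u))^2 * phi
    -sum(nq * log(pmax(h / sum(h), 1e-300)))
  }
  gr <- function(angles) {
    u <- spherical_unit(angles)
    P <- drop(Tmat %*% backsolve(R, u))
    h <- P^2 * phi
    w <- N * h / sum(h) - nq
    base <- 2 * w * ifelse(abs(P) < 1e-12, 0, 1 / P)
    dfdu <- forwardsolve(t(R), drop(crossprod(Tmat, base)))
    drop(crossprod(spherical_jacobian(angles), dfdu))
  }
  opt <- optim(angles0, fn, gr, method = "BFGS",
               control = list(maxit = 100, reltol = 1e-11))
  if (!is.finite(opt$value) || opt$value > fn(angles0) + 1e-8) {
    stop("density M-step failed to improve the complete-data likelihood")
  }
  opt$par
}

#' M step: maximize the expected complete-data log-likelihood
#'
#' Per-item weighted logistic-ordinal likelihoods are maximized by
#' quasi-Newton with analytic gradients (intercept monotonicity enforced by a
#' log-gap parameterization); the Davidian-curve angles are updated by
#' quasi-Newton on the multinomial node-count likelihood.  Both updates start
#' from the current parameters, so each step is ascent up to optimizer
#' tolerance.
#'
#' @param counts Output of [e_step()].
#' @param items Current item tibble.
#' @param k Davidian-curve order; `k <= 1` keeps the standard normal density
#'   fixed.
#' @param angles Current curve angles (required when `k >= 2`).
#' @param quad Quadrature from [make_quadrature()].
#' @return List with updated `items` tibble, `angles` and `curve`.
#' @export
m_step <- function(counts, items, k = 0, angles = NULL,
                   quad = make_quadrature()) {
  items_l <- item_list(items)
  upd <- lapply(seq_along(items_l), function(j) {
    update_item(counts$r[[j]], quad$nodes, items_l[[j]]$a, items_l[[j]]$d)
  })
  labels <- if ("label" %in% names(items)) items$label else NULL
  out_items <- item_tibble(upd, labels = labels)
  if (k >= 2) {
    if (is.null(angles)) stop("`angles` required for k >= 2")
    angles <- update_curve(counts$nq, quad$nodes, k, angles)
    curve <- angles_to_coefficients(k, angles)
  } else {
    curve <- dc_curve(0, 1)
  }
  list(items = out_items, angles = angles, curve = curve)
}

#' Information criteria for a fitted model
#'
#' `HQ = -2 logL + 2 c p log(log n)`, `AIC = -2 logL + 2p`,
#' `BIC = -2 logL + p log n`; smaller is better.  The Hannan-Quinn constant
#' `c` defaults to 1 (the form used throughout here); values above 1 make the
#' criterion strictly consistent.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n Number of observations (must be at least 3 so the HQ penalty is
#'   positive).
#' @param hq_c Hannan-Quinn multiplier.
#' @return One-row tibble with columns `HQ`, `AIC`, `BIC`.
#' @export
information_criteria <- function(loglik, n_params, n, hq_c = 1) {
  stopifnot(is.finite(loglik))
  if (n < 3) stop("`n` must be at least 3 for a positive HQ penalty")
  tibble::tibble(
    HQ = -2 * loglik + 2 * hq_c * n_params * log(log(n)),
    AIC = -2 * loglik + 2 * n_params,
    BIC = -2 * loglik + n_params * log(n)
  )
}

# Default item starts: unit slope-ish, intercepts from marginal cumulative
# endorsement rates.
start_items <- function(resp, ncat_j) {
  lapply(seq_len(ncol(resp)), function(j) {
    x <- resp[, j]
    x <- x[!is.na(x)]
    nb <- ncat_j[j] - 1L
    cum <- vapply(seq_len(nb), function(c) mean(x >= c), numeric(1))
    cum <- pmin(pmax(cum, 1 / (length(x) + 1)), 1 - 1 / (length(x) + 1))
    d <- qlogis(cum)
    # force strict decrease in degenerate corners
    for (c in seq_len(nb)[-1]) if (d[c] >= d[c - 1]) d[c] <- d[c - 1] - 0.1
    list(a = 1.5, d = d)
  })
}

# Collapse empty categories; returns recoded matrix plus per-item mapping.
collapse_categories <- function(resp, max_code = 3L) {
  ncat_j <- integer(ncol(resp))
  maps <- vector("list", ncol(resp))
  for (j in seq_len(ncol(resp))) {
    x <- resp[, j]
    present <- sort(unique(x[!is.na(x)]))
    if (length(present) < 2) {
      stop(sprintf("item %d is constant after missing-data handling", j))
    }
    if (length(present) < max_code + 1L) {
      warning(sprintf(
        "item %d: empty categories collapsed (%d observed of %d); parameter count adjusted",
        j, length(present), max_code + 1L
      ), call. = FALSE)
    }
    map <- match(x, present) - 1L
    resp[, j] <- map
    ncat_j[j] <- length(present)
    maps[[j]] <- present
  }
  list(resp = resp, ncat = ncat_j, maps = maps)
}

#' Fit a DC-IRT model of fixed order
#'
#' Marginal maximum likelihood by EM: the E step computes expected
#' category-by-node counts under the current graded-response items and
#' Davidian-curve latent density; the M step re-maximizes items and curve.
#' Iteration stops when the largest absolute parameter change falls below
#' `tol`.  Orders `k = 0` and `k = 1` fit the traditional normal-latent model
#' (the curve family reduces to the standard normal there).  If the fit has
#' not converged after `max_iter` EM cycles at `tol`, one automatic
#' continuation at `10 * tol` is attempted and recorded.
#'
#' No location/scale constraint is imposed during estimation: the curve
#' family is anchored by its standard-normal base, and the reporting metric
#' is fixed afterwards by [standardized_density()] / [standardized_items()].
#'
#' @param data Persons x items ordinal responses (data frame or matrix,
#'   codes `0..3`, `NA` missing).
#' @param k Davidian-curve order, 0 to 10.
#' @param tol Convergence threshold on the maximum absolute parameter change.
#' @param max_iter Maximum EM cycles per tolerance level.
#' @param quad_points,bounds Quadrature grid (see [make_quadrature()]).
#' @param start Optional `dcirt_fit` whose item parameters seed this fit.
#' @param include_incomplete Keep persons with partial responses (item-wise
#'   skipping in the E step) instead of the default listwise deletion.
#' @param hq_c Hannan-Quinn multiplier (see [information_criteria()]).
#' @return Object of class `dcirt_fit`.
#' @export
fit_dcirt <- function(data, k = 0, tol = 1e-3, max_iter = 500,
                      quad_points = 101, bounds = c(-6, 6), start = NULL,
                      include_incomplete = FALSE, hq_c = 1) {
  stopifnot(k >= 0, k <= 10)
  resp <- as_response_matrix(data)
  labels <- attr(resp, "labels")
  keep <- rowSums(!is.na(resp)) > 0
  if (!include_incomplete) keep <- keep & stats::complete.cases(resp)
  n_dropped <- sum(!keep)
  resp <- resp[keep, , drop = FALSE]
  if (nrow(resp) == 0) stop("no usable rows in `data`")

  coll <- collapse_categories(resp)
  resp <- coll$resp

  items_l <- if (!is.null(start)) {
    stopifnot(inherits(start, "dcirt_fit"))
    sl <- item_list(start$items)
    if (length(sl) != ncol(resp) ||
        !all(vapply(sl, function(it) length(it$d), 0L) + 1L == coll$ncat)) {
      stop("`start` is not compatible with `data`")
    }
    sl
  } else {
    start_items(resp, coll$ncat)
  }

  # collapse to unique response patterns; the E step scales with patterns,
  # not persons
  enc <- resp
  enc[is.na(enc)] <- max(coll$ncat)
  key <- drop(enc %*% (max(coll$ncat) + 1)^(seq_len(ncol(enc)) - 1))
  first <- which(!duplicated(key))
  pat <- resp[first, , drop = FALSE]
  w <- as.numeric(tabulate(match(key, key[first]), nbins = length(first)))

  quad <- make_quadrature(quad_points, bounds)
  use_curve <- k >= 2
  angles <- if (use_curve) {
    if (!is.null(start) && !is.null(start$curve$angles) &&
        length(start$curve$angles) == k) start$curve$angles else rep(pi / 2, k)
  }

  par_vec <- function() {
    c(unlist(lapply(items_l, function(it) c(it$a, it$d))), angles)
  }

  loglik_trace <- numeric(0)
  converged <- FALSE
  retried <- FALSE
  tol_used <- tol
  iter <- 0L

  run_em <- function(tol_now, budget) {
    for (i in seq_len(budget)) {
      old <- par_vec()
      logp <- log_item_probs(items_l, quad$nodes)
      lp <- log_prior_at(quad, if (use_curve) angles_to_coefficients(k, angles))
      es <- estep_weighted_cpp(pat, w, logp, lp)
      loglik_trace[length(loglik_trace) + 1L] <<- es$loglik
      for (j in seq_along(items_l)) {
        items_l[[j]] <<- update_item(es$r[[j]], quad$nodes,
                                     items_l[[j]]$a, items_l[[j]]$d)
      }
      if (use_curve) angles <<- update_curve(es$nq, quad$nodes, k, angles)
      iter <<- iter + 1L
      if (max(abs(par_vec() - old)) < tol_now) return(TRUE)
    }
    FALSE
  }

  converged <- run_em(tol, max_iter)
  if (!converged) {
    retried <- TRUE
    tol_used <- 10 * tol
    converged <- run_em(tol_used, max_iter)
  }

  # log-likelihood at the final parameters
  logp <- log_item_probs(items_l, quad$nodes)
  curve <- if (use_curve) angles_to_coefficients(k, angles) else dc_curve(0, 1)
  lp <- log_prior_at(quad, if (use_curve) curve)
  es <- estep_weighted_cpp(pat, w, logp, lp)
  loglik <- es$loglik
  loglik_trace <- c(loglik_trace, loglik)

  n_obs <- nrow(resp)
  n_params <- sum(coll$ncat) + if (use_curve) k else 0L
  structure(list(
    items = item_tibble(items_l, labels = labels),
    curve = curve,
    k = as.integer(k),
    loglik = loglik,
    n_params = as.integer(n_params),
    n_obs = n_obs,
    criteria = information_criteria(loglik, n_params, n_obs, hq_c = hq_c),
    converged = converged,
    retried = retried,
    n_iterations = iter,
    em_tolerance = tol_used,
    loglik_trace = loglik_trace,
    quad = quad,
    category_maps = coll$maps,
    n_dropped = n_dropped
  ), class = "dcirt_fit")
}

#' @export
print.dcirt_fit <- function(x, ...) {
  cat(sprintf(
    "DC-IRT fit: k = %d, %d items, n = %d\nlogLik %.2f on %d parameters (%s, %d EM cycles)\n",
    x$k, nrow(x$items), x$n_obs, x$loglik, x$n_params,
    if (x$converged) "converged" else "NOT converged", x$n_iterations
  ))
  cat(sprintf("HQ %.1f | AIC %.1f | BIC %.1f\n",
              x$criteria$HQ, x$criteria$AIC, x$criteria$BIC))
  invisible(x)
}

#' @export
logLik.dcirt_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Standardized latent density of a fit
#'
#' The fitted Davidian curve after the change of variables to mean 0 and
#' variance 1 (see [standardize_density()]); for normal-latent fits this is
#' the standard normal density exactly.
#'
#' @param fit A `dcirt_fit`.
#' @param theta Output grid.
#' @return A [density_grid()] tibble.
#' @export
standardized_density <- function(fit, theta = default_theta_grid()) {
  stopifnot(inherits(fit, "dcirt_fit"))
  standardize_density(fit$curve, theta = theta)
}

#' Item parameters on the standardized latent metric
#'
#' @param fit A `dcirt_fit`.
#' @return Item tibble rescaled by the fitted density's mean and standard
#'   deviation (see [rescale_items()]).
#' @export
standardized_items <- function(fit) {
  stopifnot(inherits(fit, "dcirt_fit"))
  mom <- dc_moments(fit$curve, 2)
  rescale_items(fit$items, mean = mom$mean, sd = mom$sd)
}

#' Fit DC-IRT across orders and select by an information criterion
#'
#' Fits the traditional normal model first; its item parameters seed every
#' higher-order fit (curve angles start at the normal configuration).  The
#' model minimizing the chosen criterion wins; ties break toward smaller
#' order.
#'
#' @param data Ordinal response data.
#' @param criterion `"HQ"`, `"AIC"` or `"BIC"`.
#' @param orders Davidian-curve orders to fit.
#' @param ... Passed to [fit_dcirt()].
#' @return Object of class `dcirt_selection` with elements `fit` (the
#'   selected model), `table` (per-order criterion tibble), `fits` (all
#'   successful fits) and `criterion`.
#' @export
select_model <- function(data, criterion = c("HQ", "AIC", "BIC"),
                         orders = c(0, 2:10), ...) {
  criterion <- match.arg(criterion)
  stopifnot(length(orders) > 0)
  orders <- sort(unique(as.integer(orders)))
  normal_fit <- fit_dcirt(data, k = 0, ...)
  fits <- list()
  errors <- character(0)
  for (k in orders) {
    fits[[as.character(k)]] <- if (k <= 1) {
      if (k == 0) normal_fit else fit_dcirt(data, k = k, ...)
    } else {
      tryCatch(fit_dcirt(data, k = k, start = normal_fit, ...),
               error = function(e) {
                 errors[[length(errors) + 1L]] <<- sprintf("k=%d: %s", k, conditionMessage(e))
                 NULL
               })
    }
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("all fits failed:\n", paste(errors, collapse = "\n"))
  }
  tab <- dplyr::bind_rows(lapply(fits, function(f) {
    dplyr::bind_cols(
      tibble::tibble(order = f$k, loglik = f$loglik, n_params = f$n_params),
      f$criteria,
      tibble::tibble(converged = f$converged, n_iterations = f$n_iterations,
                     em_tolerance = f$em_tolerance)
    )
  }))
  tab <- dplyr::arrange(tab, .data$order)
  best <- tab$order[which.min(tab[[criterion]])]
  structure(list(
    fit = fits[[as.character(best)]],
    table = tab,
    fits = fits,
    criterion = criterion,
    errors = errors
  ), class = "dcirt_selection")
}

#' @export
print.dcirt_selection <- function(x, ...) {
  cat(sprintf("DC-IRT model selection by %s: selected k = %d\n",
              x$criterion, x$fit$k))
  print(x$table)
  invisible(x)
}

#' Expected a posteriori latent-trait scores
#'
#' Posterior mean and SD of the latent trait for each person under the fitted
#' model's latent density, computed on the quadrature grid and reported on
#' the standardized (mean 0, variance 1) metric.
#'
#' @param data Ordinal response data (same items as the fit).
#' @param fit A `dcirt_fit`.
#' @return Tibble with columns `person`, `eap`, `eap_sd`.
#' @export
eap_scores <- function(data, fit) {
  stopifnot(inherits(fit, "dcirt_fit"))
  resp <- as_response_matrix(data)
  items_l <- item_list(fit$items)
  stopifnot(ncol(resp) == length(items_l))
  quad <- fit$quad
  logp <- log_item_probs(items_l, quad$nodes)
  lp <- log_prior_at(quad, if (fit$k >= 2) fit$curve)
  post <- posterior_cpp(resp, logp, lp)
  m1 <- drop(post %*% quad$nodes)
  m2 <- drop(post %*% quad$nodes^2)
  mom <- dc_moments(fit$curve, 2)
  tibble::tibble(
    person = seq_len(nrow(resp)),
    eap = (m1 - mom$mean) / mom$sd,
    eap_sd = sqrt(pmax(m2 - m1^2, 0)) / mom$sd
  )
}
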