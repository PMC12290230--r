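#' Graded-response category probabilities
#'
#' Cumulative category probabilities are logistic in the latent trait:
#' `P(X >= c | theta) = plogis(a * theta + d_c)` for `c = 1..C-1`, with
#' `P(X >= 0) = 1`.  Category probabilities are adjacent differences of the
#' cumulative curve.  No scaling constant is used inside the logistic — the
#' slope/intercept metric is the logistic one; the 1.702 constant enters only
#' in [factor_loading()].
#'
#' @param a Discrimination.
#' @param d Strictly decreasing intercept vector (`d_1 > d_2 > ...`),
#'   one per category boundary.
#' @param theta Numeric vector of latent values.
#' @return Matrix `length(theta) x (length(d) + 1)` of category
#'   probabilities; rows sum to 1.
#' @export
grm_probs <- function(a, d, theta) {
  cum <- grm_cumulative(a, d, theta)
  p <- cbind(1, cum) - cbind(cum, 0)
  pmax(p, 0)
}

grm_cumulative <- function(a, d, theta) {
  stopifnot(length(a) == 1, is.finite(a), length(d) >= 1, all(is.finite(d)))
  if (length(d) > 1 && any(diff(d) >= 0)) {
    stop("item intercepts must be strictly decreasing (d1 > d2 > ...)")
  }
  matrix(plogis(outer(a * theta, d, `+`)), nrow = length(theta))
}

#' Expected item score
#'
#' `E[X | theta] = sum_c P(X >= c | theta)`, nondecreasing in `theta` for
#' positive discrimination.
#'
#' @inheritParams grm_probs
#' @return Numeric vector of expected scores in `[0, length(d)]`.
#' @export
expected_score <- function(a, d, theta) {
  rowSums(grm_cumulative(a, d, theta))
}

#' Generalized severity of an item
#'
#' The single location index of an item response function: the latent value
#' at which the expected item score reaches half its maximum (`m/2`, with
#' `m` the highest category).  Found by bracketed root finding.
#'
#' @inheritParams grm_probs
#' @param target Expected score to invert at; defaults to `length(d) / 2`.
#' @param bracket Search interval.
#' @return Scalar latent value.
#' @examples
#' generalized_severity(3.13, c(-2.43, -4.41, -5.59)) # about 1.34
#' @export
generalized_severity <- function(a, d, target = length(d) / 2,
                                 bracket = c(-10, 10)) {
  f <- function(th) expected_score(a, d, th) - target
  lo <- f(bracket[1])
  hi <- f(bracket[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) {
    stop("degenerate item: expected score does not cross the target in the bracket")
  }
  uniroot(f, bracket, tol = 1e-10)$root
}

#' Factor loading implied by a logistic discrimination
#'
#' `a / sqrt(D^2 + a^2)` with `D = 1.702`, the constant aligning the logistic
#' with the cumulative normal; maps a slope onto the common-factor metric,
#' bounded in `[0, 1)` for `a >= 0`.
#'
#' @param a Discrimination(s).
#' @param D Logistic/normal-ogive alignment constant.
#' @return Numeric vector of loadings.
#' @examples
#' factor_loading(3.13) # 0.88 to two decimals
#' @export
factor_loading <- function(a, D = 1.702) {
  a / sqrt(D^2 + a^2)
}

#' Rescale item parameters to a new latent metric
#'
#' If the latent trait is re-expressed as `z = (theta - mean)/sd`, item
#' parameters transform as `a* = a * sd`, `d* = d + a * mean`, so that
#' category probabilities at `z` equal the original probabilities at
#' `theta = sd * z + mean`.  Used together with [standardize_density()] to
#' report fits on the mean-0, variance-1 metric.
#'
#' @param items Tibble with columns `a` and `d1`, `d2`, ... (one row per item).
#' @param mean,sd Location and scale of the original metric; `sd > 0`.
#' @return Tibble of the same shape with transformed parameters.
#' @export
rescale_items <- function(items, mean, sd) {
  stopifnot(is.data.frame(items), "a" %in% names(items))
  if (sd <= 0) stop("`sd` must be positive")
  d_cols <- grep("^d[0-9]+$", names(items), value = TRUE)
  out <- items
  for (col in d_cols) out[[col]] <- items[[col]] + items$a * mean
  out$a <- items$a * sd
  out
}

#' Item-parameter summary table
#'
#' Augments an item table with the generalized severity index and the implied
#' factor loading of each item.
#'
#' @param items Tibble with columns `label` (optional), `a`, `d1`, `d2`, ....
#' @param D Constant passed to [factor_loading()].
#' @return Tibble with added columns `severity` and `loading`.
#' @export
item_summary <- function(items, D = 1.702) {
  d_cols <- grep("^d[0-9]+$", names(items), value = TRUE)
  sev <- vapply(seq_len(nrow(items)), function(i) {
    d <- as.numeric(items[i, d_cols])
    d <- d[!is.na(d)]
    tryCatch(generalized_severity(items$a[i], d), error = function(e) NA_real_)
  }, numeric(1))
  dplyr::mutate(items, severity = sev, loading = factor_loading(.data$a, D = D))
}

# items tibble -> list of list(a, d) with NA intercepts dropped
item_list <- function(items) {
  d_cols <- grep("^d[0-9]+$", names(items), value = TRUE)
  lapply(seq_len(nrow(items)), function(i) {
    d <- as.numeric(items[i, d_cols])
    list(a = items$a[i], d = d[!is.na(d)])
  })
}

# inverse of item_list(); pads ragged intercept vectors with NA
item_tibble <- function(lst, labels = NULL) {
  ncat_max <- max(vapply(lst, function(it) length(it$d), integer(1))) + 1L
  rows <- lapply(seq_along(lst), function(i) {
    d <- lst[[i]]$d
    length(d) <- ncat_max - 1L
    out <- c(list(a = lst[[i]]$a), as.list(stats::setNames(d, paste0("d", seq_along(d)))))
    tibble::as_tibble(out)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(labels)) out <- dplyr::bind_cols(tibble::tibble(label = labels), out)
  out
}

#' Reference DC-IRT item parameters for the PHQ-9
#'
#' Published discrimination and intercept estimates for the nine PHQ-9 items
#' from a pooled NHANES 2005-2018 analysis (36,244 complete cases,
#' BIC-selected Davidian-curve latent density).  Useful as a realistic item
#' bank for examples and as input to [generalized_severity()] and
#' [factor_loading()].
#'
#' @return Tibble with columns `label`, `a`, `d1`, `d2`, `d3`.
#' @export
phq9_reference_items <- function() {
  tibble::tribble(
    ~label,                        ~a,   ~d1,   ~d2,   ~d3,
    "Loss of pleasure",          3.13, -2.43, -4.41, -5.59,
    "Low mood",                  4.32, -3.17, -5.81, -7.20,
    "In-/hypersomnia",           2.21, -1.02, -2.69, -3.55,
    "Fatigue",                   2.66, -0.40, -2.90, -3.96,
    "Changes in appetite",       2.45, -2.04, -3.66, -4.63,
    "Worthlessness/guilt",       3.77, -3.63, -5.69, -6.84,
    "Concentration problems",    2.99, -3.07, -4.75, -5.70,
    "Psychomotor problems",      2.91, -3.77, -5.27, -6.27,
    "Self-harm/death thoughts",  3.23, -5.69, -7.20, -8.08
  )
}
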