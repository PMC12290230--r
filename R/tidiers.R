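#' Tidy a fitted DC-IRT model
#'
#' One row per item, on the standardized (mean 0, variance 1) latent metric,
#' with the generalized severity index and implied factor loading of each
#' item — the layout of a published item-parameter table.
#'
#' @param x A `dcirt_fit`.
#' @param standardized Report on the standardized metric (recommended); if
#'   `FALSE`, the raw estimation metric is used.
#' @param ... Unused.
#' @return Tibble with columns `label`, `a`, `d1`, ..., `severity`,
#'   `loading`.
#' @export
tidy.dcirt_fit <- function(x, standardized = TRUE, ...) {
  items <- if (standardized) standardized_items(x) else x$items
  item_summary(items)
}

#' Glance at a fitted DC-IRT model
#'
#' @param x A `dcirt_fit`.
#' @param ... Unused.
#' @return One-row tibble: `k`, `loglik`, `n_params`, `n_obs`, `HQ`, `AIC`,
#'   `BIC`, `converged`, `n_iterations`, `em_tolerance`.
#' @export
glance.dcirt_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(k = x$k, loglik = x$loglik, n_params = x$n_params,
                   n_obs = x$n_obs),
    x$criteria,
    tibble::tibble(converged = x$converged, n_iterations = x$n_iterations,
                   em_tolerance = x$em_tolerance)
  )
}

#' Tidy a DC-IRT model selection
#'
#' @param x A `dcirt_selection`.
#' @param ... Unused.
#' @return The per-order criterion table (one row per fitted order).
#' @export
tidy.dcirt_selection <- function(x, ...) x$table

#' @export
glance.dcirt_selection <- function(x, ...) {
  dplyr::mutate(glance(x$fit), criterion = x$criterion)
}

#' Tidy a simulation study
#'
#' @param x A `dcirt_sim_study`.
#' @param ... Unused.
#' @return The long per-replicate results tibble.
#' @export
tidy.dcirt_sim_study <- function(x, ...) x$results

#' @export
glance.dcirt_sim_study <- function(x, ...) x$summary

#' Tidy a subsample density analysis
#'
#' @param x A `dcirt_subsamples`.
#' @param ... Unused.
#' @return Per-subsample moments tibble (`selected_k`, `skewness`,
#'   `ex_kurtosis`, `modes`).
#' @export
tidy.dcirt_subsamples <- function(x, ...) x$moments

#' @export
glance.dcirt_subsamples <- function(x, ...) {
  tidyr::pivot_wider(x$moment_summary, names_from = "moment",
                     values_from = c("mean", "se", "ci_lo", "ci_hi"))
}
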