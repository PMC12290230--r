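#' Sum-score descriptive statistics
#'
#' Per-person sum of item codes over complete cases, summarized by mean,
#' standard error of the mean (`SD/sqrt(n)`), Fisher's moment coefficient of
#' skewness (`m3 / m2^1.5`) and Pearson's excess kurtosis (`m4 / m2^2 - 3`),
#' with optional small-sample bias adjustment of the latter two.
#'
#' @param data Ordinal response data frame/matrix.
#' @param bias_adjust Use the bias-adjusted (sample-size-corrected)
#'   skewness/kurtosis estimators instead of the plain moment ratios.
#' @return One-row tibble: `n`, `mean`, `sd`, `sem`, `skewness`,
#'   `ex_kurtosis`.
#' @export
sum_score_descriptives <- function(data, bias_adjust = FALSE) {
  resp <- as_response_matrix(data)
  resp <- resp[stats::complete.cases(resp), , drop = FALSE]
  if (nrow(resp) == 0) stop("no complete cases in `data`")
  s <- rowSums(resp)
  n <- length(s)
  m <- mean(s)
  m2 <- mean((s - m)^2)
  if (m2 == 0) {
    warning("constant sum scores: skewness and kurtosis undefined", call. = FALSE)
    return(tibble::tibble(n = n, mean = m, sd = 0, sem = 0,
                          skewness = NA_real_, ex_kurtosis = NA_real_))
  }
  m3 <- mean((s - m)^3)
  m4 <- mean((s - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  if (bias_adjust) {
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  tibble::tibble(n = n, mean = m, sd = stats::sd(s), sem = stats::sd(s) / sqrt(n),
                 skewness = g1, ex_kurtosis = g2)
}

#' Simulation study: estimation accuracy across shapes and sample sizes
#'
#' For each latent shape, sample size and replicate: simulate ordinal data,
#' fit DC-IRT across `orders`, select per criterion, standardize the selected
#' density and measure its integrated squared error against the standardized
#' generating density.  All fits for a replicate are shared across criteria,
#' so comparing criteria costs nothing extra.  Deterministic given the master
#' seed.
#'
#' @param shapes Latent shapes (see [latent_spec()]).
#' @param sample_sizes Integer vector of simulated sample sizes.
#' @param replicates Replicates per shape-by-size cell (at least 2, so
#'   standard errors exist).
#' @param criteria Selection criteria to evaluate.
#' @param seed Master seed.
#' @param orders Davidian-curve orders to fit.
#' @param n_items,unique_variance,freqs Generator settings (see
#'   [simulate_dataset()]).
#' @param keep_details Attach a `detail` list-column to the results carrying,
#'   per replicate, the selected fit, the generating item parameters and the
#'   standardized true and estimated density grids — the raw material for
#'   recovery diagnostics.
#' @param ... Further arguments to [fit_dcirt()].
#' @return Object of class `dcirt_sim_study`: list with `results` (one row
#'   per shape x n x replicate x criterion: `selected_k`, `ise`, `converged`)
#'   and `summary` (mean ISE, its SE and a normal-approximation 95% CI per
#'   cell), plus the configuration.  Failed replicates carry `NA` ISE and are
#'   excluded from summaries (`n_failed` reports them).
#' @export
run_sim_study <- function(shapes = c("gaussian", "skewed", "bimodal"),
                          sample_sizes = c(1000, 3000), replicates = 10,
                          criteria = "HQ", seed = 1, orders = c(0, 2:10),
                          n_items = 9, unique_variance = 1 - 1 / sqrt(2),
                          freqs = default_category_freqs(n_items),
                          keep_details = FALSE, ...) {
  stopifnot(replicates >= 2)
  cells <- tidyr::expand_grid(shape = shapes, n = sample_sizes,
                              replicate = seq_len(replicates))
  cells$cell_seed <- make_child_seeds(seed, nrow(cells))
  rows <- purrr::pmap(cells, function(shape, n, replicate, cell_seed) {
    spec <- latent_spec(shape)
    sim <- simulate_dataset(spec, n, seed = cell_seed, n_items = n_items,
                            unique_variance = unique_variance, freqs = freqs)
    sel <- tryCatch(
      select_model(sim$responses, criterion = criteria[1], orders = orders, ...),
      error = function(e) NULL
    )
    purrr::map_dfr(criteria, function(crit) {
      if (is.null(sel)) {
        return(tibble::tibble(shape = shape, n = n, replicate = replicate,
                              criterion = crit, selected_k = NA_integer_,
                              ise = NA_real_, converged = NA))
      }
      best_k <- sel$table$order[which.min(sel$table[[crit]])]
      f <- sel$fits[[as.character(best_k)]]
      dens <- standardized_density(f)
      row <- tibble::tibble(
        shape = shape, n = n, replicate = replicate, criterion = crit,
        selected_k = f$k,
        ise = ise(dens, sim$density_std),
        converged = f$converged
      )
      if (keep_details) {
        row$detail <- list(list(fit = f, true_items = sim$true_items,
                                density_std = sim$density_std,
                                density_est = dens))
      }
      row
    })
  })
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$shape, .data$n, .data$criterion) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      n_failed = sum(is.na(.data$ise)),
      mean_ise = mean(.data$ise, na.rm = TRUE),
      se_ise = stats::sd(.data$ise, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$ise))),
      ci_lo = mean_ise - 1.96 * se_ise,
      ci_hi = mean_ise + 1.96 * se_ise,
      .groups = "drop"
    )
  structure(list(results = results, summary = summary,
                 config = list(shapes = shapes, sample_sizes = sample_sizes,
                               replicates = replicates, criteria = criteria,
                               seed = seed, orders = orders)),
            class = "dcirt_sim_study")
}

#' @export
print.dcirt_sim_study <- function(x, ...) {
  cat("DC-IRT simulation study\n")
  print(x$summary)
  invisible(x)
}

#' Subsample-averaged latent density with Wald confidence bands
#'
#' Draws disjoint subsamples from pooled data (one seeded permutation,
#' chunked), selects a DC-IRT model per subsample, standardizes each density
#' and reports the pointwise mean curve with a 95% Wald band
#' (`mean +/- 1.96 * SD / sqrt(n_subsamples)`), together with per-subsample
#' density skewness/excess kurtosis (by trapezoid integration on the grid)
#' and Wald summaries of those moments.
#'
#' @param data Pooled ordinal response data (complete cases are used).
#' @param n_subsamples Number of disjoint subsamples.
#' @param subsample_size Persons per subsample.
#' @param criterion Selection criterion within each subsample.
#' @param seed Seed for the permutation.
#' @param orders Davidian-curve orders to fit.
#' @param theta Common density grid.
#' @param min_prominence Mode-counting threshold (see [count_modes()]).
#' @param ... Further arguments to [fit_dcirt()].
#' @return Object of class `dcirt_subsamples`: `densities` (long tibble:
#'   `subsample`, `theta`, `density`), `band` (`theta`, `mean`, `lo`, `hi`),
#'   `moments` (per subsample: `selected_k`, `skewness`, `ex_kurtosis`,
#'   `modes`), `moment_summary`, `selections` (the per-subsample selection
#'   objects) and `subsample_rows` (the disjoint row-index sets).
#' @export
subsample_density_analysis <- function(data, n_subsamples = 12,
                                       subsample_size = 3000,
                                       criterion = "HQ", seed = 1,
                                       orders = c(0, 2:10),
                                       theta = default_theta_grid(),
                                       min_prominence = 0.05, ...) {
  resp <- as_response_matrix(data)
  resp <- resp[stats::complete.cases(resp), , drop = FALSE]
  if (nrow(resp) < n_subsamples * subsample_size) {
    stop(sprintf("pooled data has %d complete cases; %d are needed",
                 nrow(resp), n_subsamples * subsample_size))
  }
  perm <- with_seed(seed, sample.int(nrow(resp)))
  idx <- lapply(seq_len(n_subsamples), function(b) {
    perm[((b - 1) * subsample_size + 1):(b * subsample_size)]
  })
  stopifnot(!anyDuplicated(unlist(idx)))

  selections <- vector("list", n_subsamples)
  dens <- vector("list", n_subsamples)
  moments <- vector("list", n_subsamples)
  for (b in seq_len(n_subsamples)) {
    sel <- select_model(resp[idx[[b]], , drop = FALSE], criterion = criterion,
                        orders = orders, ...)
    g <- standardized_density(sel$fit, theta = theta)
    gm <- grid_moments(g)
    cm <- dc_moments(sel$fit$curve)
    if (is.finite(cm$skewness) && abs(gm$skewness - cm$skewness) > 1e-3) {
      warning(sprintf(
        "subsample %d: grid-integrated skewness differs from closed form by %.2g (grid truncation)",
        b, abs(gm$skewness - cm$skewness)
      ), call. = FALSE)
    }
    selections[[b]] <- sel
    dens[[b]] <- dplyr::mutate(g, subsample = b, .before = 1)
    moments[[b]] <- tibble::tibble(
      subsample = b, selected_k = sel$fit$k,
      skewness = gm$skewness, ex_kurtosis = gm$ex_kurtosis,
      modes = count_modes(g, min_prominence = min_prominence)
    )
  }
  densities <- dplyr::bind_rows(dens)
  dmat <- matrix(densities$density, nrow = length(theta))
  mu <- rowMeans(dmat)
  se <- apply(dmat, 1, stats::sd) / sqrt(n_subsamples)
  band <- tibble::tibble(theta = theta, mean = mu,
                         lo = mu - 1.96 * se, hi = mu + 1.96 * se)
  moments <- dplyr::bind_rows(moments)
  moment_summary <- moments |>
    tidyr::pivot_longer(c("skewness", "ex_kurtosis"), names_to = "moment") |>
    dplyr::group_by(.data$moment) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      ci_lo = mean - 1.96 * se,
      ci_hi = mean + 1.96 * se,
      .groups = "drop"
    )
  structure(list(densities = densities, band = band, moments = moments,
                 moment_summary = moment_summary, selections = selections,
                 subsample_rows = idx,
                 config = list(n_subsamples = n_subsamples,
                               subsample_size = subsample_size,
                               criterion = criterion, seed = seed)),
            class = "dcirt_subsamples")
}

#' @export
print.dcirt_subsamples <- function(x, ...) {
  cat(sprintf("DC-IRT subsample analysis: %d disjoint subsamples of %d (%s)\n",
              x$config$n_subsamples, x$config$subsample_size,
              x$config$criterion))
  print(x$moment_summary)
  invisible(x)
}

#' Full-data DC-IRT fit with a Table-style item report
#'
#' Selects a model on the pooled complete-case data (BIC by default — the
#' criterion that stays reliable at large n), then reports the standardized
#' density, its moments, the standardized item-parameter table with
#' generalized severities and implied factor loadings, and the
#' traditional-normal-IRT loadings refit on the same data for comparison.
#'
#' @param data Pooled ordinal response data.
#' @param criterion Selection criterion.
#' @param orders Davidian-curve orders to fit.
#' @param theta Density grid.
#' @param ... Further arguments to [fit_dcirt()].
#' @return Object of class `dcirt_full_fit`: `selection`, `fit`, `density`
#'   (standardized grid), `moments`, `items` (Table-style tibble with
#'   `severity`, `loading` and `loading_normal` columns) and `modes`.
#' @export
full_data_fit <- function(data, criterion = "BIC", orders = c(0, 2:10),
                          theta = default_theta_grid(), ...) {
  sel <- select_model(data, criterion = criterion, orders = orders, ...)
  dens <- standardized_density(sel$fit, theta = theta)
  items <- item_summary(standardized_items(sel$fit))
  normal_fit <- sel$fits[["0"]]
  if (is.null(normal_fit)) normal_fit <- fit_dcirt(data, k = 0, ...)
  items$loading_normal <- factor_loading(standardized_items(normal_fit)$a)
  structure(list(
    selection = sel, fit = sel$fit, density = dens,
    moments = grid_moments(dens), items = items,
    modes = count_modes(dens)
  ), class = "dcirt_full_fit")
}

#' @export
print.dcirt_full_fit <- function(x, ...) {
  cat(sprintf("DC-IRT full-data fit (%s-selected k = %d), %d modes\n",
              x$selection$criterion, x$fit$k, x$modes))
  cat(sprintf("density skewness %.3f, excess kurtosis %.3f\n",
              x$moments$skewness, x$moments$ex_kurtosis))
  print(x$items)
  invisible(x)
}
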