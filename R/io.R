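#' Item column names of the NHANES depression screener
#'
#' @return Character vector `DPQ010..DPQ090`.
#' @export
nhanes_items <- function() paste0("DPQ0", 1:9, "0")

#' Read an ordinal response table from CSV or SAS transport
#'
#' Reads a cohort file, keeps the item columns, maps the declared missing
#' codes (NHANES uses 7 = refused, 9 = don't know) to `NA` and, by default,
#' drops incomplete rows.  An ingestion report (rows read/dropped, per-item
#' category counts) is attached as attribute `"report"`.
#'
#' @param path File path.
#' @param format `"csv"`, `"xpt"` (SAS transport, needs the foreign package)
#'   or `"auto"` (by extension).
#' @param items Item column names to keep; `NULL` keeps every column.  Use
#'   [nhanes_items()] for NHANES DPQ files.
#' @param missing_codes Values recoded to missing.
#' @param listwise Drop rows with any missing item.
#' @return Tibble of integer responses with attribute `"report"`.
#' @export
read_responses <- function(path, format = c("auto", "csv", "xpt"),
                           items = NULL, missing_codes = c(7, 9),
                           listwise = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xpt$", path, ignore.case = TRUE)) "xpt" else "csv"
  }
  raw <- if (format == "xpt") {
    if (!requireNamespace("foreign", quietly = TRUE)) {
      stop("reading SAS transport files requires the 'foreign' package")
    }
    tibble::as_tibble(foreign::read.xport(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (is.null(items)) items <- names(raw)
  missing_cols <- setdiff(items, names(raw))
  if (length(missing_cols) > 0) {
    stop("item columns not found: ", paste(missing_cols, collapse = ", "))
  }
  x <- raw[items]
  for (col in items) {
    v <- x[[col]]
    v[v %in% missing_codes] <- NA
    bad <- stats::na.omit(setdiff(unique(v), 0:3))
    if (length(bad) > 0) {
      stop(sprintf("column '%s' has out-of-range code(s): %s",
                   col, paste(bad, collapse = ", ")))
    }
    x[[col]] <- as.integer(v)
  }
  rows_read <- nrow(x)
  complete <- stats::complete.cases(x)
  out <- if (listwise) x[complete, , drop = FALSE] else x
  report <- list(
    path = path,
    rows_read = rows_read,
    rows_dropped = if (listwise) sum(!complete) else 0L,
    rows_kept = nrow(out),
    category_counts = purrr::map_dfr(items, function(col) {
      tibble::tibble(item = col,
                     category = 0:3,
                     count = vapply(0:3, function(c) {
                       sum(out[[col]] == c, na.rm = TRUE)
                     }, numeric(1)))
    })
  )
  attr(out, "report") <- report
  out
}

#' Pool several cohort files into one response table
#'
#' Each file is read with [read_responses()] *without* listwise deletion;
#' deletion is applied once on the pooled table so the complete-case count
#' refers to the pooled data.
#'
#' @param paths Character vector of file paths.
#' @param items,missing_codes,format Passed to [read_responses()].
#' @param listwise Drop incomplete rows from the pooled table.
#' @return Tibble with a `cohort` column (file name) plus the item columns;
#'   attribute `"report"` summarizes per-cohort and pooled counts.
#' @export
pool_cohorts <- function(paths, items = nhanes_items(), missing_codes = c(7, 9),
                         format = "auto", listwise = TRUE) {
  parts <- lapply(paths, function(p) {
    d <- read_responses(p, format = format, items = items,
                        missing_codes = missing_codes, listwise = FALSE)
    dplyr::mutate(d, cohort = basename(p), .before = 1)
  })
  pooled <- dplyr::bind_rows(parts)
  complete <- stats::complete.cases(pooled[items])
  out <- if (listwise) pooled[complete, , drop = FALSE] else pooled
  attr(out, "report") <- list(
    cohorts = tibble::tibble(path = paths,
                             rows = vapply(parts, nrow, integer(1))),
    rows_read = nrow(pooled),
    rows_kept = nrow(out)
  )
  out
}

#' Write / read an ordinal response table as CSV
#'
#' Persons as rows, items as columns, integer codes, empty cell = missing.
#' `read_responses()` on the written file round-trips the data and its
#' missingness pattern.
#'
#' @param data Response tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, na = "")
  invisible(path)
}

#' Write a tabulated density as two-column CSV
#'
#' @param grid A [density_grid()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(grid, path) {
  stopifnot(all(c("theta", "density") %in% names(grid)))
  readr::write_csv(grid[c("theta", "density")], path)
  invisible(path)
}

#' Save / load a fitted DC-IRT model as JSON
#'
#' The file holds the item table, curve order, angles and coefficients,
#' log-likelihood, information criteria and fit metadata; [read_model()]
#' rebuilds a working `dcirt_fit` from it.
#'
#' @param fit A `dcirt_fit`.
#' @param path Output path.
#' @return `path` invisibly (`write_model`); a `dcirt_fit` (`read_model`).
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "dcirt_fit"))
  payload <- list(
    package = "dcirt",
    k = fit$k,
    coefficients = fit$curve$m,
    angles = fit$curve$angles,
    items = fit$items,
    loglik = fit$loglik,
    n_params = fit$n_params,
    n_obs = fit$n_obs,
    criteria = fit$criteria,
    converged = fit$converged,
    retried = fit$retried,
    n_iterations = fit$n_iterations,
    em_tolerance = fit$em_tolerance,
    quad = fit$quad
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  curve <- dc_curve(if (p$k >= 2) p$k else 0, p$coefficients,
                    angles = p$angles)
  structure(list(
    items = tibble::as_tibble(p$items),
    curve = curve,
    k = as.integer(p$k),
    loglik = p$loglik,
    n_params = as.integer(p$n_params),
    n_obs = as.integer(p$n_obs),
    criteria = tibble::as_tibble(p$criteria),
    converged = p$converged,
    retried = p$retried,
    n_iterations = p$n_iterations,
    em_tolerance = p$em_tolerance,
    loglik_trace = numeric(0),
    quad = list(nodes = p$quad$nodes, weights = p$quad$weights),
    category_maps = NULL,
    n_dropped = NA_integer_
  ), class = "dcirt_fit")
}
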