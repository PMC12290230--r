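#' Plot the standardized latent density of a fit
#'
#' @param object A `dcirt_fit`.
#' @param theta Evaluation grid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcirt_fit <- function(object, theta = default_theta_grid(), ...) {
  g <- standardized_density(object, theta = theta)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$theta, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "latent trait (standardized)", y = "density",
                  title = sprintf("DC-IRT latent density (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot mean integrated squared error against sample size
#'
#' @param object A `dcirt_sim_study`.
#' @param ... Unused.
#' @return A ggplot (one panel per latent shape, free y scales; line type by
#'   selection criterion; ribbon = 95% CI of the mean).
#' @export
autoplot.dcirt_sim_study <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$n, y = .data$mean_ise,
                               linetype = .data$criterion)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~shape, scales = "free_y") +
    ggplot2::labs(x = "sample size", y = "mean integrated squared error") +
    ggplot2::theme_minimal()
}

#' Plot subsample densities, their pointwise mean and Wald band
#'
#' @param object A `dcirt_subsamples`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcirt_subsamples <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = object$densities,
      ggplot2::aes(x = .data$theta, y = .data$density,
                   group = .data$subsample),
      alpha = 0.3, linewidth = 0.3
    ) +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(x = .data$theta, ymin = .data$lo, ymax = .data$hi),
      alpha = 0.25, fill = "steelblue"
    ) +
    ggplot2::geom_line(
      data = object$band,
      ggplot2::aes(x = .data$theta, y = .data$mean),
      linewidth = 0.8, colour = "steelblue4"
    ) +
    ggplot2::labs(x = "latent trait (standardized)", y = "density") +
    ggplot2::theme_minimal()
}
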