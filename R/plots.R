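# ggplot2 views of the result objects. Figures are presentation; the draws
# and percentile tables are the artifact of record.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a block series
#'
#' Scatter of per-block SNV density against standardized recombination
#' rate, with LOCF-imputed blocks distinguished.
#'
#' @param object A `block_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.block_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$imputed <- if ("locf_applied" %in% names(df)) df$locf_applied else FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$density)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$imputed),
                        alpha = 0.4, size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "standardized recombination rate",
                  y = "SNV density", colour = "LOCF") +
    ggplot2::theme_minimal()
}

#' Plot a regression posterior
#'
#' Marginal posterior densities of the intercept, slope and ARMA
#' parameters, by chain.
#'
#' @param object An `arma_regression`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.arma_regression <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws,
                              cols = -c(".chain", ".draw"),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     colour = factor(.data$.chain))) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(colour = "chain", x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot a context-variance posterior
#'
#' @param object A `variance_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.variance_posterior <- function(object, ...) {
  lbl <- if (is.na(object$direction)) object$kind
         else paste(object$kind, object$direction)
  ggplot2::ggplot(tibble::tibble(value = object$draws),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = bquote(sigma[k]^2 ~ "(" * .(lbl) * ", k =" ~
                               .(object$k) * ")"),
                  y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Compare direction-pair posteriors for strand asymmetry
#'
#' Overlaid posterior densities for a strand-complementary pair of
#' mutation directions.
#'
#' @param post_a,post_b `variance_posterior` objects for the pair.
#' @return A ggplot.
#' @export
plot_strand_pair <- function(post_a, post_b) {
  df <- dplyr::bind_rows(
    tibble::tibble(direction = post_a$direction, value = post_a$draws),
    tibble::tibble(direction = post_b$direction, value = post_b$draws)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   fill = .data$direction)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = bquote(sigma[k]^2), y = "posterior density") +
    ggplot2::theme_minimal()
}
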