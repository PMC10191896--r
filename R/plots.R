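# Plot methods ----------------------------------------------------------------

#' Plot a latent embedding on the (x, z) feature plane
#'
#' @param object A `latent_embedding`.
#' @param colour_by Optional vector (e.g. the kidney-involvement flags),
#'   row-aligned with the embedding, mapped to point colour.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot latent_embedding
#' @export
autoplot.latent_embedding <- function(object, colour_by = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- if (is.null(colour_by)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z))
  } else {
    df$colour_by <- factor(colour_by)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                     colour = .data$colour_by)) +
      ggplot2::labs(colour = NULL)
  }
  p +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "x (latent)", y = "z (latent)",
                  title = "Patients on the (x, z) feature plane")
}

#' Plot an association curve
#'
#' Mirrors the scan figures: statistic against window position (Pattern 1)
#' or z threshold (Pattern 2), the at/above-threshold region in red and the
#' below-threshold region in blue, with the ±1.96 reference band.
#'
#' @param object An `association_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot association_curve
#' @export
autoplot.association_curve <- function(object, ...) {
  long <- tidy(object)
  xlab <- if (identical(attr(object, "pattern"), 2L)) "z-axis threshold" else "window start (x)"
  ggplot2::ggplot(long[long$valid, ],
                  ggplot2::aes(x = .data$position, y = .data$statistic,
                               colour = .data$side)) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(above = "#d62728", below = "#1f77b4")) +
    ggplot2::labs(x = xlab, y = "two-proportion statistic",
                  colour = "region",
                  title = attr(object, "manifestation") %||% "association scan")
}

#' Plot the top contribution rates per feature vector
#'
#' @param object A `contribution_table`.
#' @param k Items shown per feature vector (default 6, as in the headline
#'   report).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot contribution_table
#' @export
autoplot.contribution_table <- function(object, k = 6, ...) {
  top <- top_contributors(object, k)
  top$item_id <- factor(top$item_id, levels = rev(unique(top$item_id)))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$rate, y = .data$item_id)) +
    ggplot2::geom_col(fill = "#4c72b0") +
    ggplot2::facet_wrap(~feature_vector, scales = "free") +
    ggplot2::labs(x = "contribution rate |mean ∂latent/∂item|",
                  y = NULL, title = "Top contributing survey items")
}
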