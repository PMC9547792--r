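#' Plot a Monte Carlo null distribution against the observed statistic
#'
#' Histogram of the null draws with the observed value as a vertical line;
#' the annotation gives the add-one Monte Carlo p-value.
#'
#' @param object A `null_model` from [null_continuous()] or
#'   [null_categorical()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.null_model <- function(object, ...) {
  df <- tibble::tibble(draw = object$null_draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = object$statistic_name, y = "null replicates",
      title = sprintf("Observed %.3f vs null (R = %d), p = %.3g",
                      object$observed, object$R, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot the posterior of the isotopic niche ellipse area
#'
#' @param object An `ellipse_posterior` from [ellipse_area_bayes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ellipse_posterior <- function(object, ...) {
  df <- tibble::tibble(area = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$point_estimate, colour = "black") +
    ggplot2::geom_vline(xintercept = object$credible_interval,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$ml_area, colour = "firebrick",
                        linetype = "dotted") +
    ggplot2::labs(x = expression("ellipse area (‰²)"),
                  y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot an NMDS configuration
#'
#' First two axes of the configuration, optionally coloured by a grouping
#' vector (e.g. lake).
#'
#' @param object An `nmds_result`.
#' @param colour Optional vector (one per point) mapped to colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmds_result <- function(object, colour = NULL, ...) {
  df <- tibble::as_tibble(object$points, rownames = "id")
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), alpha = 0.7) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::labs(
    title = sprintf("NMDS (k = %d), stress = %.3f", object$k, object$stress)) +
    ggplot2::theme_minimal()
}

#' Niche-component scatter against population niche width
#'
#' The classic niche-variation picture: BIC and WIC of each lake against the
#' population niche width of one axis, with least-squares lines, plus the
#' Monte Carlo null expectation of BIC as a dashed line when present. A
#' positive BIC slope is the Niche Variation Hypothesis pattern.
#'
#' @param summary A per-lake summary from [build_lake_summary()].
#' @param axis `"size"` or `"taxa"`.
#' @return A ggplot.
#' @export
plot_niche_components <- function(summary, axis = c("size", "taxa")) {
  axis <- match.arg(axis)
  pnw <- paste0("pnw_", axis)
  long <- tidyr::pivot_longer(
    summary[, c(pnw, paste0(c("wic_", "bic_"), axis))],
    cols = -all_of(pnw), names_to = "component", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data[[pnw]], y = .data$value,
                                          colour = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.7) +
    ggplot2::labs(x = paste0("PNW_", axis), y = "component value") +
    ggplot2::theme_minimal()
  nullcol <- paste0("null_bic_", axis)
  if (nullcol %in% names(summary) && !anyNA(summary[[nullcol]])) {
    df <- summary[, c(pnw, nullcol)]
    names(df) <- c("pnw", "nullbic")
    p <- p + ggplot2::geom_smooth(
      data = df, ggplot2::aes(x = .data$pnw, y = .data$nullbic),
      method = "lm", formula = y ~ x, se = FALSE, colour = "grey30",
      linetype = "dashed", linewidth = 0.6, inherit.aes = FALSE)
  }
  p
}
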