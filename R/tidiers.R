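#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' Tidy a maximum-likelihood tree fit
#'
#' One row per branch: parent and child node, child clade label, and the
#' optimized branch length.
#' @param x A `mito_ml_fit`.
#' @param ... Unused.
#' @export
tidy.mito_ml_fit <- function(x, ...) {
  tree <- x$tree
  tibble::tibble(
    parent = tree$edge[, 1],
    node = tree$edge[, 2],
    clade = vapply(tree$edge[, 2], function(nd) {
      paste(sort(tree$tip.label[tips_under(tree, nd)]), collapse = "+")
    }, character(1)),
    branch_length = tree$edge.length)
}

#' @rdname tidy.mito_ml_fit
#' @export
glance.mito_ml_fit <- function(x, ...) {
  tibble::tibble(lnL = x$lnL, alpha = x$model$alpha,
                 ts_tv = x$model$ts_tv,
                 n_taxa = length(x$tree$tip.label),
                 converged = x$converged, sweeps = x$sweeps)
}

#' Tidy / glance a molecular-clock likelihood-ratio test
#' @param x A `mito_clock_lrt`.
#' @param ... Unused.
#' @export
glance.mito_clock_lrt <- function(x, ...) {
  tibble::tibble(lnL_free = x$lnL_free, lnL_clock = x$lnL_clock,
                 statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @rdname glance.mito_clock_lrt
#' @export
tidy.mito_clock_lrt <- function(x, ...) glance.mito_clock_lrt(x)

#' Tidy / glance a calibrated rate estimate
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble::tibble(rate = x$rate, depth = x$depth, age_years = x$age_years,
                 method = x$method)
}

#' @rdname glance.rate_estimate
#' @export
tidy.rate_estimate <- function(x, ...) glance.rate_estimate(x)

#' Plot an event catalogue along the reference genome
#'
#' Event positions by kind, optionally shaded by annotated regions.
#' @param events Event tibble (from [call_events()] /
#'   [merge_micro_events()]).
#' @param genome Optional [annotated_genome()] for region shading.
#' @return A ggplot object.
#' @export
plot_events <- function(events, genome = NULL) {
  p <- ggplot2::ggplot(events,
                       ggplot2::aes(x = .data$ref_start, y = .data$kind,
                                    colour = .data$kind)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "reference position (bp)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(genome) && nrow(genome$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = genome$regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$kind),
      inherit.aes = FALSE, alpha = 0.12)
  }
  p
}

#' Plot a pairwise distance matrix as a heatmap
#' @param dists Output of [distance_table()].
#' @param value Distance column to show.
#' @return A ggplot object.
#' @export
plot_distances <- function(dists, value = "tn93_gamma") {
  both <- dplyr::bind_rows(
    dists,
    dplyr::rename(dists, taxon_a = "taxon_b", taxon_b = "taxon_a"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b,
                                     fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.4f", .data[[value]])), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal()
}

#' Plot a dated chronology
#' @param chronology Output of [date_nodes()].
#' @return A ggplot object: node ages with clade labels.
#' @export
plot_chronology <- function(chronology) {
  ggplot2::ggplot(chronology,
                  ggplot2::aes(x = .data$age_years,
                               y = stats::reorder(.data$clade,
                                                  .data$age_years))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "age (years before present)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mito_ml_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch_length,
                                   y = stats::reorder(.data$clade,
                                                      .data$branch_length))) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "branch length (substitutions/site)", y = NULL) +
    ggplot2::theme_minimal()
}
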