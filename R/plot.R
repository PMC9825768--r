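#' Trajectory line plots
#'
#' Faceted line plots of the six per-step summary statistics (threshold,
#' number of subgraphs, triples, average size, average density, relative
#' maximum size) against trajectory step, with the smallest–largest optimum
#' marked by a dashed vertical line. This is the static counterpart of the
#' interactive threshold-selection strip under a percolation visualization.
#'
#' @param stats Per-step statistics table (from [tidy()] of a `percolation`).
#' @param optimal Optional [optimal_threshold()] result to mark.
#' @return A ggplot object.
#' @export
plot_trajectory_stats <- function(stats, optimal = NULL) {
  stats <- as_tibble(stats)
  panels <- c("threshold", "n_subgraphs", "n_triples", "avg_size",
              "avg_density", "rel_max_size")
  long <- tidyr::pivot_longer(
    dplyr::select(stats, "step_index", dplyr::all_of(panels)),
    -"step_index", names_to = "statistic", values_to = "value")
  long$statistic <- factor(long$statistic, levels = panels)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$step_index, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue4", linewidth = 0.4) +
    ggplot2::geom_point(size = 0.4, color = "steelblue4") +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y",
                        strip.position = "left") +
    ggplot2::labs(x = "percolation step (edges admitted strongest first)",
                  y = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(strip.placement = "outside")
  if (!is.null(optimal)) {
    p <- p + ggplot2::geom_vline(xintercept = optimal$step_index,
                                 linetype = "dashed", color = "firebrick") +
      ggplot2::labs(subtitle = sprintf(
        "smallest-largest optimum: threshold %g (step %d)",
        optimal$threshold, optimal$step_index))
  }
  p
}

#' @describeIn plot_trajectory_stats `autoplot()` method for `percolation`
#'   objects: computes the statistics and the optimum, then draws the
#'   trajectory line plots.
#' @param object A `percolation` object.
#' @param mark_optimal Mark the smallest–largest optimum if it exists.
#' @param ... Unused.
#' @export
autoplot.percolation <- function(object, mark_optimal = TRUE, ...) {
  opt <- if (mark_optimal) {
    tryCatch(optimal_threshold(object), error = function(e) NULL)
  }
  plot_trajectory_stats(tidy(object), opt)
}

#' Per-subgraph measures plot for a snapshot
#'
#' One point per isolated subgraph at the snapshot's threshold, showing the
#' three per-subgraph measures: member count (x), mean internal strength
#' (y) and density (point size).
#'
#' @param object A `subgraph_snapshot` from [subgraphs_at()] /
#'   [subgraphs_at_step()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subgraph_snapshot <- function(object, ...) {
  sub <- object$subgraphs
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$size, y = .data$mean_strength,
                                    size = .data$density)) +
    ggplot2::geom_point(alpha = 0.7, color = "steelblue4") +
    ggplot2::scale_size_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("%d isolated subgraphs at threshold %g (%d nodes unclustered)",
                      nrow(sub), object$threshold, length(object$unclustered)),
      x = "subgraph size (nodes)", y = "mean internal strength",
      size = "density") +
    ggplot2::theme_minimal(base_size = 10)
}
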