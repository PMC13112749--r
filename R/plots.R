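# ggplot2 views of the main result types.

#' Barcode rank (knee) plot
#'
#' @param x A [find_knees()] result or a [rank_barcodes()] curve.
#' @return A ggplot.
#' @export
plot_barcode_ranks <- function(x) {
  curve <- if (inherits(x, "knee_call")) x$barcodes else mutate(x, label = "barcode")
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$rank, y = pmax(.data$count, 0.5),
                                           colour = .data$label)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "unique valid pairs", colour = NULL) +
    ggplot2::theme_classic()
  if (inherits(x, "knee_call") && x$found) {
    p <- p + ggplot2::geom_vline(xintercept = c(x$knee1, x$knee2),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Contact distance-decay plot
#'
#' @param curve A [distance_decay()] table.
#' @param by Optional grouping column for one line per group.
#' @return A ggplot.
#' @export
plot_decay <- function(curve, by = NULL) {
  aes <- if (is.null(by)) {
    ggplot2::aes(x = .data$mid, y = .data$density)
  } else {
    ggplot2::aes(x = .data$mid, y = .data$density, group = .data[[by]])
  }
  ggplot2::ggplot(filter(curve, .data$n > 0), aes) +
    ggplot2::geom_line(alpha = if (is.null(by)) 1 else 0.3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic separation (bp)", y = "contact density") +
    ggplot2::theme_classic()
}

#' @exportS3Method ggplot2::autoplot
autoplot.saturation_fit <- function(object, ...) {
  grid <- tibble(depth = exp(seq(log(min(object$data$X)),
                                 log(max(object$data$X)), length.out = 100)))
  grid$fit <- predict(object, grid$depth)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$X, y = .data$Y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$depth, y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$bmax, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sequencing depth", y = "unique valid pairs",
                  subtitle = sprintf("Bmax = %.3g, Kd = %.3g", object$bmax, object$kd)) +
    ggplot2::theme_classic()
}

#' Insulation track with called boundaries
#'
#' @param track [insulation_scores()] output (one chromosome recommended).
#' @param boundaries Optional [call_boundaries()] output.
#' @return A ggplot.
#' @export
plot_insulation <- function(track, boundaries = NULL) {
  p <- ggplot2::ggplot(filter(track, !is.na(.data$score)),
                       ggplot2::aes(x = .data$start / 1e6, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "insulation score") +
    ggplot2::theme_classic()
  if (!is.null(boundaries) && nrow(boundaries) > 0) {
    p <- p + ggplot2::geom_vline(data = boundaries,
                                 ggplot2::aes(xintercept = .data$start / 1e6),
                                 colour = "firebrick", linetype = "dashed",
                                 linewidth = 0.3)
  }
  p
}

#' Aggregate peak analysis heat map
#'
#' @param x An [apa()] result.
#' @return A ggplot (enrichment annotated at the maximal-distance corner).
#' @export
plot_apa <- function(x) {
  k <- x$half_window
  df <- purrr::map_dfr(seq_len(2 * k + 1), function(a) {
    tibble(i = a - k - 1, j = (-k):k, value = x$window[a, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = -.data$i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "downstream anchor offset (bins)",
                  y = "upstream anchor offset (bins)",
                  subtitle = sprintf("enrichment = %.2f", x$enrichment)) +
    ggplot2::theme_classic()
}

#' Cumulative insulation-score distributions of the two chromatin states
#'
#' @param scores Long per-cell ROI insulation scores (`cell_id`, `score`).
#' @param clustering A [cluster_states()] result.
#' @return A ggplot of the two empirical CDFs.
#' @export
plot_melting_cdf <- function(scores, clustering) {
  cells <- if (inherits(clustering, "state_clustering")) clustering$cells else clustering
  df <- scores |>
    left_join(select(cells, "cell_id", "state"), by = "cell_id") |>
    filter(!is.na(.data$state), !is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, colour = .data$state)) +
    ggplot2::stat_ecdf(linewidth = 0.6) +
    ggplot2::labs(x = "single-cell insulation score", y = "cumulative probability",
                  colour = NULL) +
    ggplot2::theme_classic()
}
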