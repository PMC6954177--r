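# ggplot2 views of the main result types. Each function returns a
# ggplot object so callers can restyle or facet further.

#' Plot per-sample diversity metrics across timepoints
#'
#' @param metrics Output of [repertoire_metrics()].
#' @param metric Column to plot (default the downsampled entropy).
#' @return A ggplot object.
#' @export
plot_diversity <- function(metrics, metric = "median_downsampled_entropy") {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$timepoint, y = .data[[metric]],
                               group = .data$patient_id,
                               colour = .data$patient_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = metric, colour = "patient") +
    ggplot2::theme_minimal()
}

#' Plot rank trajectories of tracked clonotypes
#'
#' Rank is drawn on a reversed axis so dominant clones sit on top; the
#' rank cap (absent clonotypes) forms the bottom row.
#'
#' @param tracks Output of [track_clonotype_ranks()].
#' @return A ggplot object.
#' @export
plot_rank_tracks <- function(tracks) {
  ggplot2::ggplot(tracks,
                  ggplot2::aes(x = .data$timepoint, y = .data$rank,
                               group = .data$clonotype_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "rank (capped)") +
    ggplot2::theme_minimal()
}

#' Plot absolute clone-count tracks by kinetic pattern
#'
#' @param x A `clonekin_tracks` object from [clone_kinetics()].
#' @return A ggplot object (log10 count axis, one panel per pattern).
#' @export
plot_clone_kinetics <- function(x) {
  df <- dplyr::left_join(x$tracks, x$patterns, by = "clonotype_id")
  df <- df[df$abs_count > 0, , drop = FALSE]
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$timepoint, y = .data$abs_count,
                               group = .data$clonotype_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::labs(x = NULL, y = "absolute clone count (cells/µl)") +
    ggplot2::theme_minimal()
}

#' Ribbon plot of integration-site clone contributions per sample
#'
#' Clones below the ribbon threshold are pooled into a gray `other`
#' ribbon, as in standard integration-site contribution plots.
#'
#' @param freqs Output of [clone_frequencies()].
#' @return A ggplot object.
#' @export
plot_clone_ribbons <- function(freqs) {
  df <- freqs
  df$clone <- ifelse(df$ribbon, df$clone_id, "other")
  df <- df |>
    dplyr::group_by(.data$sample, .data$clone) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop")
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$sample, y = .data$frequency,
                               fill = .data$clone, group = .data$clone)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "clone frequency", fill = "clone") +
    ggplot2::theme_minimal()
}

#' @describeIn clonotype_fate_test Volcano-style view of the fate test
#'   (early-vs-IP proportion ratio against adjusted p-value).
#' @param object A `clonekin_fate` object.
#' @export
autoplot.clonekin_fate <- function(object, ...) {
  df <- object$results
  eps <- 0.5
  df$log2_ratio <- log2(((df$early_count + eps) / df$early_total) /
                          ((df$ip_count + eps) / df$ip_total))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$log2_ratio,
                               y = -log10(pmax(.data$q_value, 1e-300)),
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(IRF = "#d7301f", DRF = "#0570b0",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "log2 (early / IP) proportion ratio",
                  y = "-log10 q", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
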