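#' Box-and-jitter plot of (normalized) group scores
#'
#' The figure-style summary used for each compartment: one box per age per
#' genotype, medians with interquartile boxes, individual sampling units
#' jittered on top.
#'
#' @param scores Tibble with `age_months`, `genotype` and a value column.
#' @param value Column to plot (default `normalized`).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_group_scores <- function(scores, value = "normalized", title = NULL) {
  ggplot2::ggplot(scores, ggplot2::aes(
    x = factor(.data$age_months), y = .data[[value]],
    fill = .data$genotype)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.12, dodge.width = 0.8), size = 0.7, alpha = 0.6) +
    ggplot2::labs(x = "age (months)", y = value, title = title) +
    ggplot2::theme_classic()
}

#' Plot the compartment summaries of an analysis
#'
#' @param object An `ist_analysis` from [ist_analyze()].
#' @param ... Unused.
#' @return A ggplot object faceted by compartment.
#' @method autoplot ist_analysis
#' @export
autoplot.ist_analysis <- function(object, ...) {
  plot_group_scores(object$normalized) +
    ggplot2::facet_wrap(~compartment, scales = "free_y")
}

#' Plot a gel-lane profile with its baseline and band window
#'
#' @param lane An [lane_profile()].
#' @return A ggplot object.
#' @export
plot_lane_profile <- function(lane) {
  w <- lane$band_window
  width <- w[2] - w[1] + 1L
  k <- min(3L * width, length(lane$intensity))
  if (k %% 2L == 0L) k <- k - 1L
  df <- tibble::tibble(
    position = seq_along(lane$intensity),
    intensity = lane$intensity,
    baseline = lane_baseline(lane$intensity, k))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$intensity)) +
    ggplot2::annotate("rect", xmin = w[1], xmax = w[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), linetype = 2,
                       colour = "grey40") +
    ggplot2::labs(x = "lane position", y = "intensity (a.u.)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
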