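# ggplot2 views of the main result types.

#' Plot a reads-per-tag histogram with its threshold
#'
#' Shows raw and smoothed correct-tag proportions per 2-read bin, the
#' proportion criterion, and (optionally) the derived threshold M.
#'
#' @param object A [tag_histogram()].
#' @param M Optional threshold in reads, drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.noir_histogram <- function(object, M = NULL, ...) {
  df <- dplyr::filter(as_tibble(object), .data$n_total > 0L)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$reads_lo)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop_raw),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prop_smooth),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = attr(object, "min_prop"),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reads per tag (bin lower bound)",
                  y = "proportion of correct-length tags",
                  title = "Erroneous-tag threshold derivation")
  if (!is.null(M)) {
    p <- p + ggplot2::geom_vline(xintercept = M, colour = "steelblue")
  }
  p
}

#' Plot region-level Poisson calls
#'
#' P per region on a log scale against the verdict threshold, the
#' region-level analogue of a per-sample variant-call plot.
#'
#' @param object A `noir_calls` table ([call_regions()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.noir_calls <- function(object, ...) {
  df <- tidy(object)
  df$p_plot <- pmax(df$p_value, 1e-300)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_id, y = .data$p_plot,
                                   colour = .data$variant_positive)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Poisson tail probability P",
                  colour = "variant-positive")
}

#' Saturation curve of accepted molecule counts
#'
#' @param df A tibble with columns `depth` (reads used) and `accepted`
#'   (molecule count), optionally `rule` to compare thresholding rules.
#' @return A ggplot object.
#' @export
plot_saturation <- function(df) {
  aes <- if ("rule" %in% names(df)) {
    ggplot2::aes(x = .data$depth, y = .data$accepted, colour = .data$rule)
  } else {
    ggplot2::aes(x = .data$depth, y = .data$accepted)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "reads used", y = "accepted tag families")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
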