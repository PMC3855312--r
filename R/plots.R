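#' Plot a stability selection
#'
#' Bar chart of each method's high-similarity rate p_hat, filled by whether
#' the iterative chi-square test kept the method in the stable set; the
#' dashed line marks the pooled rate of the stable methods.
#'
#' @param object A `stability_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_selection <- function(object, ...) {
  df <- object$methods
  df$method <- stats::reorder(df$method, df$p_hat)
  pooled <- mean(df$p_hat[df$stable])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$p_hat,
                                   fill = .data$stable)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = pooled, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = bquote(hat(p) ~ "= rate of similarity" >= .(object$s0)),
      fill = "stable",
      title = sprintf("Stable class-discovery methods (k = %d, %s)",
                      object$k, object$coefficient)) +
    ggplot2::theme_minimal()
}

#' Plot per-pair stability similarities
#'
#' Distribution of the M pairwise-solution similarities of one or more
#' stability records, with the threshold s0 drawn when provided.
#'
#' @param records A `stability_record` or list of them.
#' @param s0 Optional similarity threshold to mark.
#' @return A ggplot object.
#' @export
plot_stability_distribution <- function(records, s0 = NULL) {
  if (inherits(records, "stability_record")) records <- list(records)
  df <- dplyr::bind_rows(lapply(records, tidy))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                        y = .data$similarity)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "partition agreement") +
    ggplot2::theme_minimal()
  if (!is.null(s0)) {
    p <- p + ggplot2::geom_hline(yintercept = s0, linetype = "dashed")
  }
  p
}

#' Plot minimal regions along the genome
#'
#' One horizontal segment per minimal region at its probe interval, faceted
#' by chromosome and coloured by alteration type; segment height reflects
#' support size.
#'
#' @param object A `cgh_mrset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgh_mrset <- function(object, ...) {
  df <- as_tibble(object)
  df$alteration <- factor(df$alteration, levels = c(-1, 1, 2),
                          labels = c("loss", "gain", "amplification"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_pos,
                                   xend = .data$end_pos,
                                   y = .data$n_support,
                                   yend = .data$n_support,
                                   colour = .data$alteration)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "support size",
                  colour = "alteration") +
    ggplot2::theme_minimal()
}

#' Plot stable-method component frequencies
#'
#' Bar chart of how often each representation, measure and algorithm occurs
#' among the methods declared stable across the benchmark grid.
#'
#' @param object A `cgh_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgh_benchmark <- function(object, ...) {
  df <- stable_frequencies(object$grid, character(0))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$value,
                                                      .data$n_stable),
                                   y = .data$n_stable)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "occurrences among stable methods") +
    ggplot2::theme_minimal()
}
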