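#' Hockey-stick plot of super-enhancer calls
#'
#' Signal versus ascending rank with the cutoff marked; the classic
#' rank-ordering diagnostic separating typical enhancers from the
#' high-signal elbow.
#'
#' @param object An `se_calls` tibble from [call_super_enhancers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.se_calls <- function(object, ...) {
  df <- as_tibble(object)
  df$ascending_rank <- nrow(df) - df$rank + 1L
  cutoff <- attr(object, "cutoff")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ascending_rank, y = .data$signal, color = .data$is_super
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
      name = "super-enhancer"
    ) +
    ggplot2::labs(
      x = "enhancer rank (ascending signal)",
      y = "normalized H3K27ac signal"
    ) +
    ggplot2::theme_minimal()
  if (!is.na(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Funnel plot of a prioritization cascade
#'
#' Number of lncRNAs surviving each funnel step, in cascade order.
#'
#' @param object A `cascade_report` from [run_cascade()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cascade_report <- function(object, ...) {
  steps <- object$steps
  steps$step <- factor(steps$step, levels = rev(steps$step))
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$n_lncrnas, y = .data$step)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_lncrnas), hjust = -0.2, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "lncRNAs retained", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of super-enhancer dynamics
#'
#' Counts of acquired, retained and lost regions per stage from
#' [classify_se_dynamics()].
#'
#' @param dynamics Dynamics tibble (`stage`, `status`).
#' @param stage_order Optional character vector fixing the stage order.
#' @return A ggplot object.
#' @export
plot_se_dynamics <- function(dynamics, stage_order = NULL) {
  dynamics <- as_tibble(dynamics)
  if (!is.null(stage_order)) {
    dynamics$stage <- factor(dynamics$stage, levels = stage_order)
  }
  counts <- dplyr::count(dynamics, .data$stage, .data$status)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = .data$stage, y = .data$n, fill = .data$status
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "super-enhancers", fill = NULL) +
    ggplot2::theme_minimal()
}
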