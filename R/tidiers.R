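#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods
#'
#' broom-style summaries for the package's result objects.
#'
#' @param x A `cascade_report` or `anova_tukey` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @return `tidy.cascade_report()`: the per-step funnel counts.
#' @export
tidy.cascade_report <- function(x, ...) {
  x$steps
}

#' @rdname tidiers
#' @return `glance.cascade_report()`: one row with input size, pair counts
#'   and shortlist size.
#' @export
glance.cascade_report <- function(x, ...) {
  s <- setNames(x$steps$n_lncrnas, x$steps$step)
  tibble(
    n_input = s[["input"]], n_differential = s[["differential"]],
    n_paired = s[["paired"]], n_annotated = s[["annotated"]],
    n_correlated = s[["correlated"]], n_trend = s[["trend_concordant"]],
    n_top_differential = s[["top_differential"]],
    n_shortlist = s[["shortlist"]]
  )
}

#' @rdname tidiers
#' @return `tidy.anova_tukey()`: pairwise comparisons with Tukey-adjusted
#'   p-values.
#' @export
tidy.anova_tukey <- function(x, ...) {
  x$pairwise
}

#' @rdname tidiers
#' @return `glance.anova_tukey()`: the overall F-test.
#' @export
glance.anova_tukey <- function(x, ...) {
  x$overall
}
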