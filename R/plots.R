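#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a peristimulus time histogram
#'
#' @param object A `pfc_psth` tibble from [compute_psth()].
#' @param ... Unused.
#' @return A ggplot: smoothed firing rate versus time.
#' @export
autoplot.pfc_psth <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$rate_hz)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = "time (ms)", y = "rate (Hz)",
      title = unique(object$population)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the 3x3 inverted-U grid
#'
#' Delay-period preferred vs non-preferred rates per condition, faceted over
#' the DA x NE grid; the optimal/optimal cell should show the largest
#' separation (the inverted-U peak).
#'
#' @param object A `pfc_inverted_u` tibble from [inverted_u_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfc_inverted_u <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("rate_pref", "rate_npref"),
    names_to = "column", values_to = "rate_hz"
  )
  long$column <- ifelse(long$column == "rate_pref", "preferred", "non-preferred")
  long$da <- factor(long$da, levels = nm_levels())
  long$ne <- factor(long$ne, levels = nm_levels())
  ggplot2::ggplot(long, ggplot2::aes(.data$column, .data$rate_hz,
    fill = .data$column
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$da), cols = ggplot2::vars(.data$ne),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = NULL, y = "delay rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a behavioral summary grid
#'
#' Stacked correct/incorrect/null percentages per (DA, NE) condition.
#'
#' @param summary Behavior summary tibble from [summarize_behavior()].
#' @return A ggplot.
#' @export
plot_behavior_grid <- function(summary) {
  long <- tidyr::pivot_longer(
    summary, c("pct_correct", "pct_incorrect", "pct_null"),
    names_to = "outcome", values_to = "pct"
  )
  long$outcome <- sub("pct_", "", long$outcome)
  long$da <- factor(long$da, levels = nm_levels())
  long$ne <- factor(long$ne, levels = nm_levels())
  ggplot2::ggplot(long, ggplot2::aes(.data$ne, .data$pct, fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$da), labeller = ggplot2::label_both) +
    ggplot2::labs(x = "NE level", y = "% of trials", fill = NULL) +
    ggplot2::theme_minimal()
}
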