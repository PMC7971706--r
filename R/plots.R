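#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot local information measures along a scan path
#'
#' Time courses of LAIS and LGTE per fixation; a horizontal line marks
#' zero for LAIS (negative values are misinformative pasts).
#'
#' @param object A `"gaze_local_measures"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gaze_local_measures
#' @export
autoplot.gaze_local_measures <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "lais", "lgte")],
    cols = c("lais", "lgte"), names_to = "measure", values_to = "bits"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$bits,
                                     colour = .data$measure)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE, alpha = 0.8) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "fixation index t", y = "bits") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot the greedy past-state selection
#'
#' Per-step winning candidate lag, its conditional mutual information
#' and the 95% quantile of the surrogate maxima it was tested against.
#'
#' @param object A `"gaze_embedding"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gaze_embedding
#' @export
autoplot.gaze_embedding <- function(object, ...) {
  steps <- object$steps
  steps$label <- sprintf("lag %d", steps$lag)
  ggplot2::ggplot(steps, ggplot2::aes(x = factor(.data$step),
                                      y = .data$cmi,
                                      fill = .data$selected)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$surrogate_max_q95),
                        shape = 95, size = 8, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.6,
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "greedy step", y = "CMI (bits)",
                  fill = "selected",
                  caption = "dash: 95% quantile of surrogate maxima") +
    ggplot2::theme_minimal()
}

#' Plot normalized period summaries
#'
#' Mean normalized LAIS and LGTE per trial period, averaged over trials
#' within participant, with one line per participant.
#'
#' @param summaries Period summaries from [analyze_participant()] or
#'   [analyze_cohort()].
#' @return A ggplot object.
#' @export
plot_period_summaries <- function(summaries) {
  long <- summaries |>
    tidyr::pivot_longer(cols = c("normalized_lais", "normalized_lgte"),
                        names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$participant, .data$period, .data$measure) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$value,
                                     group = .data$participant)) +
    ggplot2::geom_line(alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean / mean joint entropy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
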