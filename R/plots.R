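# ggplot2 views of the evaluation outputs.

#' Plot performance against the reliability-index cutoff
#'
#' Accuracy (and optionally MCC) of the predictions retained at each
#' reliability-index cutoff, with the retained coverage on a companion axis
#' scale, mirroring the usual accuracy-versus-confidence trade-off view.
#'
#' @param strata Tibble from [ri_stratified()].
#' @return A ggplot object.
#' @export
plot_ri_performance <- function(strata) {
  long <- tidyr::pivot_longer(
    select(strata, "ri_min", "q_tot", "coverage"),
    cols = c("q_tot", "coverage"),
    names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = c("q_tot", "coverage"),
                         labels = c("Overall accuracy", "Coverage"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ri_min, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = unique(long$ri_min)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Minimum reliability index", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the disease-probability distribution by true class
#'
#' @param predictions Prediction tibble (`o_d`).
#' @param labels True labels.
#' @return A ggplot object.
#' @export
plot_probability_by_class <- function(predictions, labels) {
  df <- tibble(o_d = predictions$o_d, label = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$o_d, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.55) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "O(D), probability of the disease class",
                  y = "Variants", fill = NULL) +
    ggplot2::theme_minimal()
}
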