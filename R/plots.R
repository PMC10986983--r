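# ggplot2 displays for the two concordance result types.

#' Histogram of per-vial genus richness differences
#'
#' Morphology minus metabarcoding, one bar height per difference value; the
#' display used to compare method richness across site visits.
#'
#' @param object A `vial_concordance` from [vial_agreement()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot vial_concordance
#' @export
autoplot.vial_concordance <- function(object, ...) {
  pv <- object$per_vial
  ggplot2::ggplot(pv, ggplot2::aes(x = .data$richness_diff)) +
    ggplot2::geom_bar(fill = "#e08214") +
    ggplot2::scale_x_continuous(breaks = scales_breaks(pv$richness_diff)) +
    ggplot2::labs(
      x = "Genera detected: morphology - metabarcoding",
      y = "Composite vials",
      title = "Per-vial genus richness difference between methods") +
    ggplot2::theme_minimal()
}

scales_breaks <- function(x) seq(min(x), max(x))

#' Leg proportion by metabarcoding detection outcome
#'
#' Box plot of the proportion of a vial's legs belonging to each genus,
#' split by whether metabarcoding detected that genus in the vial.
#'
#' @param props Tibble with `proportion` and logical `detected` (the input
#'   of [proportion_detection_test()]).
#' @return A ggplot object.
#' @export
plot_detection_proportions <- function(props) {
  props |>
    dplyr::mutate(outcome = ifelse(.data$detected, "Detected",
                                   "Not detected")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$outcome, y = .data$proportion)) +
    ggplot2::geom_boxplot(fill = "#80b1d3") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "Proportion of legs in vial",
                  title = "Tissue proportion vs metabarcoding detection") +
    ggplot2::theme_minimal()
}
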