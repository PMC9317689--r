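#' Plot expected gains and coefficients of one evaluated index
#'
#' Bar chart of the expected genetic gain per trait, in the spirit of the
#' gain comparisons breeders draw for LPSI vs. RLPSI runs.
#'
#' @param object an `index_evaluation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.index_evaluation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$expected_gain)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      title = object$scenario,
      subtitle = sprintf("R = %.2f, rho_HI = %.2f, k = %.2f",
                         object$R, object$rho_HI, object$k),
      x = NULL, y = "expected genetic gain (trait units)") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of selection parameters over a weight sweep
#'
#' Boxplots of a chosen selection parameter across the levels of one weight
#' factor, split by scenario — the picture behind ANOVA-based weight
#' screening.
#'
#' @param object a `sweep_result` from [evaluate_grid()].
#' @param response column to display (default `"response"`).
#' @param factor weight column used on the x axis.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sweep_result <- function(object, response = "response",
                                  factor = NULL, ...) {
  factor <- factor %||% grep("^w_", names(object), value = TRUE)[1]
  d <- dplyr::mutate(object, .lvl = base::factor(.data[[factor]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.lvl, y = .data[[response]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::facet_wrap(~scenario, scales = "free_y") +
    ggplot2::labs(x = factor, y = response) +
    ggplot2::theme_minimal()
}

#' Plot genotype membership across selection contexts
#'
#' Tile map of which genotypes were selected in which
#' scenario x weight x dataset context; consensus genotypes are ordered
#' first.
#'
#' @param object a `consistency_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.consistency_report <- function(object, ...) {
  d <- object$membership |>
    dplyr::mutate(context = paste(.data$dataset, .data$scenario,
                                  .data$weight, sep = " | "))
  ord <- c(object$consensus, setdiff(object$union, object$consensus))
  d$genotype <- base::factor(d$genotype, levels = rev(ord))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$genotype)) +
    ggplot2::geom_tile(fill = "darkgreen") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d selected, %d consensus",
                                  length(object$union),
                                  length(object$consensus))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   axis.text.y = ggplot2::element_text(size = 5))
}
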