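#' Plot a fitted map as scaffolds drawn to genetic length
#'
#' Each scaffold is a horizontal segment whose length is its genetic map
#' length (cM), colored by orientation (forward green, reverse red), laid
#' end to end in map order with junction distances between them.
#'
#' @param object A `map_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.map_fit <- function(object, ...) {
  td <- tidy(object)
  sc <- td |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(start_cm = min(.data$cum_cm),
                     end_cm = max(.data$cum_cm),
                     orientation = dplyr::first(.data$orientation),
                     .groups = "drop") |>
    dplyr::arrange(.data$start_cm)
  ggplot2::ggplot(sc) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_cm, xend = .data$end_cm, y = 0, yend = 0,
                   color = .data$orientation),
      linewidth = 4, lineend = "butt") +
    ggplot2::scale_color_manual(values = c("+" = "forestgreen", "-" = "firebrick")) +
    ggplot2::labs(x = "map position (cM)", y = NULL,
                  title = sprintf("lnLk = %.1f, %.1f cM", object$loglik,
                                  max(sc$end_cm))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
}

#' Plot the genetic-algorithm search trace
#'
#' Best log-likelihood per generation; elitism makes the curve
#' non-decreasing.
#'
#' @param object A `ga_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ga_search <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$generation, y = .data$best_loglik)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best lnLk") +
    ggplot2::theme_minimal()
}

#' Compare two maps scaffold by scaffold
#'
#' Draws both maps to genetic length with connecting lines between the
#' positions of each shared scaffold -- reversed blocks show as crossing
#' lines.
#'
#' @param fit_a,fit_b `map_fit` objects.
#' @param labels Length-2 labels for the two maps.
#' @return A ggplot.
#' @export
plot_map_comparison <- function(fit_a, fit_b, labels = c("map A", "map B")) {
  one <- function(fit, y) {
    tidy(fit) |>
      dplyr::group_by(.data$scaffold) |>
      dplyr::summarise(start_cm = min(.data$cum_cm),
                       end_cm = max(.data$cum_cm),
                       orientation = dplyr::first(.data$orientation),
                       .groups = "drop") |>
      dplyr::mutate(y = y, mid = (.data$start_cm + .data$end_cm) / 2)
  }
  a <- one(fit_a, 1); b <- one(fit_b, 0)
  link <- dplyr::inner_join(a, b, by = "scaffold", suffix = c("_a", "_b"))
  seg <- dplyr::bind_rows(a, b)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = link,
      ggplot2::aes(x = .data$mid_a, xend = .data$mid_b, y = 0.95, yend = 0.05),
      color = "grey70", linewidth = 0.3) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start_cm, xend = .data$end_cm,
                   y = .data$y, yend = .data$y, color = .data$orientation),
      linewidth = 4) +
    ggplot2::scale_color_manual(values = c("+" = "forestgreen", "-" = "firebrick")) +
    ggplot2::scale_y_continuous(breaks = c(0, 1), labels = rev(labels)) +
    ggplot2::labs(x = "map position (cM)", y = NULL) +
    ggplot2::theme_minimal()
}
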