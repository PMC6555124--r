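# ggplot2 views of histories, reports, and corpus statistics.

#' Plot the training history of a fitted model
#'
#' Loss and accuracy (and validation curves when recorded) per epoch.
#'
#' @param object A `"venue_cnn"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.venue_cnn <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(
      ~ ifelse(grepl("loss", metric), "loss", "accuracy"),
      scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Top-N accuracy as a step curve, split by journal-size stratum when the
#' report carries one.
#'
#' @param object A `"venue_eval"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.venue_eval <- function(object, ...) {
  if (!is.null(object$strata)) {
    d <- object$strata |>
      tidyr::pivot_longer(dplyr::starts_with("acc_at_"),
                          names_to = "n", values_to = "accuracy",
                          names_prefix = "acc_at_") |>
      dplyr::mutate(n = as.integer(.data$n))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$accuracy,
                                         colour = .data$size_bin))
  } else {
    p <- ggplot2::ggplot(object$accuracy,
                         ggplot2::aes(x = .data$n, y = .data$accuracy))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "list length N", y = "acc@N", colour = "journal size",
                  title = "Top-N recommendation accuracy") +
    ggplot2::theme_minimal()
}

#' Plot an abstract-length histogram
#'
#' @param object A `"length_histogram"` tibble from [length_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.length_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "abstract length (words)", y = "abstracts",
                  title = "Abstract length distribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
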