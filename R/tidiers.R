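# broom-style tidiers for fitted models and evaluation reports.

#' Tidy the training history of a fitted model
#'
#' @param x A `"venue_cnn"`.
#' @param ... Unused.
#' @return Long tibble with columns `epoch`, `metric`, `value`.
#' @export
tidy.venue_cnn <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a fitted model
#'
#' @param x A `"venue_cnn"`.
#' @param ... Unused.
#' @return Tibble with `n_classes`, `n_parameters`, `epochs`, `final_loss`,
#'   `final_accuracy`.
#' @export
glance.venue_cnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    n_classes = x$config$n_classes,
    n_parameters = sum(purrr::map_int(x$params, length)),
    epochs = last$epoch,
    final_loss = last$loss,
    final_accuracy = last$accuracy
  )
}

#' Tidy an evaluation report
#'
#' @param x A `"venue_eval"`.
#' @param ... Unused.
#' @return Long tibble with columns `n`, `metric`, `value` covering accuracy
#'   and the macro/micro averages.
#' @export
tidy.venue_eval <- function(x, ...) {
  acc <- dplyr::transmute(x$accuracy, n = .data$n, metric = "accuracy",
                          value = .data$accuracy)
  avg <- x$averages |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "which", values_to = "value") |>
    dplyr::transmute(n = .data$n,
                     metric = paste(.data$average, .data$which, sep = "_"),
                     value = .data$value)
  dplyr::bind_rows(acc, avg)
}

#' One-row summary of an evaluation report
#'
#' @param x A `"venue_eval"`.
#' @param ... Unused.
#' @return Tibble with `n_samples` and one `acc_at_<N>` column per evaluated
#'   list length.
#' @export
glance.venue_eval <- function(x, ...) {
  out <- tibble::tibble(n_samples = x$n_samples)
  for (i in seq_len(nrow(x$accuracy))) {
    out[[paste0("acc_at_", x$accuracy$n[i])]] <- x$accuracy$accuracy[i]
  }
  out
}
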