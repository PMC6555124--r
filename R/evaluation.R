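# Top-N accuracy, macro/micro precision/recall/F1 over top-N selections, and
# journal-size-stratified accuracy.

#' Top-N accuracy
#'
#' Fraction of samples whose true label appears among the first `n` entries
#' of their ranked prediction list.
#'
#' @param ranked Character (or integer) matrix, one row per sample, columns
#'   ordered by decreasing predicted probability.
#' @param truth Vector of true labels, one per sample.
#' @param n List length to consider; every row must have at least `n`
#'   columns.
#' @return A number in `[0, 1]`.
#' @export
top_n_accuracy <- function(ranked, truth, n = 1L) {
  check_ranked(ranked, truth, n)
  hits <- ranked[, seq_len(n), drop = FALSE] == truth
  mean(rowSums(hits) > 0)
}

check_ranked <- function(ranked, truth, n) {
  if (!is.matrix(ranked)) abort("ranked must be a matrix of labels")
  if (nrow(ranked) != length(truth)) {
    abort("ranked and truth must have one row/entry per sample")
  }
  if (n < 1 || n > ncol(ranked)) {
    abort(sprintf("n = %d outside the available list length %d", n, ncol(ranked)))
  }
  invisible(TRUE)
}

#' Per-class confusion counts at list length N
#'
#' With top-N selections each sample "predicts" a set of N labels. For a
#' class `c`: `tp` counts samples of `c` with `c` in their top-N, `fn` those
#' without, `fp` samples of other classes that include `c` in their top-N,
#' and `tn` the remainder, so `tp + fp + fn + tn` equals the sample count for
#' every class.
#'
#' @inheritParams top_n_accuracy
#' @param classes Class universe (default: union of truth and predictions).
#' @return Tibble with columns `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(ranked, truth, n = 1L, classes = NULL) {
  check_ranked(ranked, truth, n)
  top <- ranked[, seq_len(n), drop = FALSE]
  if (is.null(classes)) {
    classes <- sort(unique(c(as.vector(top), as.character(truth))))
  }
  n_samples <- length(truth)
  counts <- purrr::map(classes, function(cl) {
    in_list <- rowSums(top == cl) > 0
    is_true <- truth == cl
    tp <- sum(is_true & in_list)
    fn <- sum(is_true & !in_list)
    fp <- sum(!is_true & in_list)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn,
                   tn = n_samples - tp - fn - fp)
  })
  dplyr::bind_rows(counts)
}

#' Macro- and micro-averaged precision, recall and F1
#'
#' Macro-averaging takes the unweighted mean of per-class precision, recall
#' and F1; micro-averaging computes the same metrics from the summed
#' `tp`/`fp`/`fn` counts, weighting classes by frequency. A precision or
#' recall with an empty denominator is defined as 0 (and the affected
#' classes are flagged in the `zero_denominator` attribute); F1 is 0 when
#' precision + recall is 0.
#'
#' @param counts Tibble from [confusion_counts()].
#' @return Tibble with columns `average` (`"macro"`, `"micro"`), `precision`,
#'   `recall`, `f1`.
#' @export
macro_micro_metrics <- function(counts) {
  if (nrow(counts) == 0) abort("counts must contain at least one class")
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(counts$tp, counts$tp + counts$fp)
  rec <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  mi_p <- safe_div(tp, tp + fp)
  mi_r <- safe_div(tp, tp + fn)
  out <- tibble::tibble(
    average = c("macro", "micro"),
    precision = c(mean(prec), mi_p),
    recall = c(mean(rec), mi_r),
    f1 = c(mean(f1), safe_div(2 * mi_p * mi_r, mi_p + mi_r))
  )
  flagged <- counts$class[(counts$tp + counts$fp) == 0 | (counts$tp + counts$fn) == 0]
  attr(out, "zero_denominator") <- flagged
  out
}

#' Accuracy stratified by journal size bin
#'
#' Groups test samples by the size bin of their TRUE journal (bins come from
#' the training-corpus paper counts carried by the catalog) and computes
#' top-N accuracy within each bin, together with the bin's sample count.
#'
#' @inheritParams top_n_accuracy
#' @param catalog A `journal_catalog` whose `journals` table assigns every
#'   true label a `size_bin`.
#' @param n_values Integer vector of list lengths (default `c(1, 3, 5, 10)`,
#'   capped at the available list length).
#' @return Tibble with columns `size_bin`, `n_papers`, and one `acc_at_<N>`
#'   column per requested N.
#' @export
stratified_eval <- function(ranked, truth, catalog, n_values = c(1L, 3L, 5L, 10L)) {
  n_values <- n_values[n_values <= ncol(ranked)]
  bins <- catalog$journals$size_bin[match(as.character(truth),
                                          catalog$journals$journal_label)]
  if (anyNA(bins)) {
    abort("some true labels have no size bin in the catalog")
  }
  purrr::map(levels(bins)[table(bins) > 0], function(b) {
    idx <- which(bins == b)
    row <- tibble::tibble(size_bin = b, n_papers = length(idx))
    for (n in n_values) {
      row[[paste0("acc_at_", n)]] <-
        top_n_accuracy(ranked[idx, , drop = FALSE], truth[idx], n)
    }
    row
  }) |>
    dplyr::bind_rows()
}

#' Full evaluation report
#'
#' Bundles top-N accuracy, macro/micro precision/recall/F1 at each N, and
#' (when a catalog is supplied) size-stratified accuracy into one object.
#'
#' @inheritParams top_n_accuracy
#' @param catalog Optional `journal_catalog` for the stratified table.
#' @param n_values List lengths to evaluate (default `c(1, 3, 5, 10)`,
#'   capped at the available list length).
#' @return Object of class `"venue_eval"`: list with tibbles `accuracy`
#'   (`n`, `accuracy`), `averages` (`n`, `average`, `precision`, `recall`,
#'   `f1`), `strata` (or `NULL`), and `n_samples`.
#' @export
eval_report <- function(ranked, truth, catalog = NULL,
                        n_values = c(1L, 3L, 5L, 10L)) {
  n_values <- sort(unique(as.integer(n_values[n_values <= ncol(ranked)])))
  if (length(n_values) == 0) abort("no usable n_values for the ranked lists")
  truth <- as.character(truth)
  accuracy <- tibble::tibble(
    n = n_values,
    accuracy = purrr::map_dbl(n_values, ~ top_n_accuracy(ranked, truth, .x))
  )
  averages <- purrr::map(n_values, function(n) {
    m <- macro_micro_metrics(confusion_counts(ranked, truth, n))
    dplyr::mutate(m, n = n, .before = 1)
  }) |>
    dplyr::bind_rows()
  strata <- if (!is.null(catalog)) {
    stratified_eval(ranked, truth, catalog, n_values)
  }
  structure(
    list(accuracy = accuracy, averages = averages, strata = strata,
         n_samples = length(truth)),
    class = "venue_eval"
  )
}

#' @export
print.venue_eval <- function(x, digits = 3, ...) {
  cat("<venue_eval>", x$n_samples, "samples\n")
  acc <- x$accuracy
  cat(paste(sprintf("  acc@%d = %.*f", acc$n, digits, acc$accuracy),
            collapse = "  "), "\n")
  if (!is.null(x$strata)) {
    cat("  stratified by journal size:\n")
    print(as.data.frame(x$strata), row.names = FALSE, digits = digits)
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits a delimited text table per component plus one machine-readable JSON
#' file with the full report.
#'
#' @param report A `"venue_eval"` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$accuracy, file.path(dir, "accuracy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$averages, file.path(dir, "averages.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$strata)) {
    utils::write.table(report$strata, file.path(dir, "strata.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(n_samples = report$n_samples, accuracy = report$accuracy,
         averages = report$averages, strata = report$strata),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' Evaluate a fitted model on a test set
#'
#' Ranks every test abstract and computes the full report.
#'
#' @param model A fitted `"venue_cnn"`.
#' @param data Tibble with `abstract_text` and `journal_label`.
#' @param catalog Optional `journal_catalog`.
#' @param n_values List lengths (default `c(1, 3, 5, 10)`).
#' @return A `"venue_eval"` report.
#' @export
evaluate_model <- function(model, data, catalog = NULL,
                           n_values = c(1L, 3L, 5L, 10L)) {
  ranked <- predict(model, data, type = "rank")
  eval_report(ranked, data$journal_label, catalog = catalog,
              n_values = n_values)
}
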