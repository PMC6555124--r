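# Ranking class probabilities into a top-N journal recommendation list.

#' Rank class probabilities into a top-N recommendation list
#'
#' Journals are ordered by decreasing probability; ties break by ascending
#' journal label, so rankings are stable and identical across runs.
#'
#' @param S Named probability vector over journals (names are journal
#'   labels), or an unnamed vector with `labels` supplied.
#' @param n Number of entries to return (`1 <= n <= T`).
#' @param labels Journal labels when `S` is unnamed.
#' @param catalog Optional `journal_catalog`; when given, each entry's size
#'   bin is joined in.
#' @return Tibble with columns `rank`, `journal_label`, `probability`
#'   (non-increasing), and `size_bin` when a catalog is supplied.
#' @export
rank_probabilities <- function(S, n = length(S), labels = names(S),
                               catalog = NULL) {
  if (is.null(labels)) abort("S must be named or labels supplied")
  if (n < 1 || n > length(S)) {
    abort(sprintf("n must be between 1 and the number of journals (%d)", length(S)))
  }
  ord <- order(-S, labels)[seq_len(n)]
  out <- tibble::tibble(
    rank = seq_len(n),
    journal_label = labels[ord],
    probability = as.numeric(S[ord])
  )
  if (!is.null(catalog)) {
    out <- dplyr::left_join(out, catalog$journals[, c("journal_label", "size_bin")],
                            by = "journal_label")
  }
  out
}

#' Recommend journals for an abstract
#'
#' End-to-end composition: tokenize, encode with the model's vocabulary,
#' embed, run the network, rank. Pure given a fixed model: the same abstract
#' always yields the same list. Very short abstracts are scored anyway — the
#' corpus 200-character rule applies to training data, not queries — but a
#' warning is attached to (and raised for) results below
#' `min_tokens` tokens.
#'
#' @param model A fitted `"venue_cnn"`.
#' @param abstract_text A single non-empty abstract string.
#' @param n Number of journals to return (default 10, capped at `T`).
#' @param catalog Optional `journal_catalog` for size-bin annotation.
#' @param min_tokens Length below which a short-abstract warning is attached
#'   (default 20 tokens).
#' @return A [rank_probabilities()] tibble; short queries carry a
#'   `"venuecast_warning"` attribute.
#' @export
recommend <- function(model, abstract_text, n = 10L, catalog = NULL,
                      min_tokens = 20L) {
  toks <- tokenize(abstract_text)
  n <- min(as.integer(n), length(model$labels))
  seq <- encode_sequence(toks, model$vocabulary, m = model$config$m)
  ids <- matrix(seq$token_ids, nrow = 1)
  probs <- predict(model, ids, type = "prob")[1, ]
  out <- rank_probabilities(probs, n = n, labels = model$labels,
                            catalog = catalog)
  if (length(toks) < min_tokens) {
    msg <- sprintf("abstract has only %d tokens (< %d); recommendation may be unreliable",
                   length(toks), min_tokens)
    attr(out, "venuecast_warning") <- msg
    warn(msg)
  }
  out
}
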