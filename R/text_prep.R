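# Tokenization, corpus length statistics, and fixed-length integer encoding.

#' Tokenize an abstract
#'
#' Deterministic word segmentation: the text is case-folded (by default) and
#' split into word tokens and single punctuation tokens. Internal hyphens,
#' apostrophes and slashes are kept inside a word token, so "p53-mediated"
#' stays one token while trailing punctuation is split off.
#'
#' @param text A length-1 character vector, non-empty.
#' @param lowercase Fold to lower case first (default `TRUE`; pretrained
#'   biomedical embedding vocabularies are predominantly lowercase).
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize("Deep learning, applied.")
tokenize <- function(text, lowercase = TRUE) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    abort("text must be a single non-empty string")
  }
  if (lowercase) text <- tolower(text)
  toks <- stringr::str_extract_all(
    text,
    "[\\p{L}\\p{N}]+(?:[-'/][\\p{L}\\p{N}]+)*|[^\\s\\p{L}\\p{N}]"
  )[[1]]
  toks
}

#' Word-count histogram of a tokenized corpus
#'
#' Default bin edges follow the standard abstract-length bands
#' (20, 50, 100, 150, 200, 250, 300, 350 words, plus an open top bin); an
#' under-20 band is included so that counts always sum to the corpus size.
#'
#' @param corpus List of token vectors (or a record tibble with
#'   `abstract_text`, which is tokenized first).
#' @param edges Increasing numeric bin edges; bins are `[e_i, e_{i+1})` with
#'   an implicit `[0, e_1)` band below and `[e_last, Inf)` band above.
#' @return Tibble of class `"length_histogram"` with columns `bin`
#'   (ordered factor), `lower`, `upper`, `count`.
#' @export
length_histogram <- function(corpus,
                             edges = c(20, 50, 100, 150, 200, 250, 300, 350)) {
  if (is.data.frame(corpus)) {
    corpus <- purrr::map(corpus$abstract_text, tokenize)
  }
  stopifnot(all(diff(edges) > 0))
  lens <- purrr::map_int(corpus, length)
  breaks <- c(0, edges, Inf)
  labels <- c(
    paste0("<", edges[1]),
    paste0("[", edges[-length(edges)], ",", edges[-1], ")"),
    paste0(">=", edges[length(edges)])
  )
  bin <- cut(lens, breaks = breaks, labels = labels, right = FALSE)
  counts <- table(factor(bin, levels = labels))
  out <- tibble::tibble(
    bin = factor(labels, levels = labels, ordered = TRUE),
    lower = c(0, edges),
    upper = c(edges, Inf),
    count = as.integer(counts)
  )
  class(out) <- c("length_histogram", class(out))
  out
}

#' Build an id vocabulary from a tokenized corpus
#'
#' Ids start at 1; id 0 is reserved for padding and unseen tokens at encode
#' time. Tokens are ordered by decreasing corpus frequency (ties
#' alphabetical), so truncating the vocabulary keeps the most frequent words.
#'
#' @param corpus List of token vectors.
#' @param min_count Drop tokens seen fewer than this many times (default 1).
#' @return Tibble with columns `token`, `id`, `count`.
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  counts <- table(unlist(corpus, use.names = FALSE))
  counts <- counts[counts >= min_count]
  ord <- order(-as.integer(counts), names(counts))
  tibble::tibble(
    token = names(counts)[ord],
    id = seq_along(ord),
    count = as.integer(counts)[ord]
  )
}

#' Write / read a vocabulary as plain text
#'
#' One `token<TAB>id` pair per line.
#'
#' @param vocabulary Vocabulary tibble from [build_vocabulary()].
#' @param path File path.
#' @export
write_vocabulary <- function(vocabulary, path) {
  writeLines(paste(vocabulary$token, vocabulary$id, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- strsplit(readLines(path, encoding = "UTF-8"), "\t", fixed = TRUE)
  tibble::tibble(
    token = purrr::map_chr(lines, 1),
    id = as.integer(purrr::map_chr(lines, 2))
  )
}

#' Encode a token list as a fixed-length id sequence
#'
#' Sequences shorter than `m` are zero-padded at the tail; longer sequences
#' keep their first `m` tokens (tail truncation). Tokens absent from the
#' vocabulary get id 0, the same sentinel as padding; their embedding resolves
#' to the zero vector downstream.
#'
#' @param tokens Non-empty character vector of tokens.
#' @param vocabulary Vocabulary tibble (`token`, `id`).
#' @param m Fixed sequence length (default 350).
#' @return Object of class `"token_sequence"`: list with `token_ids` (integer
#'   vector of length exactly `m`), `true_length` (pre-padding token count),
#'   and `m`.
#' @export
encode_sequence <- function(tokens, vocabulary, m = 350L) {
  if (!is.numeric(m) || length(m) != 1 || m <= 0) abort("m must be a positive integer")
  if (length(tokens) == 0) abort("tokens must be non-empty")
  m <- as.integer(m)
  lut <- stats::setNames(vocabulary$id, vocabulary$token)
  ids <- unname(lut[tokens])
  ids[is.na(ids)] <- 0L
  true_length <- length(ids)
  if (true_length >= m) {
    ids <- ids[seq_len(m)]
  } else {
    ids <- c(ids, integer(m - true_length))
  }
  structure(
    list(token_ids = as.integer(ids), true_length = true_length, m = m),
    class = "token_sequence"
  )
}

#' Recover tokens from an encoded sequence
#'
#' Inverse of [encode_sequence()] up to truncation and vocabulary coverage:
#' returns the first `min(true_length, m)` tokens, with `NA` where the
#' original token was out of vocabulary.
#'
#' @param seq A `token_sequence`.
#' @param vocabulary Vocabulary tibble.
#' @return Character vector.
#' @export
decode_sequence <- function(seq, vocabulary) {
  n <- min(seq$true_length, seq$m)
  ids <- seq$token_ids[seq_len(n)]
  out <- rep(NA_character_, n)
  hit <- ids > 0
  out[hit] <- vocabulary$token[match(ids[hit], vocabulary$id)]
  out
}

#' Encode a whole corpus as an id matrix
#'
#' @param corpus List of token vectors.
#' @param vocabulary Vocabulary tibble.
#' @param m Fixed sequence length.
#' @return List with `ids` (integer matrix, one row per document, `m`
#'   columns) and `true_length` (integer vector).
#' @export
encode_corpus <- function(corpus, vocabulary, m = 350L) {
  seqs <- purrr::map(corpus, encode_sequence, vocabulary = vocabulary, m = m)
  list(
    ids = do.call(rbind, purrr::map(seqs, "token_ids")),
    true_length = purrr::map_int(seqs, "true_length")
  )
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("<token_sequence> m =", x$m, "true_length =", x$true_length, "\n")
  invisible(x)
}
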