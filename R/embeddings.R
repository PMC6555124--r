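# Word-embedding tables: word2vec text/binary I/O, lookup with the
# zero-vector rule for unknown tokens, and the m x k abstract matrix.

#' Construct an embedding table
#'
#' @param vectors Numeric matrix, one row per token, with row names giving
#'   the tokens.
#' @return Object of class `"embedding_table"`: list with `vectors`, `k`
#'   (vector dimension), `tokens`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  structure(
    list(vectors = vectors, k = ncol(vectors), tokens = rownames(vectors)),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table>", length(x$tokens), "tokens, k =", x$k, "\n")
  invisible(x)
}

#' Look up word vectors, with zeros for unknown tokens
#'
#' Any token absent from the table resolves to the all-zero vector.
#'
#' @param table An `embedding_table`.
#' @param tokens Character vector.
#' @return Numeric matrix `length(tokens)` x `k`.
#' @export
lookup_vectors <- function(table, tokens) {
  out <- matrix(0, nrow = length(tokens), ncol = table$k)
  idx <- match(tokens, table$tokens)
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  rownames(out) <- tokens
  out
}

#' Read word vectors in word2vec text or binary format
#'
#' The text dialect is one header line `"<vocab> <k>"` followed by
#' `token v1 ... vk` lines; the binary dialect is the same header followed by
#' `token<space>` and `k` little-endian 4-byte floats per word.
#'
#' @param path File path.
#' @param expected_k If non-`NULL`, error unless the file's dimension matches.
#' @param binary `TRUE`, `FALSE`, or `"auto"` (default: sniff the content).
#' @return An `embedding_table`.
#' @export
load_word_vectors <- function(path, expected_k = NULL, binary = "auto") {
  if (identical(binary, "auto")) {
    head_bytes <- readBin(path, "raw", n = 4096)
    nl <- which(head_bytes == as.raw(10))[1]
    if (is.na(nl)) abort("truncated word-vector file: no header line")
    after <- head_bytes[seq(nl + 1, length(head_bytes))]
    binary <- any(after == as.raw(0)) ||
      mean(after >= as.raw(32) & after <= as.raw(126) | after == as.raw(10)) < 0.95
  }
  if (binary) read_w2v_binary(path, expected_k) else read_w2v_text(path, expected_k)
}

read_w2v_text <- function(path, expected_k) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) abort("truncated word-vector file")
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(header) != 2 || anyNA(header)) abort("malformed word2vec header")
  v <- header[1]; k <- header[2]
  check_k(k, expected_k)
  if (length(lines) < v + 1) abort("truncated word-vector file: fewer rows than header declares")
  parts <- strsplit(trimws(lines[2:(v + 1)]), "\\s+")
  bad <- purrr::map_int(parts, length) != k + 1
  if (any(bad)) abort("truncated word-vector file: row with wrong arity")
  mat <- matrix(as.numeric(unlist(purrr::map(parts, `[`, -1))),
                nrow = v, ncol = k, byrow = TRUE)
  rownames(mat) <- purrr::map_chr(parts, 1)
  embedding_table(mat)
}

read_w2v_binary <- function(path, expected_k) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (length(ch) == 0) abort("truncated word-vector file")
    if (ch == as.raw(10)) break
    header <- c(header, rawToChar(ch))
  }
  header <- as.integer(strsplit(trimws(paste(header, collapse = "")), "\\s+")[[1]])
  if (length(header) != 2 || anyNA(header)) abort("malformed word2vec header")
  v <- header[1]; k <- header[2]
  check_k(k, expected_k)
  mat <- matrix(0, nrow = v, ncol = k)
  tokens <- character(v)
  for (i in seq_len(v)) {
    word <- raw(0)
    repeat {
      ch <- readBin(con, "raw", n = 1)
      if (length(ch) == 0) abort("truncated word-vector file")
      if (ch == as.raw(32)) break
      if (ch != as.raw(10)) word <- c(word, ch)
    }
    tokens[i] <- rawToChar(word)
    vec <- readBin(con, "numeric", n = k, size = 4, endian = "little")
    if (length(vec) != k) abort("truncated word-vector file: short vector")
    mat[i, ] <- vec
  }
  rownames(mat) <- tokens
  embedding_table(mat)
}

check_k <- function(k, expected_k) {
  if (!is.null(expected_k) && k != expected_k) {
    abort(sprintf("embedding dimension mismatch: file has k=%d, expected %d",
                  k, expected_k))
  }
}

#' Write an embedding table in word2vec text or binary format
#'
#' @param table An `embedding_table`.
#' @param path File path.
#' @param binary Write the binary dialect (little-endian float32)?
#' @export
write_word_vectors <- function(table, path, binary = FALSE) {
  v <- length(table$tokens); k <- table$k
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%d %d\n", v, k)), con)
    for (i in seq_len(v)) {
      writeBin(charToRaw(paste0(table$tokens[i], " ")), con)
      writeBin(as.numeric(table$vectors[i, ]), con, size = 4, endian = "little")
      writeBin(charToRaw("\n"), con)
    }
  } else {
    lines <- c(
      sprintf("%d %d", v, k),
      purrr::map_chr(seq_len(v), function(i) {
        paste(table$tokens[i],
              paste(formatC(table$vectors[i, ], format = "g", digits = 8),
                    collapse = " "))
      })
    )
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Build the m x k abstract matrix from an encoded sequence
#'
#' Row `i` is the embedding of token `i`; padding and out-of-vocabulary
#' positions (id 0) are all-zero rows, so rows beyond `true_length` are zero.
#'
#' @param seq A `token_sequence`.
#' @param table An `embedding_table`.
#' @param vocabulary The vocabulary tibble used at encode time (maps ids back
#'   to tokens for the table lookup).
#' @return Numeric matrix of shape `m` x `k`.
#' @export
embed_abstract <- function(seq, table, vocabulary) {
  V <- matrix(0, nrow = seq$m, ncol = table$k)
  n <- min(seq$true_length, seq$m)
  ids <- seq$token_ids[seq_len(n)]
  hit <- ids > 0
  if (any(hit)) {
    toks <- vocabulary$token[match(ids[hit], vocabulary$id)]
    V[which(hit), ] <- lookup_vectors(table, toks)
  }
  V
}

#' Align an embedding table with a vocabulary
#'
#' Produces the id-indexed embedding matrix the network consumes: row `i`
#' holds the vector of the token with id `i`, zero where the token is absent
#' from the table (and implicitly zero for id 0).
#'
#' @param table An `embedding_table`.
#' @param vocabulary Vocabulary tibble (`token`, `id` with ids `1..V`).
#' @return Numeric matrix `V x k`.
#' @export
align_embeddings <- function(table, vocabulary) {
  stopifnot(all(sort(vocabulary$id) == seq_len(nrow(vocabulary))))
  out <- matrix(0, nrow = nrow(vocabulary), ncol = table$k)
  out[vocabulary$id, ] <- lookup_vectors(table, vocabulary$token)
  out
}

#' Random embedding table over a vocabulary
#'
#' Small uniform initialisation (the word2vec convention,
#' `U(-0.5, 0.5)/k`), for use when embeddings are learned jointly with the
#' classifier rather than pretrained.
#'
#' @param vocabulary Vocabulary tibble.
#' @param k Vector dimension.
#' @param seed Integer seed.
#' @return An `embedding_table`.
#' @export
random_embeddings <- function(vocabulary, k = 200L, seed = 1L) {
  mat <- withr::with_seed(seed, {
    matrix(runif(nrow(vocabulary) * k, -0.5, 0.5) / k,
           nrow = nrow(vocabulary), ncol = k)
  })
  rownames(mat) <- vocabulary$token
  embedding_table(mat)
}
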