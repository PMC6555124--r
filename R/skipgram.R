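# Skip-gram word-embedding trainer with hierarchical softmax and frequent-word
# subsampling. Pure R; intended for desk-scale corpora (property tests, small
# pipelines) — pretrained vectors are the route for full-size corpora.

#' Train skip-gram word embeddings
#'
#' Classic skip-gram with a Huffman-tree hierarchical softmax output and
#' frequent-word subsampling. For each centre word a window radius is drawn
#' uniformly from `1..window`; each context word's input vector is updated
#' against the centre word's Huffman path with a linearly decaying learning
#' rate. Deterministic for a fixed seed (single worker).
#'
#' @param corpus List of token vectors.
#' @param k Embedding dimension (default 200).
#' @param window Maximum window radius (default 5).
#' @param subsample_threshold Frequent-word subsampling threshold `t`
#'   (default 0.001); a token with corpus frequency `f` is kept with
#'   probability `(sqrt(f/(t N)) + 1) * t N / f`. Set to 0 to disable.
#' @param mode Only `"hierarchical_softmax"` is implemented.
#' @param epochs Passes over the corpus (default 5).
#' @param learning_rate Initial learning rate (default 0.025), decaying
#'   linearly to 1e-4 of its initial value.
#' @param min_count Drop tokens rarer than this (default 1).
#' @param seed Integer seed.
#' @return An [embedding_table()] over the corpus vocabulary.
#' @export
train_skipgram <- function(corpus, k = 200L, window = 5L,
                           subsample_threshold = 0.001,
                           mode = "hierarchical_softmax",
                           epochs = 5L, learning_rate = 0.025,
                           min_count = 1L, seed = 1L) {
  if (!identical(mode, "hierarchical_softmax")) {
    abort("only mode = 'hierarchical_softmax' is implemented")
  }
  if (length(corpus) == 0) abort("corpus must be non-empty")
  n_tokens <- sum(purrr::map_int(corpus, length))
  if (n_tokens < window) abort("corpus smaller than the window size")

  vocab <- build_vocabulary(corpus, min_count = min_count)
  V <- nrow(vocab)
  if (V < 2) abort("need at least 2 distinct tokens to train embeddings")
  lut <- stats::setNames(vocab$id, vocab$token)
  docs <- purrr::map(corpus, function(toks) {
    ids <- unname(lut[toks])
    ids[!is.na(ids)]
  })

  tree <- build_huffman(vocab$count)
  total_words <- sum(vocab$count)
  keep_prob <- if (subsample_threshold > 0) {
    tn <- subsample_threshold * total_words
    pmin(1, (sqrt(vocab$count / tn) + 1) * tn / vocab$count)
  } else {
    rep(1, V)
  }

  withr::with_seed(seed, {
    syn0 <- matrix(runif(V * k, -0.5, 0.5) / k, nrow = V, ncol = k)
    syn1 <- matrix(0, nrow = V - 1, ncol = k)
    schedule_total <- total_words * epochs
    processed <- 0
    lr0 <- learning_rate
    for (ep in seq_len(epochs)) {
      for (doc in docs) {
        if (length(doc) == 0) next
        kept <- doc[runif(length(doc)) < keep_prob[doc]]
        processed <- processed + length(doc)
        n <- length(kept)
        if (n < 2) next
        lr <- max(lr0 * (1 - processed / schedule_total), lr0 * 1e-4)
        radii <- sample.int(window, n, replace = TRUE)
        for (pos in seq_len(n)) {
          centre <- kept[pos]
          path <- tree$paths[[centre]]
          if (length(path) == 0) next
          code <- tree$codes[[centre]]
          lo <- max(1L, pos - radii[pos]); hi <- min(n, pos + radii[pos])
          for (cpos in lo:hi) {
            if (cpos == pos) next
            cw <- kept[cpos]
            l1 <- syn0[cw, ]
            f <- 1 / (1 + exp(-as.vector(syn1[path, , drop = FALSE] %*% l1)))
            g <- (1 - code - f) * lr
            neu1e <- as.vector(crossprod(syn1[path, , drop = FALSE], g))
            syn1[path, ] <- syn1[path, , drop = FALSE] + tcrossprod(g, l1)
            syn0[cw, ] <- l1 + neu1e
          }
        }
      }
    }
    rownames(syn0) <- vocab$token
    embedding_table(syn0)
  })
}

# Huffman coding over vocabulary counts (counts must be sorted decreasing,
# as build_vocabulary guarantees). Returns, per word, the root-to-leaf list
# of inner-node indices (1..V-1) and the 0/1 branch codes.
build_huffman <- function(counts) {
  V <- length(counts)
  stopifnot(V >= 2, !is.unsorted(rev(counts)))
  count <- c(as.numeric(counts), rep(Inf, V - 1))
  parent <- integer(2 * V - 1)
  binary <- integer(2 * V - 1)
  pos1 <- V; pos2 <- V + 1
  for (a in seq_len(V - 1)) {
    pick <- function() {
      if (pos1 >= 1 && (pos2 > V + a - 1 || count[pos1] < count[pos2])) {
        m <- pos1; pos1 <<- pos1 - 1
      } else {
        m <- pos2; pos2 <<- pos2 + 1
      }
      m
    }
    min1 <- pick(); min2 <- pick()
    count[V + a] <- count[min1] + count[min2]
    parent[min1] <- V + a
    parent[min2] <- V + a
    binary[min2] <- 1L
  }
  paths <- vector("list", V)
  codes <- vector("list", V)
  for (w in seq_len(V)) {
    node <- w
    p <- integer(0); c_ <- integer(0)
    while (parent[node] != 0) {
      p <- c(parent[node] - V, p)   # inner node carrying this branch
      c_ <- c(binary[node], c_)
      node <- parent[node]
    }
    paths[[w]] <- p
    codes[[w]] <- c_
  }
  list(paths = paths, codes = codes)
}
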