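# Shared fixtures: minimal JATS documents, toy record tables, naive oracles.

jats_xml <- function(abstract,
                     pissn = "2000-0019", eissn = NULL,
                     year = 2012, month = 4, id = "PMC0001") {
  issn <- paste0(
    if (!is.null(pissn)) sprintf("<issn pub-type='ppub'>%s</issn>", pissn) else "",
    if (!is.null(eissn)) sprintf("<issn pub-type='epub'>%s</issn>", eissn) else ""
  )
  abs_tag <- if (is.null(abstract)) "" else sprintf("<abstract><p>%s</p></abstract>", abstract)
  sprintf(paste0(
    "<article><front><journal-meta>%s</journal-meta><article-meta>",
    "<article-id pub-id-type='pmc'>%s</article-id>",
    "<pub-date><month>%d</month><year>%d</year></pub-date>",
    "%s</article-meta></front></article>"
  ), issn, id, month, year, abs_tag)
}

long_abstract <- function(n_chars = 250, word = "signal") {
  txt <- paste(rep(word, ceiling(n_chars / (nchar(word) + 1))), collapse = " ")
  substr(txt, 1, n_chars)
}

# toy record table: one journal label per element of `sizes`
toy_records <- function(sizes, abstract = long_abstract(250),
                        year = 2012, month = 6) {
  labels <- sprintf("J%02d", seq_along(sizes))
  n <- sum(sizes)
  tibble::tibble(
    paper_id = sprintf("P%04d", seq_len(n)),
    abstract_text = abstract,
    journal_label = rep(labels, sizes),
    issn_print = rep(sprintf("1000-%04d", seq_along(sizes)), sizes),
    issn_electronic = rep(sprintf("2000-%04d", seq_along(sizes)), sizes),
    pub_year = year,
    pub_month = month
  )
}

# independent nested-loop oracle for valid convolution + width-2 pooling
naive_conv <- function(input, kernels, biases, relu = TRUE) {
  h <- ncol(kernels[[1]])
  Lc <- nrow(input) - h + 1
  out <- matrix(0, Lc, length(kernels))
  for (j in seq_along(kernels)) {
    for (i in seq_len(Lc)) {
      acc <- 0
      for (q in seq_len(h)) {
        acc <- acc + sum(kernels[[j]][, q] * input[i + q - 1, ])
      }
      v <- acc + biases[j]
      out[i, j] <- if (relu) max(v, 0) else v
    }
  }
  out
}

naive_pool2 <- function(v) {
  out <- numeric(length(v) %/% 2)
  for (i in seq_along(out)) out[i] <- max(v[2 * i - 1], v[2 * i])
  out
}

# independent brute-force oracle: per-class confusion counts by literal
# enumeration over samples
enumerate_counts <- function(ranked, truth, n, classes) {
  out <- NULL
  for (cl in classes) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(truth)) {
      listed <- cl %in% ranked[i, 1:n]
      if (truth[i] == cl && listed) tp <- tp + 1
      if (truth[i] == cl && !listed) fn <- fn + 1
      if (truth[i] != cl && listed) fp <- fp + 1
      if (truth[i] != cl && !listed) tn <- tn + 1
    }
    out <- rbind(out, data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn))
  }
  out
}

# small, fast network configuration for training tests
tiny_config <- function(n_classes, m = 60, k = 16, seed = 1L, ...) {
  venue_cnn_config(
    n_classes = n_classes, m = m, k = k,
    conv_stages = list(c(16, 3), c(8, 4), c(8, 5)),
    hidden_sizes = c(32, 16),
    batch_size = 32, learning_rate = 3e-3, seed = seed, ...
  )
}

# short-document synthetic spec so training fixtures stay fast
short_doc_spec <- function(n_classes, class_sizes, sharpness = 1,
                           vocab_size = 600, seed = 1L) {
  synthetic_spec(
    n_classes = n_classes, class_sizes = class_sizes,
    vocab_size = vocab_size, topic_sharpness = sharpness,
    length_distribution = tibble::tibble(lower = 30, upper = 60, prob = 1),
    seed = seed
  )
}
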