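# Synthetic journal-labelled corpora: per-class topic vocabularies with a
# shared pool, controllable imbalance, and a realistic abstract-length
# distribution, so the whole pipeline is testable without downloads.

# Proportions of abstracts per word-count band in a large PMC-style corpus
# (bands [20,50), [50,100), ..., [300,350), and 350+).
pmc_length_profile <- function() {
  counts <- c(25499, 76614, 139420, 227993, 191156, 87597, 46275, 43328)
  tibble::tibble(
    lower = c(20, 50, 100, 150, 200, 250, 300, 350),
    upper = c(50, 100, 150, 200, 250, 300, 350, 450),
    prob = counts / sum(counts)
  )
}

#' Specification of a synthetic labelled corpus
#'
#' Documents are drawn from a per-class unigram mixture: each word comes from
#' the class-specific vocabulary with probability `topic_sharpness` and from
#' a shared pool otherwise. Class vocabularies are disjoint; sharpness 1
#' therefore makes classes perfectly separable by vocabulary membership,
#' while sharpness 0 removes all signal. Abstract lengths are drawn from a
#' banded word-count distribution whose default mirrors the length profile
#' of a large PMC corpus.
#'
#' @param n_classes Number of journals.
#' @param class_sizes Documents per class (recycled to `n_classes`);
#'   imbalance ratios up to about 1000:1 are supported.
#' @param vocab_size Total vocabulary size.
#' @param topic_sharpness Probability in `[0, 1]` that a word is drawn from
#'   the class vocabulary.
#' @param shared_vocab_fraction Fraction of the vocabulary forming the shared
#'   pool.
#' @param length_distribution Tibble with columns `lower`, `upper`, `prob`
#'   (word-count bands and their probabilities; normalised internally).
#'   Default: the PMC-style profile.
#' @param seed Integer seed.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_classes = 20L,
                           class_sizes = 100L,
                           vocab_size = 5000L,
                           topic_sharpness = 0.9,
                           shared_vocab_fraction = 0.3,
                           length_distribution = pmc_length_profile(),
                           seed = 1L) {
  class_sizes <- rep_len(as.integer(class_sizes), n_classes)
  stopifnot(n_classes >= 1, all(class_sizes >= 1),
            topic_sharpness >= 0, topic_sharpness <= 1,
            shared_vocab_fraction >= 0, shared_vocab_fraction < 1,
            all(c("lower", "upper", "prob") %in% names(length_distribution)))
  ld <- dplyr::mutate(length_distribution, prob = .data$prob / sum(.data$prob))
  structure(
    list(n_classes = as.integer(n_classes), class_sizes = class_sizes,
         vocab_size = as.integer(vocab_size),
         topic_sharpness = topic_sharpness,
         shared_vocab_fraction = shared_vocab_fraction,
         length_distribution = ld, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Desk-scale imbalanced corpus preset
#'
#' Class sizes span all four catalog size bins at their true boundaries
#' (tiny: 150, 150; small: 600, 600; medium: 2500; large: 10,500 papers),
#' 14,500 documents in total — large enough to exercise size-stratified
#' evaluation, small enough for a workstation.
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
imbalanced_preset <- function(seed = 1L) {
  synthetic_spec(
    n_classes = 6L,
    class_sizes = c(150L, 150L, 600L, 600L, 2500L, 10500L),
    vocab_size = 4000L,
    topic_sharpness = 0.9,
    shared_vocab_fraction = 0.3,
    seed = seed
  )
}

#' Generate a journal-labelled synthetic corpus
#'
#' Deterministic for a fixed `spec$seed`. Each class receives a synthetic
#' NLM-catalog-style journal identifier and a print/electronic ISSN pair with
#' valid check digits; publication dates fall inside 2008-2016.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (paper-record tibble with `journal_label`),
#'   `class_vocab` (named list of per-class token vectors, ground truth),
#'   `shared_vocab`, `journal_list` (tibble `issn`, `journal_label`), and
#'   `spec`.
#' @export
generate_corpus <- function(spec) {
  T_ <- spec$n_classes
  vocab <- sprintf("w%05d", seq_len(spec$vocab_size))
  n_shared <- floor(spec$shared_vocab_fraction * spec$vocab_size)
  n_class_pool <- spec$vocab_size - n_shared
  if (n_class_pool < T_) {
    abort(sprintf(
      "vocabulary too small: %d non-shared tokens cannot form %d disjoint class vocabularies",
      n_class_pool, T_))
  }
  shared <- vocab[seq_len(n_shared)]
  per_class <- n_class_pool %/% T_
  class_vocab <- purrr::map(seq_len(T_), function(j) {
    vocab[n_shared + ((j - 1L) * per_class + 1L):(j * per_class)]
  })
  labels <- sprintf("NLM%05d", seq_len(T_))
  names(class_vocab) <- labels

  withr::with_seed(spec$seed, {
    issn_p <- purrr::map_chr(seq_len(T_), ~ make_issn(2 * .x - 1))
    issn_e <- purrr::map_chr(seq_len(T_), ~ make_issn(2 * .x))
    ld <- spec$length_distribution
    total <- sum(spec$class_sizes)
    class_of <- rep(seq_len(T_), spec$class_sizes)
    bin <- sample.int(nrow(ld), total, replace = TRUE, prob = ld$prob)
    len <- floor(runif(total, ld$lower[bin], ld$upper[bin]))
    texts <- character(total)
    for (i in seq_len(total)) {
      j <- class_of[i]
      from_class <- runif(len[i]) < spec$topic_sharpness
      if (length(shared) == 0) from_class[] <- TRUE
      words <- character(len[i])
      n_c <- sum(from_class)
      if (n_c > 0) words[from_class] <- sample(class_vocab[[j]], n_c, replace = TRUE)
      if (n_c < len[i]) words[!from_class] <- sample(shared, len[i] - n_c, replace = TRUE)
      texts[i] <- paste(words, collapse = " ")
    }
    records <- tibble::tibble(
      paper_id = sprintf("SYN%06d", seq_len(total)),
      abstract_text = texts,
      journal_label = labels[class_of],
      issn_print = issn_p[class_of],
      issn_electronic = issn_e[class_of],
      pub_year = sample(2008:2016, total, replace = TRUE),
      pub_month = sample(1:12, total, replace = TRUE)
    )
    journal_list <- tibble::tibble(
      issn = c(issn_p, issn_e),
      journal_label = c(labels, labels)
    )
    list(records = records, class_vocab = class_vocab, shared_vocab = shared,
         journal_list = journal_list, spec = spec)
  })
}

# ISSN with a valid check digit: weights 8..2 over seven digits, check is
# (11 - sum mod 11) mod 11, with 10 written as X.
make_issn <- function(serial) {
  digits <- as.integer(strsplit(sprintf("%07d", 2000000 + serial), "")[[1]])
  s <- sum(digits * 8:2)
  chk <- (11 - s %% 11) %% 11
  chk <- if (chk == 10) "X" else as.character(chk)
  sprintf("%s-%s%s",
          paste(digits[1:4], collapse = ""),
          paste(digits[5:7], collapse = ""), chk)
}

#' Write records as minimal JATS XML fixture files
#'
#' One well-formed JATS-style article per record, round-trippable through
#' [parse_jats_record()].
#'
#' @param records Paper-record tibble.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, one per record.
#' @export
make_fixture_xml <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::map_chr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    issn_tags <- paste0(
      if (!is.na(r$issn_print))
        sprintf("<issn pub-type=\"ppub\">%s</issn>", r$issn_print) else "",
      if (!is.na(r$issn_electronic))
        sprintf("<issn pub-type=\"epub\">%s</issn>", r$issn_electronic) else ""
    )
    xml <- sprintf(
      paste0(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
        "<article><front><journal-meta>%s</journal-meta><article-meta>",
        "<article-id pub-id-type=\"pmc\">%s</article-id>",
        "<pub-date pub-type=\"epub\"><month>%d</month><year>%d</year></pub-date>",
        "<abstract><p>%s</p></abstract>",
        "</article-meta></front></article>"
      ),
      issn_tags, r$paper_id, r$pub_month, r$pub_year,
      xml_escape(r$abstract_text)
    )
    path <- file.path(dir, paste0(r$paper_id, ".xml"))
    writeLines(xml, path, useBytes = TRUE)
    path
  })
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Naive vocabulary-overlap classifier
#'
#' Assigns each document to the class whose ground-truth vocabulary covers
#' the most of its tokens (ties to the first class in order). With disjoint
#' class vocabularies and sharpness 1 this is a perfect classifier; it
#' upper-bounds what a trained model can reach on the synthetic task.
#'
#' @param texts Character vector of abstracts (or list of token vectors).
#' @param class_vocab Named list of per-class token vectors.
#' @return Character vector of class names.
#' @export
vocab_overlap_classify <- function(texts, class_vocab) {
  toks <- if (is.character(texts)) purrr::map(texts, tokenize) else texts
  scores <- vapply(class_vocab,
                   function(v) purrr::map_int(toks, ~ sum(.x %in% v)),
                   integer(length(toks)))
  if (length(toks) == 1L) scores <- matrix(scores, nrow = 1)
  names(class_vocab)[max.col(scores, ties.method = "first")]
}
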