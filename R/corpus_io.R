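# JATS/PMC ingestion: parse article XML into paper records, apply the corpus
# inclusion filters, build the journal catalog, and split the corpus.

#' Parse a single JATS article into a paper record
#'
#' Extracts the abstract, ISSNs, and publication date from one PMC-style JATS
#' XML document. A record is rejected (never an error) when the document is
#' malformed, has no abstract, has an abstract shorter than
#' `min_abstract_chars`, or carries no ISSN; the rejection carries a
#' machine-readable reason code.
#'
#' Character counting happens after whitespace normalisation: runs of
#' whitespace in the abstract collapse to single spaces before the length
#' check.
#'
#' @param xml_text A length-1 character vector holding the XML document, or an
#'   `xml2` document.
#' @param min_abstract_chars Minimum abstract length in characters
#'   (default 200).
#' @param paper_id Identifier to use when the document carries no
#'   `<article-id>`.
#' @return A one-row tibble with columns `paper_id`, `abstract_text`,
#'   `issn_print`, `issn_electronic`, `pub_year`, `pub_month` when accepted;
#'   otherwise an object of class `"paper_rejection"` whose `reason` is one of
#'   `"malformed"`, `"no_abstract"`, `"short_abstract"`, `"no_issn"`.
#' @seealso [parse_jats_corpus()], [filter_corpus()]
#' @export
#' @examples
#' xml <- paste0(
#'   "<article><front><article-meta>",
#'   "<article-id pub-id-type='pmc'>PMC1</article-id>",
#'   "<issn pub-type='ppub'>0028-0836</issn>",
#'   "<pub-date><month>3</month><year>2013</year></pub-date>",
#'   "<abstract><p>", strrep("Convolutional venue recommendation. ", 8),
#'   "</p></abstract></article-meta></front></article>"
#' )
#' parse_jats_record(xml)
parse_jats_record <- function(xml_text, min_abstract_chars = 200,
                              paper_id = NULL) {
  doc <- tryCatch(
    if (inherits(xml_text, "xml_document")) xml_text else xml2::read_xml(xml_text),
    error = function(e) NULL
  )
  if (is.null(doc)) {
    return(paper_rejection("malformed", paper_id))
  }

  id_node <- xml2::xml_find_first(
    doc, ".//article-id[@pub-id-type='pmc'] | .//article-id"
  )
  id <- if (!inherits(id_node, "xml_missing")) {
    stringr::str_squish(xml2::xml_text(id_node))
  } else {
    paper_id %||% NA_character_
  }

  abs_node <- xml2::xml_find_first(doc, ".//abstract")
  if (inherits(abs_node, "xml_missing")) {
    return(paper_rejection("no_abstract", id))
  }
  abstract <- stringr::str_squish(xml2::xml_text(abs_node))
  if (nchar(abstract) < min_abstract_chars) {
    return(paper_rejection("short_abstract", id))
  }

  issn_nodes <- xml2::xml_find_all(doc, ".//issn")
  if (length(issn_nodes) == 0) {
    return(paper_rejection("no_issn", id))
  }
  issn_type <- xml2::xml_attr(issn_nodes, "pub-type")
  issn_val <- stringr::str_squish(xml2::xml_text(issn_nodes))
  pick <- function(type) {
    hit <- issn_val[!is.na(issn_type) & issn_type == type]
    if (length(hit)) hit[[1]] else NA_character_
  }
  issn_print <- pick("ppub")
  issn_electronic <- pick("epub")
  if (is.na(issn_print) && is.na(issn_electronic)) {
    issn_print <- issn_val[[1]]
  }

  date_node <- xml2::xml_find_first(doc, ".//pub-date[year]")
  pub_year <- pub_month <- NA_integer_
  if (!inherits(date_node, "xml_missing")) {
    pub_year <- suppressWarnings(
      as.integer(xml2::xml_text(xml2::xml_find_first(date_node, "./year")))
    )
    m_node <- xml2::xml_find_first(date_node, "./month")
    pub_month <- if (inherits(m_node, "xml_missing")) {
      1L  # month precision; missing month treated as January
    } else {
      suppressWarnings(as.integer(xml2::xml_text(m_node)))
    }
    if (is.na(pub_month)) pub_month <- 1L
  }

  tibble::tibble(
    paper_id = id,
    abstract_text = abstract,
    issn_print = issn_print,
    issn_electronic = issn_electronic,
    pub_year = pub_year,
    pub_month = pub_month
  )
}

paper_rejection <- function(reason, paper_id = NULL) {
  structure(
    list(reason = reason, paper_id = paper_id %||% NA_character_),
    class = "paper_rejection"
  )
}

#' @export
print.paper_rejection <- function(x, ...) {
  cat("<paper_rejection> reason:", x$reason, "id:", x$paper_id, "\n")
  invisible(x)
}

#' Parse a set of JATS files or XML strings into a record table
#'
#' @param x Character vector of file paths (or raw XML strings when
#'   `from_files = FALSE`).
#' @param from_files Interpret `x` as paths (default) or as XML text.
#' @inheritParams parse_jats_record
#' @return A list with `records` (tibble of accepted papers) and `rejections`
#'   (tibble with `paper_id`, `reason`). `nrow(records) + nrow(rejections)`
#'   always equals `length(x)`.
#' @export
parse_jats_corpus <- function(x, from_files = TRUE, min_abstract_chars = 200) {
  parsed <- purrr::imap(x, function(item, i) {
    id_hint <- if (from_files) sub("\\.xml$", "", basename(item)) else paste0("doc", i)
    txt <- if (from_files) paste(readLines(item, warn = FALSE), collapse = "\n") else item
    parse_jats_record(txt, min_abstract_chars = min_abstract_chars,
                      paper_id = id_hint)
  })
  ok <- purrr::map_lgl(parsed, tibble::is_tibble)
  records <- if (any(ok)) dplyr::bind_rows(parsed[ok]) else empty_records()
  rejections <- tibble::tibble(
    paper_id = purrr::map_chr(parsed[!ok], "paper_id"),
    reason = purrr::map_chr(parsed[!ok], "reason")
  )
  list(records = records, rejections = rejections)
}

empty_records <- function() {
  tibble::tibble(
    paper_id = character(), abstract_text = character(),
    issn_print = character(), issn_electronic = character(),
    pub_year = integer(), pub_month = integer()
  )
}

#' Attach journal labels to records via an ISSN-to-journal mapping
#'
#' Maps each record's print or electronic ISSN to a catalog-style unique
#' journal identifier (a LocatorPlus-like ID). Records whose ISSNs are absent
#' from the mapping are rejected with reason `no_issn`.
#'
#' @param records Record tibble from [parse_jats_corpus()].
#' @param journal_list Tibble with columns `issn`, `journal_label`.
#' @return List with `records` (labelled tibble, `journal_label` column added)
#'   and `rejections` (tibble `paper_id`, `reason`).
#' @export
resolve_journal_labels <- function(records, journal_list) {
  stopifnot(all(c("issn", "journal_label") %in% names(journal_list)))
  lut <- stats::setNames(journal_list$journal_label, journal_list$issn)
  lab_p <- unname(lut[records$issn_print])
  lab_e <- unname(lut[records$issn_electronic])
  disagree <- !is.na(lab_p) & !is.na(lab_e) & lab_p != lab_e
  if (any(disagree)) {
    abort("print and electronic ISSN map to different journals for some records")
  }
  label <- dplyr::coalesce(lab_p, lab_e)
  out <- dplyr::mutate(records, journal_label = label)
  keep <- !is.na(label)
  list(
    records = out[keep, , drop = FALSE],
    rejections = tibble::tibble(
      paper_id = records$paper_id[!keep],
      reason = rep("no_issn", sum(!keep))
    )
  )
}

#' Apply the corpus inclusion filters
#'
#' Drops papers with short abstracts, papers outside the date range, and then
#' (on the surviving counts) all papers of journals left with fewer than
#' `min_journal_papers` papers. The journal-size filter is applied once, after
#' the per-paper filters, with no fixpoint iteration: a journal at 105 papers
#' of which 10 fail the abstract rule drops to 95 and is removed entirely.
#'
#' @param records Labelled record tibble (needs `journal_label`).
#' @param min_abstract_chars Minimum abstract length (default 200 characters,
#'   counted after whitespace normalisation).
#' @param min_journal_papers Minimum surviving papers per journal (default
#'   100).
#' @param date_start,date_end Inclusive `"YYYY-MM"` bounds (defaults
#'   `"2007-01"` and `"2017-04"`); `NULL` disables the date filter. Records
#'   with no parsable date are treated as out of range.
#' @return List with `records` (kept tibble) and `log` (tibble `paper_id`,
#'   `rule`), satisfying `nrow(records) + nrow(log) == nrow(input)`.
#' @export
filter_corpus <- function(records, min_abstract_chars = 200,
                          min_journal_papers = 100,
                          date_start = "2007-01", date_end = "2017-04") {
  if (nrow(records) == 0) {
    return(list(records = records,
                log = tibble::tibble(paper_id = character(), rule = character())))
  }
  rule <- rep(NA_character_, nrow(records))

  abs_len <- nchar(stringr::str_squish(records$abstract_text))
  rule[is.na(rule) & abs_len < min_abstract_chars] <- "short_abstract"

  if (!is.null(date_start) && !is.null(date_end)) {
    lo <- parse_year_month(date_start)
    hi <- parse_year_month(date_end)
    if (lo > hi) abort("date_start is after date_end")
    ym <- records$pub_year * 12L + (records$pub_month - 1L)
    out_of_range <- is.na(ym) | ym < lo | ym > hi
    rule[is.na(rule) & out_of_range] <- "date_range"
  }

  if ("journal_label" %in% names(records)) {
    rule[is.na(rule) & (is.na(records$journal_label) |
                          records$journal_label == "")] <- "no_issn"
    # journal-size filter runs on the papers that survived the per-paper rules
    surviving <- records$journal_label[is.na(rule)]
    counts <- table(surviving)
    small <- names(counts)[counts < min_journal_papers]
    rule[is.na(rule) & records$journal_label %in% small] <- "small_journal"
  }

  keep <- is.na(rule)
  list(
    records = records[keep, , drop = FALSE],
    log = tibble::tibble(paper_id = records$paper_id[!keep], rule = rule[!keep])
  )
}

parse_year_month <- function(x) {
  parts <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  if (length(parts) != 2 || anyNA(parts) || parts[2] < 1 || parts[2] > 12) {
    abort("dates must be 'YYYY-MM' strings")
  }
  parts[1] * 12L + (parts[2] - 1L)
}

#' Build the journal catalog from a filtered corpus
#'
#' Tabulates papers per journal, assigns each journal a size bin (tiny: up to
#' 400 papers, small: 400 to 2000, medium: 2000 to 10,000, large: above
#' 10,000), and records the ISSN-to-label mapping. Both the print and the
#' electronic ISSN of a journal map to the same label; an ISSN claimed by two
#' journals is an error.
#'
#' @param records Labelled record tibble.
#' @return A list of class `"journal_catalog"` with `journals` (tibble
#'   `journal_label`, `paper_count`, `size_bin`) and `issn_map` (tibble
#'   `issn`, `journal_label`).
#' @export
build_journal_catalog <- function(records) {
  stopifnot("journal_label" %in% names(records))
  journals <- records |>
    dplyr::count(.data$journal_label, name = "paper_count") |>
    dplyr::mutate(size_bin = size_bin_of(.data$paper_count)) |>
    dplyr::arrange(.data$journal_label)

  issn_map <- dplyr::bind_rows(
    dplyr::select(records, issn = "issn_print", "journal_label"),
    dplyr::select(records, issn = "issn_electronic", "journal_label")
  ) |>
    dplyr::filter(!is.na(.data$issn)) |>
    dplyr::distinct()
  dup <- issn_map |>
    dplyr::count(.data$issn) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("ambiguous catalog: ISSN(s) mapped to multiple journals: ",
                 paste(dup$issn, collapse = ", ")))
  }
  structure(list(journals = journals, issn_map = issn_map),
            class = "journal_catalog")
}

#' Journal size bin from a paper count
#'
#' Boundaries are 400, 2000, and 10,000 papers: `tiny` up to 400, `small`
#' 400 to 2000, `medium` 2000 to 10,000, `large` above 10,000. Counts below
#' the 100-paper corpus floor (which the filters normally remove) fall in
#' `tiny`.
#'
#' @param n Integer vector of per-journal paper counts.
#' @return Factor with levels tiny, small, medium, large.
#' @export
size_bin_of <- function(n) {
  cut(n, breaks = c(-Inf, 400, 2000, 10000, Inf),
      labels = c("tiny", "small", "medium", "large"))
}

#' @export
print.journal_catalog <- function(x, ...) {
  cat("<journal_catalog>", nrow(x$journals), "journals,",
      sum(x$journals$paper_count), "papers\n")
  print(table(x$journals$size_bin))
  invisible(x)
}

#' Split a corpus into train / validation / test sets
#'
#' Deterministic for a fixed seed. Subset sizes are `round(fraction * n)` for
#' the train and validation parts, with the remainder forming the test part,
#' so the requested fractions hold to within integer rounding and the three
#' parts are a disjoint cover of the input.
#'
#' @param records Record tibble.
#' @param fractions Length-3 numeric `(train, validation, test)`, positive,
#'   summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed.
#' @return The input tibble with an added factor column `split` (levels
#'   `train`, `validation`, `test`); the seed is attached as attribute
#'   `"split_seed"`.
#' @export
split_corpus <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0)) {
    abort("fractions must be 3 positive numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must sum to 1")
  }
  n <- nrow(records)
  if (n < 3) abort("need at least 3 records to split")
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val >= n) {  # guarantee a non-empty test part
    n_val <- max(1L, n - n_train - 1L)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "validation"
  split[split == ""] <- "test"
  out <- dplyr::mutate(records,
                       split = factor(split, levels = c("train", "validation", "test")))
  attr(out, "split_seed") <- as.integer(seed)
  out
}

#' Write / read paper records as newline-delimited JSON
#'
#' One JSON object per paper; round-trips losslessly through [read_records()].
#'
#' @param records Record tibble.
#' @param path File path.
#' @return `write_records` returns `path` invisibly; `read_records` returns
#'   the record tibble.
#' @export
write_records <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null", digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) return(empty_records())
  rows <- purrr::map(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    obj <- purrr::map(obj, ~ if (is.null(.x)) NA_character_ else .x)
    tibble::as_tibble(obj)
  })
  out <- dplyr::bind_rows(rows)
  out$pub_year <- as.integer(out$pub_year)
  out$pub_month <- as.integer(out$pub_month)
  out
}

#' Write / read a journal catalog as tab-separated text
#'
#' @param catalog A `journal_catalog`.
#' @param path Base file path; `<path>` holds the journal table and
#'   `<path>.issn` the ISSN map.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` a
#'   `journal_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog$journals, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(catalog$issn_map, paste0(path, ".issn"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  journals <- tibble::as_tibble(
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = c("character", "integer", "character"))
  )
  journals$size_bin <- factor(journals$size_bin,
                              levels = c("tiny", "small", "medium", "large"))
  issn_map <- tibble::as_tibble(
    utils::read.table(paste0(path, ".issn"), sep = "\t", header = TRUE,
                      colClasses = "character")
  )
  structure(list(journals = journals, issn_map = issn_map),
            class = "journal_catalog")
}
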