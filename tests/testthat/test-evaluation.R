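test_that("top_n_accuracy counts hits in the first N entries", {
  ranked <- rbind(c("a", "b", "c"))
  expect_equal(top_n_accuracy(ranked, "a", 1), 1)
  ranked2 <- rbind(c("b", "c", "a"))
  expect_equal(top_n_accuracy(ranked2, "a", 1), 0)
  expect_equal(top_n_accuracy(ranked2, "a", 3), 1)
  expect_error(top_n_accuracy(ranked, c("a", "b"), 1), "per sample")
  expect_error(top_n_accuracy(ranked, "a", 4), "outside")
})

test_that("acc@N is non-decreasing in N on random fixtures", {
  withr::with_seed(31, {
    classes <- letters[1:6]
    for (rep in 1:5) {
      ranked <- t(replicate(40, sample(classes)))
      truth <- sample(classes, 40, replace = TRUE)
      accs <- sapply(1:6, function(n) top_n_accuracy(ranked, truth, n))
      expect_true(all(diff(accs) >= 0))
      expect_equal(accs[6], 1)   # full list always contains the truth
    }
  })
})

test_that("confusion counts partition the sample and match enumeration", {
  withr::with_seed(17, {
    classes <- c("x", "y", "z")
    ranked <- t(replicate(6, sample(classes)))
    truth <- sample(classes, 6, replace = TRUE)
  })
  for (n in 1:2) {
    got <- confusion_counts(ranked, truth, n, classes = classes)
    oracle <- enumerate_counts(ranked, truth, n, classes)
    expect_equal(as.data.frame(got), oracle)
    expect_true(all(got$tp + got$fp + got$fn + got$tn == 6))
    # per class, tp + fn equals the true membership count
    expect_equal(got$tp + got$fn,
                 as.integer(table(factor(truth, classes))))
  }
  perfect <- cbind(truth, ranked[, 1])
  cc <- confusion_counts(perfect, truth, 1, classes = classes)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
})

test_that("macro/micro metrics reproduce hand-computed values", {
  counts <- tibble::tibble(class = c("a", "b"),
                           tp = c(3, 1), fp = c(1, 3), fn = c(2, 1),
                           tn = c(10, 10))
  m <- macro_micro_metrics(counts)
  macro <- m[m$average == "macro", ]
  micro <- m[m$average == "micro", ]
  # per-class: a: p=3/4 r=3/5 f1=2/3; b: p=1/4 r=1/2 f1=1/3
  expect_equal(macro$precision, 0.5)
  expect_equal(macro$recall, 0.55)
  expect_equal(macro$f1, 0.5)
  # summed: tp=4 fp=4 fn=3
  expect_equal(micro$precision, 0.5)
  expect_equal(micro$recall, 4 / 7)
  expect_equal(micro$f1, 8 / 15)
})

test_that("all-correct predictions score 1 and zero denominators give 0", {
  truth <- c("a", "b", "a")
  ranked <- cbind(truth, c("b", "a", "b"))
  m <- macro_micro_metrics(confusion_counts(ranked, truth, 1))
  expect_true(all(m$precision == 1 & m$recall == 1 & m$f1 == 1))

  counts <- tibble::tibble(class = c("a", "b"), tp = c(2, 0), fp = c(0, 0),
                           fn = c(0, 1), tn = c(1, 2))
  m2 <- macro_micro_metrics(counts)
  expect_equal(m2$precision[m2$average == "macro"], 0.5)  # b flagged as 0
  expect_equal(attr(m2, "zero_denominator"), "b")
  expect_error(macro_micro_metrics(counts[0, ]), "at least one")
})

test_that("micro precision = recall = F1 = accuracy at N = 1", {
  withr::with_seed(23, {
    classes <- letters[1:5]
    for (rep in 1:5) {
      ranked <- t(replicate(30, sample(classes)))
      truth <- sample(classes, 30, replace = TRUE)
      acc <- top_n_accuracy(ranked, truth, 1)
      micro <- macro_micro_metrics(confusion_counts(ranked, truth, 1)) |>
        dplyr::filter(average == "micro")
      expect_equal(micro$precision, acc)
      expect_equal(micro$recall, acc)
      expect_equal(micro$f1, acc)
    }
  })
})

test_that("stratified accuracy matches hand enumeration on a 2-bin fixture", {
  recs <- toy_records(c(300, 5000))
  catalog <- build_journal_catalog(recs)   # J01 tiny, J02 medium
  truth <- c("J01", "J01", "J01", "J02", "J02")
  ranked <- rbind(
    c("J01", "J02"),  # tiny hit @1
    c("J02", "J01"),  # tiny hit @2 only
    c("J02", "J01"),
    c("J02", "J01"),  # medium hit @1
    c("J01", "J02")   # medium hit @2 only
  )
  s <- stratified_eval(ranked, truth, catalog, n_values = c(1, 2))
  tiny <- s[s$size_bin == "tiny", ]; med <- s[s$size_bin == "medium", ]
  expect_equal(tiny$n_papers, 3); expect_equal(med$n_papers, 2)
  expect_equal(tiny$acc_at_1, 1 / 3); expect_equal(tiny$acc_at_2, 1)
  expect_equal(med$acc_at_1, 1 / 2); expect_equal(med$acc_at_2, 1)
  # partition identity: weighted bin accuracies recover total correct
  expect_equal(sum(s$n_papers * s$acc_at_1),
               sum(ranked[, 1] == truth))
  expect_error(stratified_eval(ranked, c(truth[-1], "J99"), catalog), "size bin")
})

test_that("eval_report bundles accuracy, averages and strata coherently", {
  withr::with_seed(41, {
    classes <- sprintf("J%02d", 1:4)
    ranked <- t(replicate(50, sample(classes)))
    truth <- sample(classes, 50, replace = TRUE)
  })
  rep_ <- eval_report(ranked, truth, n_values = c(1, 2, 3, 4))
  expect_true(all(diff(rep_$accuracy$accuracy) >= 0))
  expect_equal(rep_$accuracy$accuracy[4], 1)
  # macro recall at N = T is 1: every true label is in the full list
  macro4 <- dplyr::filter(rep_$averages, n == 4, average == "macro")
  expect_equal(macro4$recall, 1)
  expect_true(all(dplyr::select(rep_$averages, precision:f1) >= 0 &
                    dplyr::select(rep_$averages, precision:f1) <= 1))
  g <- glance(rep_)
  expect_equal(g$acc_at_1, rep_$accuracy$accuracy[1])
  td <- tidy(rep_)
  expect_true(all(c("accuracy", "macro_f1", "micro_precision") %in% td$metric))
})

test_that("reports serialise to delimited text and JSON", {
  ranked <- rbind(c("a", "b"), c("b", "a"), c("a", "b"))
  rep_ <- eval_report(ranked, c("a", "b", "b"), n_values = c(1, 2))
  dir <- withr::local_tempdir()
  write_eval_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "accuracy.tsv")))
  js <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(js$n_samples, 3)
  expect_equal(js$accuracy$accuracy[1], rep_$accuracy$accuracy[1])
})
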