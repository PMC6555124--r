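# Training engine: the batched pass is checked against the single-sample
# operations, against finite differences, and for determinism.

small_fit_fixture <- function(seed = 1L, n_per_class = 12, n_classes = 3) {
  spec <- short_doc_spec(n_classes, n_per_class, sharpness = 1,
                         vocab_size = 300, seed = seed)
  generate_corpus(spec)$records
}

test_that("batched forward equals conv_valid + maxpool2 + dense by hand", {
  corp <- small_fit_fixture()
  cfg <- tiny_config(3, m = 40, k = 8, max_epochs = 1, seed = 5)
  model <- venue_cnn(corp, config = cfg)
  toks <- tokenize(corp$abstract_text[7])
  s <- encode_sequence(toks, model$vocabulary, m = cfg$m)
  emb_tab <- embedding_table(
    `rownames<-`(model$params$emb, model$vocabulary$token))
  V <- embed_abstract(s, emb_tab, model$vocabulary)

  # hand-composed forward pass through the exported single-sample ops
  A <- V
  for (t in seq_along(cfg$conv_stages)) {
    W <- model$params[[paste0("conv", t, "_W")]]
    b <- model$params[[paste0("conv", t, "_b")]]
    d <- nrow(W) / cfg$conv_stages[[t]][2]
    kerns <- lapply(seq_len(ncol(W)), function(j) matrix(W[, j], nrow = d))
    C <- conv_valid(A, kerns, biases = b, activation = "relu")
    A <- apply(C, 2, maxpool2)
  }
  f <- as.vector(A)
  relu <- function(x) pmax(x, 0)
  h1 <- relu(f %*% model$params$fc1_W + model$params$fc1_b)
  h2 <- relu(h1 %*% model$params$fc2_W + model$params$fc2_b)
  z_hand <- as.vector(h2 %*% model$params$out_W + model$params$out_b)

  got <- cnn_forward(model, V)
  expect_equal(unname(got$z), z_hand, tolerance = 1e-10)
  expect_equal(sum(got$S), 1, tolerance = 1e-9)
  expect_true(all(got$S >= 0 & got$S < 1))
})

test_that("analytic gradients match central finite differences", {
  cfg <- venue_cnn_config(
    n_classes = 3, m = 24, k = 3,
    conv_stages = list(c(3, 2), c(3, 2), c(2, 2)),
    hidden_sizes = c(4, 3), dropout_rate = 0,      # deterministic pass
    l2_coefficient = 1e-3, batch_size = 4, seed = 2
  )
  withr::with_seed(11, {
    emb <- matrix(rnorm(9 * cfg$k, sd = 0.3), 9, cfg$k)
    params <- venuecast:::init_params(cfg, emb)
    params$out_W[] <- rnorm(length(params$out_W), sd = 0.2)
    # move every bias off zero so no ReLU sits exactly at its kink,
    # where the loss is not differentiable and finite differences disagree
    for (nm in grep("_b$", names(params), value = TRUE)) {
      params[[nm]][] <- rnorm(length(params[[nm]]), sd = 0.1)
    }
    ids <- matrix(sample(0:9, 4 * cfg$m, replace = TRUE), 4, cfg$m)
    y <- sample(3, 4, replace = TRUE)
  })
  loss_at <- function(p) {
    A0 <- venuecast:::embed_batch(ids, p$emb)
    venuecast:::backward_pass(p, cfg, A0, y)$loss
  }
  A0 <- venuecast:::embed_batch(ids, params$emb)
  bp <- venuecast:::backward_pass(params, cfg, A0, y)
  bp$grads$emb <- venuecast:::embedding_grad(bp$dA0, ids, nrow(params$emb))

  eps <- 1e-5
  withr::with_seed(3, {
    for (nm in names(bp$grads)) {
      idx <- sample(length(params[[nm]]), min(5, length(params[[nm]])))
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_equal(bp$grads[[nm]][i], num, tolerance = 1e-5,
                     label = paste("grad", nm, i))
      }
    }
  })
})

test_that("a zero-initialised softmax head starts at loss log(T)", {
  cfg <- tiny_config(4, m = 40, k = 6, dropout_rate = 0, l2_coefficient = 0)
  withr::with_seed(7, {
    params <- venuecast:::init_params(cfg, matrix(rnorm(50 * 6, sd = 0.2), 50, 6))
    ids <- matrix(sample(0:50, 8 * 40, replace = TRUE), 8, 40)
    A0 <- venuecast:::embed_batch(ids, params$emb)
    bp <- venuecast:::backward_pass(params, cfg, A0, sample(4, 8, TRUE))
  })
  expect_equal(bp$loss, log(4), tolerance = 1e-12)
})

test_that("training is reproducible and loss decreases on separable data", {
  corp <- small_fit_fixture(seed = 3)
  cfg <- tiny_config(3, max_epochs = 8, seed = 9)
  m1 <- venue_cnn(corp, config = cfg)
  m2 <- venue_cnn(corp, config = cfg)
  expect_equal(m1$history$loss, m2$history$loss, tolerance = 1e-12)
  expect_equal(m1$params$fc1_W, m2$params$fc1_W, tolerance = 1e-12)
  expect_lt(dplyr::last(m1$history$loss), m1$history$loss[1])
})

test_that("dropout is off at inference: repeated passes are identical", {
  corp <- small_fit_fixture(seed = 4)
  model <- venue_cnn(corp, config = tiny_config(3, max_epochs = 2, seed = 1))
  p1 <- predict(model, corp[1:5, ], type = "prob")
  p2 <- predict(model, corp[1:5, ], type = "prob")
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 5), tolerance = 1e-9)
})

test_that("config / label mismatch and empty training sets are errors", {
  corp <- small_fit_fixture()
  expect_error(venue_cnn(corp, config = tiny_config(7)), "classes")
  vocab <- tibble::tibble(token = "a", id = 1L)
  expect_error(
    fit_venue_cnn(matrix(integer(0), 0, 60), factor(character(), "x"),
                  tiny_config(2, m = 60), vocab),
    "classes|empty"
  )
})

test_that("checkpoints round-trip weights, config and vocabulary", {
  corp <- small_fit_fixture(seed = 6)
  model <- venue_cnn(corp, config = tiny_config(3, max_epochs = 2, seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(predict(back, corp[1:4, ], type = "prob"),
               predict(model, corp[1:4, ], type = "prob"))
  expect_equal(back$labels, model$labels)
  # tampering with the vocabulary breaks the hash check
  obj <- readRDS(path)
  obj$vocabulary$token[1] <- "tampered"
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "hash")
})

test_that("tidy and glance summarise the fit", {
  corp <- small_fit_fixture(seed = 8)
  model <- venue_cnn(corp, config = tiny_config(3, max_epochs = 3, seed = 2))
  td <- tidy(model)
  expect_setequal(unique(td$metric), c("loss", "accuracy"))
  g <- glance(model)
  expect_equal(g$epochs, 3L)
  expect_equal(g$n_classes, 3L)
  expect_gt(g$n_parameters, 0)
})
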