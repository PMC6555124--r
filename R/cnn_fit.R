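# Batched forward/backward pass and Adam training for the three-stage
# convolutional abstract classifier. Minibatches are processed as
# (batch, position, channel) arrays; each convolution stage is one im2col
# matrix product, so the heavy lifting stays inside BLAS.

# ---- parameter initialisation -------------------------------------------

init_params <- function(cfg, emb) {
  plan <- cfg$plan
  params <- list(emb = emb)
  d_prev <- cfg$k
  for (t in seq_along(cfg$conv_stages)) {
    r <- cfg$conv_stages[[t]][1]; h <- cfg$conv_stages[[t]][2]
    fan_in <- h * d_prev
    params[[paste0("conv", t, "_W")]] <-
      matrix(rnorm(fan_in * r, sd = sqrt(2 / fan_in)), fan_in, r)
    params[[paste0("conv", t, "_b")]] <- numeric(r)
    d_prev <- r
  }
  feat <- if (cfg$global_max_pool) d_prev else attr(plan, "feature_size")
  h1 <- cfg$hidden_sizes[1]; h2 <- cfg$hidden_sizes[2]
  params$fc1_W <- matrix(rnorm(feat * h1, sd = sqrt(2 / feat)), feat, h1)
  params$fc1_b <- numeric(h1)
  params$fc2_W <- matrix(rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2)
  params$fc2_b <- numeric(h2)
  # zero-initialised softmax head: epoch-0 loss is exactly log(T)
  params$out_W <- matrix(0, h2, cfg$n_classes)
  params$out_b <- numeric(cfg$n_classes)
  params
}

l2_weight_names <- function(params) {
  c(grep("^conv[0-9]+_W$", names(params), value = TRUE),
    "fc1_W", "fc2_W", "out_W")
}

# ---- batched array plumbing ---------------------------------------------

# ids: B x m integer matrix -> (B, m, k) embedding array
embed_batch <- function(ids, emb) {
  B <- nrow(ids); m <- ncol(ids); k <- ncol(emb)
  flat <- as.vector(ids)              # (b, pos) pairs, b fastest
  X <- matrix(0, B * m, k)
  nz <- flat > 0L
  if (any(nz)) X[nz, ] <- emb[flat[nz], , drop = FALSE]
  dim(X) <- c(B, m, k)
  X
}

# (B, L, d) -> (B*Lc) x (h*d), offset-major column blocks
im2col_batch <- function(A, h) {
  B <- dim(A)[1]; L <- dim(A)[2]; d <- dim(A)[3]
  Lc <- L - h + 1L
  do.call(cbind, lapply(seq_len(h), function(j) {
    blk <- A[, j:(j + Lc - 1L), , drop = FALSE]
    dim(blk) <- c(B * Lc, d)
    blk
  }))
}

col2im_batch <- function(dX, B, L, d, h) {
  Lc <- L - h + 1L
  dA <- array(0, c(B, L, d))
  for (j in seq_len(h)) {
    blk <- dX[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
    dim(blk) <- c(B, Lc, d)
    dA[, j:(j + Lc - 1L), ] <- dA[, j:(j + Lc - 1L), , drop = FALSE] + blk
  }
  dA
}

# ---- forward / backward --------------------------------------------------

# A0: (B, m, k) input array. Returns logits and (optionally) caches for the
# backward pass. Dropout masks are drawn from the current RNG stream only in
# training mode, so inference is exactly reproducible.
forward_pass <- function(params, cfg, A0, training = FALSE, keep_cache = FALSE) {
  B <- dim(A0)[1]
  A <- A0
  stages <- list()
  for (t in seq_along(cfg$conv_stages)) {
    h <- cfg$conv_stages[[t]][2]; r <- cfg$conv_stages[[t]][1]
    L <- dim(A)[2]; d <- dim(A)[3]
    X <- im2col_batch(A, h)
    Z <- X %*% params[[paste0("conv", t, "_W")]]
    Z <- Z + matrix(params[[paste0("conv", t, "_b")]], nrow(Z), r, byrow = TRUE)
    relu_mask <- Z > 0
    Z[!relu_mask] <- 0
    Lc <- L - h + 1L
    dim(Z) <- c(B, Lc, r)
    Lp <- Lc %/% 2L
    i1 <- seq(1L, 2L * Lp, by = 2L)
    H1 <- Z[, i1, , drop = FALSE]
    H2 <- Z[, i1 + 1L, , drop = FALSE]
    pool_mask <- H1 >= H2          # ties take the earlier position
    P <- pmax(H1, H2)
    stages[[t]] <- if (keep_cache) {
      list(X = X, relu_mask = relu_mask, pool_mask = pool_mask,
           L = L, d = d, Lc = Lc, Lp = Lp)
    } else {
      list(Lp = Lp)
    }
    A <- P
  }
  Lp3 <- dim(A)[2]; r3 <- dim(A)[3]
  if (cfg$global_max_pool) {
    Fm <- A[, 1L, ]; dim(Fm) <- c(B, r3)
    arg <- matrix(1L, B, r3)
    if (Lp3 > 1L) {
      for (i in 2:Lp3) {
        cur <- A[, i, ]; dim(cur) <- c(B, r3)
        upd <- cur > Fm
        Fm[upd] <- cur[upd]
        arg[upd] <- i
      }
    }
    gmp <- list(arg = arg, Lp = Lp3, r = r3)
  } else {
    Fm <- A
    dim(Fm) <- c(B, Lp3 * r3)
    gmp <- NULL
  }

  keep <- 1 - cfg$dropout_rate
  drop_mask <- function(nr, nc) {
    if (training && cfg$dropout_rate > 0) {
      matrix((runif(nr * nc) < keep) / keep, nr, nc)
    } else {
      NULL
    }
  }
  H1p <- Fm %*% params$fc1_W
  H1p <- H1p + matrix(params$fc1_b, B, ncol(H1p), byrow = TRUE)
  m1 <- H1p > 0; H1a <- H1p; H1a[!m1] <- 0
  d1 <- drop_mask(B, ncol(H1a)); if (!is.null(d1)) H1a <- H1a * d1
  H2p <- H1a %*% params$fc2_W
  H2p <- H2p + matrix(params$fc2_b, B, ncol(H2p), byrow = TRUE)
  m2 <- H2p > 0; H2a <- H2p; H2a[!m2] <- 0
  d2 <- drop_mask(B, ncol(H2a)); if (!is.null(d2)) H2a <- H2a * d2
  logits <- H2a %*% params$out_W
  logits <- logits + matrix(params$out_b, B, ncol(logits), byrow = TRUE)

  cache <- if (keep_cache) {
    list(stages = stages, Fm = Fm, gmp = gmp,
         m1 = m1, d1 = d1, H1a = H1a, m2 = m2, d2 = d2, H2a = H2a,
         B = B, Lp3 = Lp3, r3 = r3)
  }
  list(logits = logits, cache = cache)
}

# Cross-entropy (+ L2) loss and gradients for one minibatch.
backward_pass <- function(params, cfg, A0, y, sample_w = NULL) {
  fw <- forward_pass(params, cfg, A0, training = TRUE, keep_cache = TRUE)
  logits <- fw$logits; cache <- fw$cache
  B <- cache$B; T_ <- cfg$n_classes
  lse <- row_logsumexp(logits)
  z_true <- logits[cbind(seq_len(B), y)]
  losses <- lse - z_true
  if (is.null(sample_w)) {
    data_loss <- mean(losses)
    wnorm <- rep(1 / B, B)
  } else {
    wnorm <- sample_w / sum(sample_w)
    data_loss <- sum(losses * wnorm)
  }
  l2 <- cfg$l2_coefficient
  wnames <- l2_weight_names(params)
  penalty <- if (l2 > 0) l2 / 2 * sum(purrr::map_dbl(params[wnames], ~ sum(.x^2))) else 0
  loss <- data_loss + penalty

  probs <- exp(logits - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits * wnorm

  grads <- list()
  grads$out_W <- crossprod(cache$H2a, dlogits)
  grads$out_b <- colSums(dlogits)
  dH2a <- tcrossprod(dlogits, params$out_W)
  if (!is.null(cache$d2)) dH2a <- dH2a * cache$d2
  dH2p <- dH2a * cache$m2
  grads$fc2_W <- crossprod(cache$H1a, dH2p)
  grads$fc2_b <- colSums(dH2p)
  dH1a <- tcrossprod(dH2p, params$fc2_W)
  if (!is.null(cache$d1)) dH1a <- dH1a * cache$d1
  dH1p <- dH1a * cache$m1
  grads$fc1_W <- crossprod(cache$Fm, dH1p)
  grads$fc1_b <- colSums(dH1p)
  dFm <- tcrossprod(dH1p, params$fc1_W)

  if (cfg$global_max_pool) {
    g <- cache$gmp
    dP <- array(0, c(B, g$Lp, g$r))
    idx <- cbind(rep(seq_len(B), times = g$r),
                 as.vector(g$arg),
                 rep(seq_len(g$r), each = B))
    dP[idx] <- as.vector(dFm)
  } else {
    dP <- dFm
    dim(dP) <- c(B, cache$Lp3, cache$r3)
  }

  for (t in rev(seq_along(cfg$conv_stages))) {
    st <- cache$stages[[t]]
    r <- cfg$conv_stages[[t]][1]; h <- cfg$conv_stages[[t]][2]
    dZ <- array(0, c(B, st$Lc, r))
    i1 <- seq(1L, 2L * st$Lp, by = 2L)
    dZ[, i1, ] <- dP * st$pool_mask
    dZ[, i1 + 1L, ] <- dP * !st$pool_mask
    dim(dZ) <- c(B * st$Lc, r)
    dZ <- dZ * st$relu_mask
    wname <- paste0("conv", t, "_W")
    grads[[wname]] <- crossprod(st$X, dZ)
    grads[[paste0("conv", t, "_b")]] <- colSums(dZ)
    dX <- tcrossprod(dZ, params[[wname]])
    dP <- col2im_batch(dX, B, st$L, st$d, h)
  }

  if (l2 > 0) {
    for (w in wnames) grads[[w]] <- grads[[w]] + l2 * params[[w]]
  }

  acc_hits <- max.col(logits, ties.method = "first") == y
  list(loss = loss, grads = grads, dA0 = dP, n_correct = sum(acc_hits))
}

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  lr_t <- cfg$learning_rate *
    sqrt(1 - cfg$beta2^state$t) / (1 - cfg$beta1^state$t)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr_t * state$m[[nm]] / (sqrt(state$v[[nm]]) + cfg$epsilon)
  }
  list(params = params, state = state)
}

# ---- fitting -------------------------------------------------------------

#' Fit the convolutional abstract classifier on encoded sequences
#'
#' Low-level trainer: takes an integer id matrix and class labels and runs
#' minibatch Adam on the L2-regularised cross-entropy. Deterministic for a
#' fixed `config$seed` under single-threaded execution. Training aborts with
#' a diagnostic if the loss diverges to a non-finite value.
#'
#' @param x Integer matrix, one row per document, `config$m` columns of token
#'   ids (0 = padding / out-of-vocabulary).
#' @param y Class labels: factor, character, or integers `1..T`.
#' @param config A [venue_cnn_config()]; its `n_classes` must match the
#'   labels.
#' @param vocabulary Vocabulary tibble used for encoding (stored on the model
#'   for later queries).
#' @param embeddings Optional [embedding_table()] of pretrained vectors; when
#'   `NULL`, embeddings are randomly initialised. Fine-tuned during training
#'   unless `config$embedding_trainable` is `FALSE`.
#' @param validation Optional list with elements `x`, `y` scored after each
#'   epoch.
#' @param verbose Print per-epoch progress?
#' @return Object of class `"venue_cnn"`: parameters, config, vocabulary,
#'   label set, and a per-epoch `history` tibble (`epoch`, `loss`,
#'   `accuracy`, and validation columns when supplied).
#' @seealso [venue_cnn()] for the data-frame interface, [predict.venue_cnn()]
#' @export
fit_venue_cnn <- function(x, y, config, vocabulary, embeddings = NULL,
                          validation = NULL, verbose = FALSE) {
  stopifnot(is.matrix(x), ncol(x) == config$m)
  labels <- label_levels(y)
  y_int <- match(as.character(y), labels)
  if (length(labels) != config$n_classes) {
    abort(sprintf("config declares %d classes but the labels contain %d",
                  config$n_classes, length(labels)))
  }
  if (nrow(x) == 0) abort("training set is empty")
  if (!is.null(validation)) {
    val_y <- match(as.character(validation$y), labels)
    if (anyNA(val_y)) abort("validation labels outside the training label set")
  }

  class_w <- if (config$class_weighting == "inverse_frequency") {
    freq <- tabulate(y_int, nbins = config$n_classes)
    w <- sum(freq) / (config$n_classes * pmax(freq, 1))
    w
  }

  withr::with_seed(config$seed, {
    emb0 <- if (is.null(embeddings)) {
      matrix(runif(nrow(vocabulary) * config$k, -0.5, 0.5) / config$k,
             nrow(vocabulary), config$k)
    } else {
      check_k(embeddings$k, config$k)
      align_embeddings(embeddings, vocabulary)
    }
    params <- init_params(config, emb0)
    state <- adam_init(params)
    n <- nrow(x)
    hist_rows <- list()
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        ids <- x[idx, , drop = FALSE]
        A0 <- embed_batch(ids, params$emb)
        sw <- if (!is.null(class_w)) class_w[y_int[idx]]
        bp <- backward_pass(params, config, A0, y_int[idx], sample_w = sw)
        if (!is.finite(bp$loss)) {
          abort(sprintf("training diverged: non-finite loss at epoch %d", epoch))
        }
        if (config$embedding_trainable) {
          bp$grads$emb <- embedding_grad(bp$dA0, ids, nrow(params$emb))
        }
        upd <- adam_step(params, bp$grads, state, config)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + bp$loss * length(idx)
        ep_correct <- ep_correct + bp$n_correct
      }
      row <- tibble::tibble(epoch = epoch, loss = ep_loss / n,
                            accuracy = ep_correct / n)
      if (!is.null(validation)) {
        vs <- score_ids(params, config, validation$x)
        v_lse <- row_logsumexp(vs)
        row$val_loss <- mean(v_lse - vs[cbind(seq_len(nrow(vs)), val_y)])
        row$val_accuracy <- mean(max.col(vs, ties.method = "first") == val_y)
      }
      hist_rows[[epoch]] <- row
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f  acc %.4f\n",
                    epoch, row$loss, row$accuracy))
      }
      if (!is.null(config$stop_at_train_acc) &&
          row$accuracy >= config$stop_at_train_acc) break
    }
    structure(
      list(params = params, config = config, vocabulary = vocabulary,
           labels = labels, history = dplyr::bind_rows(hist_rows),
           plan = config$plan),
      class = "venue_cnn"
    )
  })
}

label_levels <- function(y) {
  if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
}

embedding_grad <- function(dA0, ids, n_rows) {
  B <- dim(dA0)[1]; m <- dim(dA0)[2]; k <- dim(dA0)[3]
  dmat <- dA0
  dim(dmat) <- c(B * m, k)
  flat <- as.vector(ids)
  nz <- flat > 0L
  demb <- matrix(0, n_rows, k)
  if (any(nz)) {
    agg <- rowsum(dmat[nz, , drop = FALSE], group = flat[nz])
    demb[as.integer(rownames(agg)), ] <- agg
  }
  demb
}

# class-score logits for an id matrix, inference mode, batched
score_ids <- function(params, cfg, x, batch_size = 256L) {
  n <- nrow(x)
  out <- matrix(0, n, cfg$n_classes)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    A0 <- embed_batch(x[idx, , drop = FALSE], params$emb)
    out[idx, ] <- forward_pass(params, cfg, A0, training = FALSE)$logits
  }
  out
}

#' Fit the venue classifier from a paper-record table
#'
#' Data-frame front end: tokenizes `abstract_text`, builds (or reuses) a
#' vocabulary, encodes to length `config$m`, and calls [fit_venue_cnn()].
#' Labels come from `journal_label`.
#'
#' @param data Tibble with columns `abstract_text` and `journal_label`.
#' @param config A [venue_cnn_config()]; when `NULL` a default configuration
#'   is built for the observed number of journals.
#' @param vocabulary Optional vocabulary tibble; built from `data` when
#'   `NULL`.
#' @param embeddings Optional pretrained [embedding_table()].
#' @param validation Optional tibble with the same columns, scored per epoch.
#' @param verbose Print progress?
#' @return A fitted `"venue_cnn"` model.
#' @export
venue_cnn <- function(data, config = NULL, vocabulary = NULL,
                      embeddings = NULL, validation = NULL, verbose = FALSE) {
  stopifnot(all(c("abstract_text", "journal_label") %in% names(data)))
  labels <- sort(unique(as.character(data$journal_label)))
  if (is.null(config)) config <- venue_cnn_config(n_classes = length(labels))
  tokens <- purrr::map(data$abstract_text, tokenize)
  if (is.null(vocabulary)) vocabulary <- build_vocabulary(tokens)
  x <- encode_corpus(tokens, vocabulary, m = config$m)$ids
  val <- NULL
  if (!is.null(validation)) {
    vtok <- purrr::map(validation$abstract_text, tokenize)
    val <- list(x = encode_corpus(vtok, vocabulary, m = config$m)$ids,
                y = factor(validation$journal_label, levels = labels))
  }
  fit_venue_cnn(x, factor(data$journal_label, levels = labels), config,
                vocabulary = vocabulary, embeddings = embeddings,
                validation = val, verbose = verbose)
}

#' @export
print.venue_cnn <- function(x, ...) {
  n_par <- sum(purrr::map_int(x$params, length))
  cat("<venue_cnn>", x$config$n_classes, "classes,",
      format(n_par, big.mark = ","), "parameters\n")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, accuracy %.4f\n",
                last$epoch, last$loss, last$accuracy))
  }
  invisible(x)
}

#' Class scores for a single abstract matrix
#'
#' Runs one `m x k` input through the network in inference mode (dropout
#' off): three convolution / pooling stages, dense head, softmax.
#'
#' @param model A fitted `"venue_cnn"`.
#' @param V Numeric `m x k` matrix (e.g. from [embed_abstract()]).
#' @param training_mode Apply dropout (training behaviour)?
#' @return List with `z` (pre-softmax scores, length `T`) and `S`
#'   (probabilities summing to 1).
#' @export
cnn_forward <- function(model, V, training_mode = FALSE) {
  cfg <- model$config
  if (!is.matrix(V) || nrow(V) != cfg$m || ncol(V) != cfg$k) {
    abort(sprintf("V must be a %d x %d matrix", cfg$m, cfg$k))
  }
  A0 <- array(V, c(1L, cfg$m, cfg$k))
  # array(V) with B=1 keeps (position, channel) layout: element (1, i, c)
  A0[1, , ] <- V
  z <- as.vector(forward_pass(model$params, cfg, A0,
                              training = training_mode)$logits)
  names(z) <- model$labels
  list(z = z, S = softmax(z))
}

#' Predict journal probabilities, classes, or full rankings
#'
#' @param object A fitted `"venue_cnn"`.
#' @param newdata Tibble with `abstract_text`, or an integer id matrix
#'   encoded with the model's vocabulary.
#' @param type `"prob"` (n x T probability matrix), `"class"` (top-1 label
#'   vector), or `"rank"` (n x T character matrix of labels by decreasing
#'   probability, ties broken by ascending label).
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.venue_cnn <- function(object, newdata,
                              type = c("prob", "class", "rank"),
                              batch_size = 256L, ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) {
    newdata
  } else {
    toks <- purrr::map(newdata$abstract_text, tokenize)
    encode_corpus(toks, object$vocabulary, m = object$config$m)$ids
  }
  logits <- score_ids(object$params, object$config, x, batch_size)
  probs <- softmax(logits)
  colnames(probs) <- object$labels
  switch(type,
    prob = probs,
    class = object$labels[max.col(probs, ties.method = "first")],
    rank = rank_label_matrix(probs, object$labels)
  )
}

rank_label_matrix <- function(probs, labels) {
  t(apply(probs, 1, function(p) labels[order(-p, labels)]))
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint carries a versioned header, the full configuration, all
#' weights, the vocabulary and a vocabulary hash; loading verifies the format
#' and version.
#'
#' @param model A fitted `"venue_cnn"`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint` the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    format = "venue_cnn-checkpoint", version = 1L,
    config = model$config, params = model$params,
    vocabulary = model$vocabulary,
    vocab_hash = rlang::hash(model$vocabulary$token),
    labels = model$labels, history = model$history
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "venue_cnn-checkpoint")) {
    abort("not a venue_cnn checkpoint file")
  }
  if (!identical(obj$version, 1L)) {
    abort(sprintf("unsupported checkpoint version %s", obj$version))
  }
  if (!identical(obj$vocab_hash, rlang::hash(obj$vocabulary$token))) {
    abort("checkpoint vocabulary hash mismatch (corrupt file?)")
  }
  structure(
    list(params = obj$params, config = obj$config,
         vocabulary = obj$vocabulary, labels = obj$labels,
         history = obj$history, plan = obj$config$plan),
    class = "venue_cnn"
  )
}
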