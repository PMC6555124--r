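# Network configuration and the pure shape arithmetic for the three-stage
# convolution / pooling stack.

#' Configuration of the abstract-classification network
#'
#' Defaults follow the reference architecture: a 350 x 200 input (350 tokens,
#' 200-dimensional word vectors), three convolution stages with 256/128/96
#' kernels of window 3/4/5, ReLU activations, width-2 stride-2 max pooling,
#' dropout 0.2 on the dense layers, and a fully connected (512) + hidden
#' (256) + softmax head trained with Adam on the L2-regularised
#' cross-entropy.
#'
#' @param n_classes Number of journals `T`.
#' @param m Input sequence length (default 350).
#' @param k Word-vector dimension (default 200).
#' @param conv_stages List of `c(kernel_count, window)` pairs, one per stage
#'   (default `list(c(256, 3), c(128, 4), c(96, 5))`).
#' @param pool_window,pool_stride Max-pooling geometry (both fixed at 2; other
#'   values are rejected).
#' @param dropout_rate Dropout probability on dense-layer activations
#'   (default 0.2), active only in training mode.
#' @param l2_coefficient L2 penalty coefficient on convolution and dense
#'   weights (default 1e-4).
#' @param hidden_sizes Widths of the fully connected and hidden layers
#'   (default `c(512, 256)`).
#' @param learning_rate,beta1,beta2,epsilon Adam settings.
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Training epochs (default 10).
#' @param embedding_trainable Fine-tune word vectors during training
#'   (default `TRUE`)?
#' @param global_max_pool Reduce the third stage to one value per kernel
#'   instead of flattening all positions (default `FALSE`, i.e. flatten)?
#' @param class_weighting `"none"` (default; train on the raw imbalanced
#'   corpus) or `"inverse_frequency"`.
#' @param stop_at_train_acc Optional early-stop threshold on training
#'   accuracy.
#' @param seed Integer seed governing initialisation, shuffling and dropout.
#' @return Object of class `"venue_cnn_config"`. Construction fails if any
#'   stage's feature map would collapse (see [layer_length_plan()]).
#' @export
venue_cnn_config <- function(n_classes,
                             m = 350L, k = 200L,
                             conv_stages = list(c(256L, 3L), c(128L, 4L), c(96L, 5L)),
                             pool_window = 2L, pool_stride = 2L,
                             dropout_rate = 0.2,
                             l2_coefficient = 1e-4,
                             hidden_sizes = c(512L, 256L),
                             learning_rate = 1e-3,
                             beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                             batch_size = 64L, max_epochs = 10L,
                             embedding_trainable = TRUE,
                             global_max_pool = FALSE,
                             class_weighting = c("none", "inverse_frequency"),
                             stop_at_train_acc = NULL,
                             seed = 1L) {
  stopifnot(n_classes >= 2, m >= 1, k >= 1, length(hidden_sizes) == 2,
            all(hidden_sizes >= 1), dropout_rate >= 0, dropout_rate < 1,
            l2_coefficient >= 0)
  if (pool_window != 2L || pool_stride != 2L) {
    abort("only pool_window = 2 with pool_stride = 2 is supported")
  }
  cfg <- structure(
    list(
      n_classes = as.integer(n_classes), m = as.integer(m), k = as.integer(k),
      conv_stages = purrr::map(conv_stages, as.integer),
      pool_window = 2L, pool_stride = 2L,
      dropout_rate = dropout_rate, l2_coefficient = l2_coefficient,
      hidden_sizes = as.integer(hidden_sizes),
      learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
      epsilon = epsilon,
      batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
      embedding_trainable = isTRUE(embedding_trainable),
      global_max_pool = isTRUE(global_max_pool),
      class_weighting = match.arg(class_weighting),
      stop_at_train_acc = stop_at_train_acc,
      seed = as.integer(seed)
    ),
    class = "venue_cnn_config"
  )
  cfg$plan <- layer_length_plan(cfg)   # validates the geometry
  cfg
}

#' Per-stage feature-map lengths of the convolution / pooling stack
#'
#' Pure arithmetic: stage `t` with window `h_t` maps an input of length
#' `L_{t-1}` to a convolution output of `L_{t-1} - h_t + 1` positions
#' ("valid" convolution) and then halves it by width-2 stride-2 max pooling,
#' dropping a trailing unpaired element (`floor(L/2)`). Errors, naming the
#' offending stage, as soon as a convolution no longer fits or a feature map
#' is too short to pool.
#'
#' @param config A `venue_cnn_config`, or a plain list with elements `m` and
#'   `conv_stages`.
#' @return Tibble with columns `stage`, `kernels`, `window`, `conv_len`,
#'   `pooled_len`; the flattened feature width is attached as attribute
#'   `"feature_size"`.
#' @export
#' @examples
#' cfg <- venue_cnn_config(n_classes = 10)
#' layer_length_plan(cfg)  # (348,174), (171,85), (81,40)
layer_length_plan <- function(config) {
  L <- as.integer(config$m)
  stages <- config$conv_stages
  out <- vector("list", length(stages))
  for (t in seq_along(stages)) {
    r <- stages[[t]][1]; h <- stages[[t]][2]
    if (r < 1 || h < 1) abort(sprintf("stage %d: kernel count and window must be positive", t))
    conv_len <- L - h + 1L
    if (conv_len < 1L) {
      abort(sprintf(
        "stage %d: window %d does not fit an input of length %d (conv length would be %d)",
        t, h, L, conv_len))
    }
    if (conv_len < 2L) {
      abort(sprintf(
        "stage %d: feature map of length %d is too short for width-2 max pooling",
        t, conv_len))
    }
    pooled <- conv_len %/% 2L
    out[[t]] <- tibble::tibble(stage = t, kernels = r, window = h,
                               conv_len = conv_len, pooled_len = pooled)
    L <- pooled
  }
  plan <- dplyr::bind_rows(out)
  r_last <- stages[[length(stages)]][1]
  attr(plan, "feature_size") <- as.integer(r_last * L)
  plan
}

#' @export
print.venue_cnn_config <- function(x, ...) {
  cat("<venue_cnn_config>", x$n_classes, "classes, input", x$m, "x", x$k, "\n")
  stages <- purrr::map_chr(x$conv_stages,
                           ~ sprintf("%d kernels, window %d", .x[1], .x[2]))
  cat(paste0("  stage ", seq_along(stages), ": ", stages, collapse = "\n"), "\n")
  cat("  head:", paste(x$hidden_sizes, collapse = " -> "), "->",
      x$n_classes, if (x$global_max_pool) "(global max pool)" else "(flatten)", "\n")
  invisible(x)
}
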