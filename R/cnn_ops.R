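# Elementary network operations: valid 1-D convolution over a token-by-channel
# matrix, width-2 max pooling, numerically stable softmax, and the
# cross-entropy loss. These are the single-sample reference surfaces; training
# runs the same arithmetic batched (see cnn_fit.R).

#' Valid 1-D convolution with per-kernel feature maps
#'
#' Position `i` of feature map `j` is the elementwise product of kernel `j`
#' with input rows `i .. i+h-1`, summed, plus the bias, passed through the
#' activation. No padding: the output has `L - h + 1` positions.
#'
#' @param input Numeric matrix `L x d` (positions by channels).
#' @param kernels List of `d x h` numeric matrices (channels by window), or a
#'   single such matrix.
#' @param biases Numeric vector, one per kernel (recycled from a scalar).
#' @param activation `"relu"` or `"identity"`.
#' @return Numeric matrix `(L - h + 1) x length(kernels)`; one feature map
#'   per column.
#' @export
conv_valid <- function(input, kernels, biases = 0, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (is.matrix(kernels)) kernels <- list(kernels)
  d <- ncol(input); L <- nrow(input)
  h <- ncol(kernels[[1]])
  ok <- purrr::map_lgl(kernels, ~ is.matrix(.x) && nrow(.x) == d && ncol(.x) == h)
  if (!all(ok)) abort("all kernels must be d x h matrices matching the input channels")
  if (L < h) abort(sprintf("input length %d is shorter than the window %d", L, h))
  W <- vapply(kernels, as.vector, numeric(d * h))   # (h*d) x r, offset-major
  X <- im2col(input, h)
  Z <- X %*% W
  Z <- Z + matrix(rep(biases, length.out = ncol(Z)), nrow(Z), ncol(Z), byrow = TRUE)
  if (activation == "relu") Z[Z < 0] <- 0
  Z
}

# (L-h+1) x (h*d) matrix whose row i concatenates input rows i..i+h-1
# (channel-fastest within each offset block).
im2col <- function(input, h) {
  L <- nrow(input)
  Lc <- L - h + 1L
  do.call(cbind, lapply(seq_len(h), function(j) {
    input[j:(j + Lc - 1L), , drop = FALSE]
  }))
}

#' Width-2, stride-2 max pooling of a feature map
#'
#' Output `i` is the maximum of elements `2i-1` and `2i`; a trailing unpaired
#' element of an odd-length map is dropped, so the output length is
#' `floor(L/2)`.
#'
#' @param feature_map Numeric vector of length `L >= 2`, or a matrix pooled
#'   column-wise.
#' @return Vector (or matrix) of length `floor(L/2)`.
#' @export
#' @examples
#' maxpool2(c(1, 3, 2, 5))  # 3 5
maxpool2 <- function(feature_map) {
  if (is.matrix(feature_map)) {
    return(apply(feature_map, 2, maxpool2))
  }
  L <- length(feature_map)
  if (L < 2) abort("max pooling needs a feature map of length >= 2")
  Lp <- L %/% 2L
  pmax(feature_map[seq(1L, 2L * Lp, by = 2L)],
       feature_map[seq(2L, 2L * Lp, by = 2L)])
}

#' Numerically stable softmax
#'
#' Computed with max-subtraction so that large score magnitudes do not
#' overflow. For a matrix, rows are treated as independent score vectors.
#'
#' @param z Numeric vector of class scores, or a matrix of row vectors.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    mx <- apply(z, 1, max)
    e <- exp(z - mx)
    return(e / rowSums(e))
  }
  e <- exp(z - max(z))
  e / sum(e)
}

# log(sum(exp(z))) per row, stable.
row_logsumexp <- function(z) {
  mx <- apply(z, 1, max)
  mx + log(rowSums(exp(z - mx)))
}

#' Cross-entropy loss with optional L2 penalty
#'
#' The negative log of the probability the prediction assigns to the true
#' class, plus `l2_coefficient / 2` times the summed squares of any supplied
#' weight arrays. With a matrix of predictions the per-sample losses are
#' averaged (optionally with per-sample weights).
#'
#' @param S Probability vector over `T` classes, or an `n x T` matrix of row
#'   probabilities.
#' @param Y One-hot vector (or `n x T` one-hot matrix) marking the true class.
#' @param l2_coefficient Nonnegative penalty coefficient.
#' @param weights Optional list of numeric arrays entering the L2 penalty
#'   (typically the model's convolution and dense weight matrices), or `NULL`.
#' @param sample_weights Optional nonnegative per-sample weights (matrix case).
#' @return A nonnegative scalar.
#' @export
cross_entropy_loss <- function(S, Y, l2_coefficient = 0, weights = NULL,
                               sample_weights = NULL) {
  if (!is.matrix(S)) S <- matrix(S, nrow = 1)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  stopifnot(identical(dim(S), dim(Y)))
  one_hot_ok <- all(Y %in% c(0, 1)) && all(rowSums(Y) == 1)
  if (!one_hot_ok) abort("Y must be one-hot (rows of 0s with a single 1)")
  p_true <- rowSums(S * Y)
  losses <- -log(pmax(p_true, .Machine$double.xmin))
  data_term <- if (is.null(sample_weights)) {
    mean(losses)
  } else {
    sum(losses * sample_weights) / sum(sample_weights)
  }
  penalty <- if (l2_coefficient > 0 && !is.null(weights)) {
    l2_coefficient / 2 * sum(purrr::map_dbl(weights, ~ sum(.x^2)))
  } else {
    0
  }
  data_term + penalty
}

#' One-hot encode integer class labels
#'
#' @param y Integer labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return `length(y) x n_classes` 0/1 matrix.
#' @export
one_hot <- function(y, n_classes) {
  stopifnot(all(y >= 1), all(y <= n_classes))
  out <- matrix(0, length(y), n_classes)
  out[cbind(seq_along(y), y)] <- 1
  out
}
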