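test_that("conv_valid matches the naive nested-loop oracle", {
  withr::with_seed(12, {
    for (rep in 1:5) {
      inp <- matrix(rnorm(20 * 8), 20, 8)
      h <- sample(2:5, 1)
      kerns <- replicate(3, matrix(rnorm(8 * h), 8, h), simplify = FALSE)
      b <- rnorm(3)
      got <- conv_valid(inp, kerns, biases = b, activation = "relu")
      expect_equal(dim(got), c(20 - h + 1, 3))
      expect_equal(got, naive_conv(inp, kerns, b, relu = TRUE),
                   tolerance = 1e-10)
    }
  })
})

test_that("conv_valid output length, ReLU clipping and the L < h error", {
  inp <- matrix(1, 350, 4)
  k <- matrix(1 / 12, 4, 3)
  out <- conv_valid(inp, k, activation = "identity")
  expect_equal(nrow(out), 348)
  # all-ones kernel on a one-hot input gives sliding-window sums
  hot <- matrix(0, 10, 2); hot[4, 1] <- 1
  ones <- matrix(1, 2, 3)
  sums <- conv_valid(hot, ones, activation = "identity")[, 1]
  expect_equal(sums, c(0, 1, 1, 1, 0, 0, 0, 0))
  # negative pre-activation clips to zero under ReLU
  neg <- conv_valid(matrix(-1, 6, 2), matrix(1, 2, 2), biases = 0)
  expect_true(all(neg == 0))
  expect_error(conv_valid(matrix(1, 2, 2), matrix(1, 2, 3)), "shorter")
})

test_that("maxpool2 halves with floor and drops a trailing element", {
  expect_equal(maxpool2(c(1, 3, 2, 5)), c(3, 5))
  expect_equal(length(maxpool2(rnorm(171))), 85)
  expect_equal(maxpool2(rep(2, 7)), rep(2, 3))
  expect_error(maxpool2(1), "length >= 2")
  # agrees with the naive loop
  withr::with_seed(2, {
    v <- rnorm(25)
    expect_equal(maxpool2(v), naive_pool2(v))
  })
})

test_that("softmax closed forms and log-sum-exp stability", {
  expect_equal(softmax(rep(0, 4)), rep(0.25, 4))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  big <- softmax(c(1e4, 1e4 - 2, -1e4))
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1, tolerance = 1e-12)
  withr::with_seed(8, {
    for (rep in 1:20) {
      z <- rnorm(7, sd = 2)
      s <- softmax(z)
      expect_equal(sum(s), 1, tolerance = 1e-6)
      expect_true(all(s > 0 & s < 1))
      # extreme magnitudes must stay normalised and finite
      s_big <- softmax(z * 1e4)
      expect_true(all(is.finite(s_big)) && abs(sum(s_big) - 1) < 1e-6)
    }
  })
})

test_that("cross-entropy loss closed forms and the independent formula", {
  T_ <- 6
  near_one <- c(1 - 1e-9, rep(1e-9 / (T_ - 1), T_ - 1))
  expect_lt(cross_entropy_loss(near_one, c(1, rep(0, T_ - 1))), 1e-6)
  expect_equal(cross_entropy_loss(rep(1 / T_, T_), c(0, 0, 1, 0, 0, 0)),
               log(T_))
  withr::with_seed(13, {
    for (rep in 1:10) {
      S <- softmax(rnorm(T_))
      y <- sample(T_, 1)
      Y <- replace(rep(0, T_), y, 1)
      expect_equal(cross_entropy_loss(S, Y), -log(S[y]), tolerance = 1e-12)
    }
  })
  expect_error(cross_entropy_loss(rep(1 / 4, 4), c(1, 1, 0, 0)), "one-hot")
})

test_that("the L2 penalty adds half the coefficient times summed squares", {
  S <- c(0.7, 0.3); Y <- c(1, 0)
  W <- list(matrix(1:4, 2), matrix(c(-1, 2), 1))
  expect_equal(
    cross_entropy_loss(S, Y, l2_coefficient = 0.1, weights = W),
    -log(0.7) + 0.05 * (sum((1:4)^2) + 5)
  )
})

test_that("layer_length_plan reproduces the default geometry", {
  cfg <- venue_cnn_config(n_classes = 5)
  plan <- layer_length_plan(cfg)
  expect_equal(plan$conv_len, c(348L, 171L, 81L))
  expect_equal(plan$pooled_len, c(174L, 85L, 40L))
  expect_equal(attr(plan, "feature_size"), 3840L)
  # independent arithmetic loop
  L <- 350
  for (t in 1:3) {
    h <- c(3, 4, 5)[t]
    expect_equal(plan$conv_len[t], L - h + 1)
    L <- (L - h + 1) %/% 2
    expect_equal(plan$pooled_len[t], L)
  }
})

test_that("degenerate geometries error naming the offending stage", {
  # m=10 with windows 3/4/5: stage 2 conv length is 1, unpoolable
  expect_error(
    layer_length_plan(list(m = 10, conv_stages = list(c(4L, 3L), c(4L, 4L), c(4L, 5L)))),
    "stage 2"
  )
  # a single stage m=5, h=5 gives a length-1 map: pooling impossible
  expect_error(
    layer_length_plan(list(m = 5, conv_stages = list(c(2L, 5L)))),
    "stage 1"
  )
  # window larger than input
  expect_error(
    layer_length_plan(list(m = 3, conv_stages = list(c(2L, 5L)))),
    "stage 1"
  )
  expect_error(venue_cnn_config(n_classes = 4, m = 10), "stage")
})

test_that("one_hot encodes and validates", {
  Y <- one_hot(c(2, 1, 3), 3)
  expect_equal(rowSums(Y), c(1, 1, 1))
  expect_equal(which(Y[1, ] == 1), 2L)
  expect_error(one_hot(c(0, 1), 3))
})
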