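test_that("tanh activation matches its printed closed form", {
  expect_identical(tanh_activation(0), 0)
  x <- seq(-3, 3, by = 0.37)
  expect_equal(tanh_activation(-x), -tanh_activation(x))
  # direct evaluation of 2 / (1 + exp(-2x)) - 1
  expect_equal(tanh_activation(1), 2 / (1 + exp(-2)) - 1, tolerance = 1e-15)
  expect_equal(tanh_activation(x), 2 / (1 + exp(-2 * x)) - 1,
               tolerance = 1e-12)
  # saturates without blowing up
  expect_equal(tanh_activation(c(-1e6, 1e6)), c(-1, 1))
})

test_that("softmax is a stable, shift-invariant probability map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  big <- softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big, c(1, 0), tolerance = 1e-12)
  u <- c(1, 2)
  expect_equal(softmax(u), exp(u) / sum(exp(u)), tolerance = 1e-15)
  expect_equal(softmax(u + 17.3), softmax(u), tolerance = 1e-12)
  withr::with_seed(4, {
    v <- rnorm(6)
    expect_equal(sum(softmax(v)), 1, tolerance = 1e-12)
    expect_true(all(softmax(v) > 0))
  })
})

test_that("rnn_step is exactly tanh(W_h h + W_x x)", {
  zero <- rnn_params(matrix(0, 2, 2), matrix(0, 2, 3), matrix(0, 2, 2))
  expect_equal(rnn_step(zero, c(1, -1), c(1, 2, 3)), c(0, 0))
  # scalar case W_h = 0, W_x = 1, x = 0
  sc <- rnn_params(matrix(0, 1, 1), matrix(1, 1, 1), matrix(1, 2, 1))
  expect_equal(rnn_step(sc, 0.3, 0), 0)
  # random small instance vs naive matrix arithmetic
  withr::with_seed(11, {
    p <- init_rnn_params(3, 2, seed = 11)
    h <- rnorm(2); x <- rnorm(3)
    expect_equal(rnn_step(p, h, x),
                 as.numeric(tanh(p$W_h %*% h + p$W_x %*% x)),
                 tolerance = 1e-14)
  })
  expect_error(rnn_step(sc, c(1, 2), 0), class = "mmgru_shape_error")
})

test_that("gru_step follows the standard gated update", {
  zero <- gru_params(matrix(0, 2, 3), matrix(0, 2, 2), c(0, 0),
                     matrix(0, 2, 3), matrix(0, 2, 2), c(0, 0),
                     matrix(0, 2, 3), matrix(0, 2, 2), c(0, 0),
                     matrix(0, 2, 2))
  # all-zero parameters: gates 0.5, candidate 0 -> h = 0.5 h_prev
  h_prev <- c(0.4, -0.8)
  expect_equal(gru_step(zero, h_prev, c(1, 2, 3)), 0.5 * h_prev)
  expect_equal(gru_step(zero, c(0, 0), c(5, -5, 1)), c(0, 0))
  # scalar GRU vs an independent hand computation
  p <- gru_params(matrix(0.3), matrix(-0.2), 0.1,
                  matrix(0.5), matrix(0.4), -0.3,
                  matrix(0.7), matrix(0.6), 0.2,
                  matrix(c(1, -1), 2, 1))
  h <- 0.25; x <- -0.5
  sig <- function(v) 1 / (1 + exp(-v))
  z <- sig(0.3 * x + (-0.2) * h + 0.1)
  r <- sig(0.5 * x + 0.4 * h - 0.3)
  hc <- tanh(0.7 * x + 0.6 * (r * h) + 0.2)
  expect_equal(gru_step(p, h, x), (1 - z) * h + z * hc, tolerance = 1e-14)
  expect_error(gru_step(p, c(1, 2), x), class = "mmgru_shape_error")
})

test_that("encode_sequence composes cell steps from the zero state", {
  p <- random_gru(2, 3, seed = 2)
  x1 <- c(0.3, -0.1); x2 <- c(-0.4, 0.9)
  # T = 1 equals a single step from zero
  expect_equal(encode_sequence(p, matrix(x1, 1)),
               gru_step(p, rep(0, 3), x1))
  # length 2 equals composing the single-step oracle twice
  expect_equal(encode_sequence(p, rbind(x1, x2)),
               gru_step(p, gru_step(p, rep(0, 3), x1), x2),
               tolerance = 1e-14)
  expect_error(encode_sequence(p, matrix(numeric(0), 0, 2)),
               class = "mmgru_empty_sequence")
})

test_that("hidden states stay strictly inside (-1, 1) from the zero state", {
  withr::with_seed(31, {
    for (i in 1:10) {
      hd <- sample(1:3, 1); nf <- sample(1:3, 1); tl <- sample(1:4, 1)
      obs <- matrix(rnorm(tl * nf, sd = 3), tl, nf)
      hg <- encode_sequence(init_gru_params(nf, hd, seed = i), obs)
      hr <- encode_sequence(init_rnn_params(nf, hd, seed = i), obs)
      expect_true(all(abs(hg) < 1))
      expect_true(all(abs(hr) < 1))
    }
  })
})

test_that("classify is softmax over the output head", {
  expect_equal(classify(c(0.4, -0.2), matrix(0, 2, 2)), c(0.5, 0.5))
  withr::with_seed(8, {
    h <- rnorm(3); W <- matrix(rnorm(6), 2, 3)
    p <- classify(h, W)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, softmax(as.numeric(W %*% h)), tolerance = 1e-14)
  })
  expect_error(classify(c(1, 2, 3), matrix(0, 2, 2)),
               class = "mmgru_shape_error")
})

test_that("cross-entropy has the right closed forms and naive oracle", {
  perfect <- rbind(c(1, 0), c(0, 1))
  expect_equal(cross_entropy(c(1L, 2L), perfect), 0)
  uniform <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(cross_entropy(c(1L, 2L), uniform), log(2), tolerance = 1e-12)
  # 3-sample batch vs naive per-sample summation
  yhat <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.6, 0.4))
  y <- c(1L, 2L, 2L)
  naive <- -(log(0.7) + log(0.8) + log(0.4)) / 3
  expect_equal(cross_entropy(y, yhat), naive, tolerance = 1e-12)
  expect_gte(cross_entropy(y, yhat), 0)
  expect_error(cross_entropy(integer(0), matrix(numeric(0), 0, 2)),
               class = "mmgru_empty_batch")
})

test_that("encoding is invariant to sequence chunking", {
  p <- random_gru(2, 3, seed = 6)
  obs <- matrix(rnorm(8), 4, 2)
  h_all <- encode_sequence(p, obs)
  h <- rep(0, 3)
  for (t in 1:4) h <- gru_step(p, h, obs[t, ])
  expect_equal(h_all, h, tolerance = 1e-14)
  # batched forward agrees with the sequential path
  fw <- forward_batch(p, new_batch(list(obs, obs[1:2, ]), c(1L, 2L)))
  expect_equal(as.numeric(fw$H[1, ]), h_all, tolerance = 1e-14)
  expect_equal(as.numeric(fw$H[2, ]), encode_sequence(p, obs[1:2, ]),
               tolerance = 1e-14)
})
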