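# scalar-loop oracle for the indRNN recurrence, written independently of the
# package implementation
oracle_indrnn <- function(x, layers, act = function(z) pmax(z, 0)) {
  seqs <- x
  for (ly in layers) {
    units <- nrow(ly$W)
    H <- matrix(0, nrow(seqs), units)
    h <- rep(0, units)
    for (t in seq_len(nrow(seqs))) {
      hn <- numeric(units)
      for (i in seq_len(units)) {
        acc <- 0
        for (j in seq_len(ncol(ly$W))) acc <- acc + ly$W[i, j] * seqs[t, j]
        hn[i] <- act(acc + ly$u[i] * h[i] + ly$b[i])
      }
      h <- hn
      H[t, ] <- h
    }
    seqs <- H
  }
  seqs[nrow(seqs), ]
}

test_that("indRNN step: recurrence is element-wise, not a matrix product", {
  p <- list(W = diag(2), u = c(0, 0), b = c(0, 0))
  expect_equal(indrnn_step(c(1, -2), c(5, 5), p), c(1, 0))
  p2 <- list(W = matrix(0, 1, 1), u = 1, b = 0)
  expect_equal(indrnn_step(0, 3, p2), 3)       # pure memory
  expect_error(indrnn_step(c(1, 2, 3), c(0, 0), p), "input length")
  expect_error(indrnn_step(c(1, 2), c(0, 0, 0), p), "hidden length")
})

test_that("stacked indRNN forward matches the scalar unrolled oracle", {
  set.seed(7)
  for (rep in 1:20) {
    T_len <- sample(1:8, 1)
    d <- sample(1:4, 1)
    u1 <- sample(1:4, 1)
    u2 <- sample(1:4, 1)
    layers <- list(
      list(W = matrix(rnorm(u1 * d), u1, d), u = runif(u1, -1, 1),
           b = rnorm(u1, sd = 0.1)),
      list(W = matrix(rnorm(u2 * u1), u2, u1), u = runif(u2, -1, 1),
           b = rnorm(u2, sd = 0.1))
    )
    x <- matrix(rnorm(T_len * d), T_len, d)
    expect_equal(indrnn_forward(x, layers), oracle_indrnn(x, layers),
                 tolerance = 1e-6)
  }
})

test_that("indRNN forward degenerates correctly at T = 1 and u = 0", {
  set.seed(3)
  ly <- list(W = matrix(rnorm(6), 3, 2), u = runif(3, -1, 1), b = rnorm(3))
  x1 <- matrix(rnorm(2), 1, 2)
  expect_equal(indrnn_forward(x1, list(ly)),
               indrnn_step(x1[1, ], rep(0, 3), ly))
  # u = 0: output depends only on the last input, so permuting the first
  # T-1 rows changes nothing
  ly0 <- list(W = ly$W, u = rep(0, 3), b = ly$b)
  x <- matrix(rnorm(10), 5, 2)
  xp <- x[c(3, 1, 4, 2, 5), ]
  expect_equal(indrnn_forward(x, list(ly0)), indrnn_forward(xp, list(ly0)))
  expect_error(indrnn_forward(x[0, , drop = FALSE], list(ly)), "at least one")
})

test_that("residual blocks halve the time axis and keep zero at zero", {
  m <- build_rcnn(tiny_arch(), input_len = 4096, seed = 2)
  bp <- m$params$blocks[[1]]
  out <- residual_block_forward(matrix(rnorm(4096), ncol = 1), bp)
  expect_equal(nrow(out), 2048L)
  expect_equal(ncol(out), 4L)
  # zero input, identity BN stats (fresh init), beta = 0 -> exactly zero out
  z <- residual_block_forward(matrix(0, 64, 1), bp)
  expect_true(all(z == 0))
})

test_that("block-1 convolution parameter count matches the closed form", {
  spec <- architecture_spec(n_class = 2)      # default 64/128/64
  m <- build_rcnn(spec, input_len = 4096, seed = 1)
  b1 <- m$params$blocks[[1]]
  n_w <- function(p) length(p$W) + length(p$b)
  counts <- c(n_w(b1$conv1), n_w(b1$conv2), n_w(b1$conv3), n_w(b1$proj))
  expect_equal(counts, c(1 * 8 * 64 + 64, 64 * 5 * 64 + 64,
                         64 * 3 * 64 + 64, 1 * 1 * 64 + 64))
  expect_equal(sum(counts), 33600L)
})

test_that("total trainable parameters equal the closed-form layer sum", {
  spec <- tiny_arch(n_class = 3, f = c(4, 6, 4), rnn = c(5, 5), dense = 8)
  m <- build_rcnn(spec, input_len = 256, seed = 1)
  conv <- function(cin, k, f) cin * k * f + f + 2 * f      # W + b + gamma/beta
  closed <-
    conv(1, 8, 4) + conv(4, 5, 4) + conv(4, 3, 4) + conv(1, 1, 4) +
    conv(4, 8, 6) + conv(6, 5, 6) + conv(6, 3, 6) + conv(4, 1, 6) +
    conv(6, 8, 4) + conv(4, 5, 4) + conv(4, 3, 4) + conv(6, 1, 4) +
    (5 * 4 + 5 + 5 + 2 * 5) +          # indRNN1: W + u + b + gamma/beta
    (5 * 5 + 5 + 5 + 2 * 5) +
    (5 * 8 + 8) + (8 * 3 + 3)
  expect_equal(rcnn_param_count(m), closed)
})

test_that("the shape chain follows ceil-division through the stack", {
  spec <- architecture_spec(n_class = 2)
  m <- build_rcnn(spec, input_len = 4096)
  expect_equal(m$shapes$t[grepl("block3", m$shapes$layer)], 512L)
  expect_equal(m$t_rnn, 256L)
  for (L in c(100, 137, 1000, 4096, 5000)) {
    sc <- rcnneeg:::rcnn_shape_chain(spec, L)
    expect_equal(sc$t_conv, ceiling(ceiling(ceiling(L / 2) / 2) / 2))
    expect_equal(sc$t_rnn, sc$t_conv %/% 2)
  }
  expect_error(build_rcnn(spec, input_len = 8), "at least")
})

test_that("softmax output is a probability vector with stable argmax", {
  m <- build_rcnn(tiny_arch(n_class = 2), input_len = 128, seed = 4)
  w <- rnorm(128)
  p <- predict_window(m, w)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(predict_window(m, w), p)
  expect_error(predict_window(m, rnorm(64)), "expects 128")
})

test_that("constant input through a fresh symmetric model is uniform", {
  for (seed in c(1, 9, 33)) {
    m <- build_rcnn(tiny_arch(n_class = 3), input_len = 128, seed = seed)
    p <- predict_window(m, rep(2.5, 128))
    expect_equal(unname(p), rep(1 / 3, 3), tolerance = 1e-4)
  }
})

test_that("compiled engine and pure-R reference forward agree", {
  m <- build_rcnn(tiny_arch(n_class = 3), input_len = 200, seed = 6)
  for (i in 1:3) {
    w <- rnorm(200)
    pc <- predict_window(m, w, engine = "compiled")
    pr <- predict_window(m, w, engine = "reference")
    expect_equal(pc, pr, tolerance = 1e-5)
  }
})

test_that("LeakyReLU and softmax behave pointwise as defined", {
  x <- c(-2, -0.5, 0, 0.5, 3)
  expect_equal(leaky_relu(x, 0.01), c(-0.02, -0.005, 0, 0.5, 3))
  s <- softmax(matrix(c(1, 2, 3, 1, 1, 1), 2, byrow = TRUE))
  expect_equal(rowSums(s), c(1, 1))
  expect_equal(s[2, ], rep(1 / 3, 3))
})
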