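#' Leaky rectified linear activation
#'
#' `f(x) = x` for `x >= 0` and `slope * x` otherwise.
#'
#' @param x Numeric vector/matrix.
#' @param slope Negative-side slope (default 0.01).
#' @return Object of the same shape as `x`.
#' @export
leaky_relu <- function(x, slope = 0.01) {
  ifelse(x >= 0, x, slope * x)
}

#' Row-wise softmax
#'
#' Numerically stable softmax over the last dimension; rows of the result
#' are non-negative and sum to one.
#'
#' @param x Numeric matrix (rows = cases) or vector.
#' @return Matrix (or vector) of probabilities.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) {
    e <- exp(x - max(x))
    return(e / sum(e))
  }
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# reference "same"-padding 1-D convolution, double precision.
# x: (T x C); W: (C*k x F), column layout tap-major (tap j, channel c at row
# j*C + c); returns (ceil(T/stride) x F)
r_conv1d <- function(x, W, b, k, stride = 1) {
  T_in <- nrow(x)
  C <- ncol(x)
  T_out <- ceiling(T_in / stride)
  pad <- max((T_out - 1) * stride + k - T_in, 0) %/% 2
  cols <- matrix(0, T_out, C * k)
  for (j in seq_len(k) - 1L) {
    p <- (seq_len(T_out) - 1L) * stride - pad + j
    ok <- p >= 0 & p < T_in
    cols[ok, j * C + seq_len(C)] <- x[p[ok] + 1L, , drop = FALSE]
  }
  sweep(cols %*% W, 2, b, "+")
}

# reference batch-norm in inference mode (stored running statistics)
r_bn_infer <- function(x, bn, eps = 1e-3) {
  xhat <- sweep(sweep(x, 2, bn$rm, "-"), 2, sqrt(bn$rv + eps), "/")
  sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
}

#' One step of an independently recurrent (indRNN) cell
#'
#' The indRNN recurrence is `h_t = act(W x_t + u * h_{t-1} + b)` where the
#' recurrent weight `u` acts element-wise: each hidden unit recurs only onto
#' itself, with no hidden-to-hidden matrix. This keeps per-unit gradient
#' growth controllable (via clipping `|u|`) and lets many layers be stacked.
#'
#' @param x Input vector (length `d`).
#' @param h_prev Previous hidden state (length `units`).
#' @param params List with `W` (`units x d` matrix), `u` (length `units`),
#'   `b` (length `units`).
#' @param activation Activation function (default `relu`).
#' @return Hidden state vector of length `units`.
#' @export
indrnn_step <- function(x, h_prev, params,
                        activation = function(z) pmax(z, 0)) {
  W <- params$W
  if (length(x) != ncol(W)) {
    stop(sprintf("input length %d does not match W columns %d",
                 length(x), ncol(W)), call. = FALSE)
  }
  if (length(h_prev) != nrow(W)) {
    stop(sprintf("hidden length %d does not match W rows %d",
                 length(h_prev), nrow(W)), call. = FALSE)
  }
  activation(as.numeric(W %*% x) + params$u * h_prev + params$b)
}

#' Forward pass through stacked indRNN layers
#'
#' Layer 1 consumes the input sequence; each further layer consumes the
#' previous layer's hidden-state sequence. If a layer carries batch-norm
#' parameters (`bn` with `gamma`, `beta`, `rm`, `rv`), they are applied to
#' that layer's output sequence in inference mode. Returns the final layer's
#' last hidden state.
#'
#' @param x Numeric matrix, `T x d` (time in rows); `T >= 1`.
#' @param layers List of per-layer parameter lists (see [indrnn_step()]),
#'   each optionally containing a `bn` element.
#' @param activation Activation used inside the recurrence (default `relu`).
#' @param bn_eps Batch-norm epsilon (default 1e-3).
#' @param return_sequence Return the full `T x units` hidden sequence of the
#'   last layer instead of its final state.
#' @return Hidden-state vector of the last layer at the last time step (or
#'   the full sequence).
#' @export
indrnn_forward <- function(x, layers,
                           activation = function(z) pmax(z, 0),
                           bn_eps = 1e-3, return_sequence = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("sequence must have at least one step", call. = FALSE)
  seqs <- x
  for (ly in layers) {
    units <- nrow(ly$W)
    H <- matrix(0, nrow(seqs), units)
    h <- numeric(units)
    for (t in seq_len(nrow(seqs))) {
      h <- indrnn_step(seqs[t, ], h, ly, activation)
      H[t, ] <- h
    }
    if (!is.null(ly$bn)) H <- r_bn_infer(H, ly$bn, bn_eps)
    seqs <- H
  }
  if (return_sequence) seqs else seqs[nrow(seqs), ]
}

#' Reference forward pass through one residual 1-D convolution block
#'
#' Main path: `Conv(k1, s1)+BN+LeakyReLU -> Conv(k2, s2)+BN+LeakyReLU ->
#' Conv(k3, s3)+BN`; shortcut: `Conv(1, s1*s2*s3)+BN` when the block uses a
#' projection, otherwise strided subsampling of the input. Output is
#' `LeakyReLU(main + shortcut)` with "same" padding throughout, so the time
#' axis shrinks from `T` to `ceil(T / (s1*s2*s3))`. Batch norm runs in
#' inference mode from the stored statistics (double precision; this is the
#' reference path used to validate the compiled training engine).
#'
#' @param x Numeric matrix `T x C_in` (time in rows).
#' @param block_params Parameter list for one block as found in
#'   `model$params` (see [build_rcnn()]): elements `conv1`..`conv3` and
#'   optionally `proj`, each with `W`, `b`, `gamma`, `beta`, `rm`, `rv`.
#' @param kernels Integer kernel triple (default `c(8, 5, 3)`).
#' @param strides Integer stride triple (default `c(1, 2, 1)`).
#' @param leaky_slope LeakyReLU negative slope (default 0.01).
#' @param bn_eps Batch-norm epsilon (default 1e-3).
#' @return Numeric matrix `ceil(T/2) x filters` for the default strides.
#' @export
residual_block_forward <- function(x, block_params, kernels = c(8, 5, 3),
                                   strides = c(1, 2, 1), leaky_slope = 0.01,
                                   bn_eps = 1e-3) {
  x <- as.matrix(x)
  cb <- function(inp, p, k, s, act) {
    y <- r_bn_infer(r_conv1d(inp, p$W, p$b, k, s), p, bn_eps)
    if (act) leaky_relu(y, leaky_slope) else y
  }
  a1 <- cb(x, block_params$conv1, kernels[1], strides[1], TRUE)
  a2 <- cb(a1, block_params$conv2, kernels[2], strides[2], TRUE)
  main <- cb(a2, block_params$conv3, kernels[3], strides[3], FALSE)
  s_total <- prod(strides)
  if (!is.null(block_params$proj)) {
    shortcut <- cb(x, block_params$proj, 1, s_total, FALSE)
  } else {
    if (ncol(x) != ncol(main)) {
      stop("identity shortcut requires matching channel counts", call. = FALSE)
    }
    shortcut <- x[seq(1, nrow(x), by = s_total), , drop = FALSE]
  }
  stopifnot(nrow(shortcut) == nrow(main))
  leaky_relu(main + shortcut, leaky_slope)
}
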