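#' Residual block specification
#'
#' One residual unit of the convolutional stage: three "same"-padded 1-D
#' convolutions (kernel sizes `kernels`, strides `strides` — exactly one
#' stride-2 stage by default) plus a shortcut. The shortcut is a kernel-1
#' projection convolution when `projection_shortcut` is TRUE *or* when the
#' channel count changes across the block (an identity add cannot
#' type-check otherwise); it is strided subsampling of the input otherwise.
#'
#' @param filters Number of output channels (> 0).
#' @param kernels Integer kernel-size triple (default `c(8, 5, 3)`).
#' @param strides Integer stride triple (default `c(1, 2, 1)`).
#' @param projection_shortcut Use a kernel-1 projection shortcut
#'   (default TRUE).
#' @return A list of class `block_spec`.
#' @export
block_spec <- function(filters, kernels = c(8, 5, 3), strides = c(1, 2, 1),
                       projection_shortcut = TRUE) {
  stopifnot(filters > 0, length(kernels) == 3, all(kernels >= 1),
            length(strides) == 3, all(strides >= 1))
  structure(
    list(filters = as.integer(filters), kernels = as.integer(kernels),
         strides = as.integer(strides),
         projection_shortcut = isTRUE(projection_shortcut)),
    class = "block_spec"
  )
}

#' Network architecture specification
#'
#' Declarative description of the residual 1-D CNN + stacked indRNN
#' classifier. The default mirrors the reference design: three residual
#' blocks with 64/128/64 filters and kernels (8, 5, 3), average pooling of
#' width 2 over time, two 128-unit indRNN layers each followed by batch
#' norm, a 256-unit fully connected layer and a softmax head.
#'
#' `pool = "avg2"` averages adjacent time-step pairs (halving the sequence
#' the recurrent stage sees); `pool = "global"` instead averages the
#' convolutional output within `n_segments` equal sub-segments, so the
#' recurrent stage runs over `n_segments` pooled feature vectors;
#' `pool = "none"` feeds the full convolutional output sequence.
#'
#' @param blocks List of [block_spec()]s (default 64/128/64).
#' @param pool One of `"avg2"`, `"global"`, `"none"`.
#' @param n_segments Sub-segment count for `pool = "global"` (default 8).
#' @param rnn_layers Integer vector of indRNN units per layer
#'   (default `c(128, 128)`).
#' @param dense_units Fully connected layer width (default 256).
#' @param n_class Number of output classes (>= 2).
#' @param leaky_slope LeakyReLU negative slope (default 0.01).
#' @param bn_momentum Batch-norm running-average momentum (default 0.99).
#' @param bn_eps Batch-norm epsilon (default 1e-3).
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(blocks = list(block_spec(64),
                                            block_spec(128),
                                            block_spec(64,
                                              projection_shortcut = FALSE)),
                              pool = c("avg2", "global", "none"),
                              n_segments = 8,
                              rnn_layers = c(128, 128),
                              dense_units = 256,
                              n_class = 2,
                              leaky_slope = 0.01,
                              bn_momentum = 0.99,
                              bn_eps = 1e-3) {
  pool <- match.arg(pool)
  stopifnot(length(blocks) >= 1, all(vapply(blocks, inherits, TRUE, "block_spec")),
            length(rnn_layers) >= 1, all(rnn_layers > 0),
            dense_units > 0, n_class >= 2)
  structure(
    list(blocks = blocks, pool = pool, n_segments = as.integer(n_segments),
         rnn_layers = as.integer(rnn_layers),
         dense_units = as.integer(dense_units), n_class = as.integer(n_class),
         leaky_slope = leaky_slope, bn_momentum = bn_momentum,
         bn_eps = bn_eps),
    class = "architecture_spec"
  )
}

# does block b of `spec`, fed `cin` channels, use a projection shortcut?
block_uses_proj <- function(bs, cin) {
  bs$projection_shortcut || cin != bs$filters
}

# per-layer time lengths through the network for a given input length
rcnn_shape_chain <- function(spec, input_len) {
  t <- input_len
  t_blocks <- integer(0)
  for (bs in spec$blocks) {
    t <- ceiling(t / prod(bs$strides))
    t_blocks <- c(t_blocks, t)
  }
  t_conv <- t
  pool_w <- switch(spec$pool,
                   avg2 = 2L,
                   global = max(1L, t_conv %/% spec$n_segments),
                   none = 1L)
  t_rnn <- if (pool_w > 1L) t_conv %/% pool_w else t_conv
  list(t_blocks = t_blocks, t_conv = t_conv, pool_w = pool_w, t_rnn = t_rnn)
}

init_bn <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out),
       rm = rep(0, c_out), rv = rep(1, c_out))
}

init_conv <- function(rng, c_in, k, f) {
  c(list(W = matrix(rng$rnorm(c_in * k * f, sd = sqrt(2 / (c_in * k))),
                    c_in * k, f),
         b = rep(0, f)),
    init_bn(f))
}

#' Build the residual CNN + indRNN model
#'
#' Instantiates seeded parameters for an [architecture_spec()] at a fixed
#' input window length and returns an inspectable model handle. Convolution
#' and dense weights use He-normal initialization (Glorot-uniform for the
#' softmax head and recurrent input weights); indRNN recurrent weights start
#' at `u = 1` (each ReLU unit begins as a perfect integrator over the
#' window, the long-memory initialization for independently recurrent
#' units) and are kept within `|u| <= u_clip` with `u_clip = 2^(1/T)` for a
#' recurrent sequence of length `T`, so memory can at most double over the
#' sequence.
#'
#' @param spec An [architecture_spec()].
#' @param input_len Window length in samples (e.g. 5000 for 10 s at 500 Hz).
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `rcnn_model`: fields `spec`, `input_len`,
#'   `params` (nested list: `blocks`, `rnn`, `dense`, `out`), `shapes`
#'   (layer table), `t_rnn`, `u_clip`, `n_params`, `classes` (set by
#'   [train()]).
#' @export
build_rcnn <- function(spec, input_len, seed = 1) {
  stopifnot(inherits(spec, "architecture_spec"))
  sc <- rcnn_shape_chain(spec, input_len)
  if (sc$t_rnn < 1) {
    min_len <- prod(vapply(spec$blocks, function(b) prod(b$strides), 1)) *
      max(sc$pool_w, 1L)
    stop(sprintf("input_len %d too short: need at least %d samples",
                 input_len, min_len), call. = FALSE)
  }
  rng <- local_rng(seed)
  u_clip <- 2^(1 / sc$t_rnn)

  params <- list(blocks = list(), rnn = list(), dense = NULL, out = NULL)
  cin <- 1L
  for (bs in spec$blocks) {
    f <- bs$filters
    blk <- list(
      conv1 = init_conv(rng, cin, bs$kernels[1], f),
      conv2 = init_conv(rng, f, bs$kernels[2], f),
      conv3 = init_conv(rng, f, bs$kernels[3], f)
    )
    if (block_uses_proj(bs, cin)) {
      blk$proj <- init_conv(rng, cin, 1L, f)
    }
    params$blocks[[length(params$blocks) + 1L]] <- blk
    cin <- f
  }
  d <- cin
  for (units in spec$rnn_layers) {
    lim <- sqrt(6 / (d + units))
    # long-memory initialization: u = 1 makes every ReLU unit a perfect
    # integrator of its input projection, so evidence from anywhere in the
    # window reaches the final hidden state; training shortens memory where
    # useful (and the clip keeps |u| <= u_clip)
    params$rnn[[length(params$rnn) + 1L]] <- c(
      list(W = matrix(rng$runif(units * d, -lim, lim), units, d),
           u = rep(min(1, u_clip), units),
           b = rep(0, units)),
      init_bn(units)
    )
    d <- units
  }
  params$dense <- list(
    W = matrix(rng$rnorm(d * spec$dense_units, sd = sqrt(2 / d)),
               d, spec$dense_units),
    b = rep(0, spec$dense_units)
  )
  lim <- sqrt(6 / (spec$dense_units + spec$n_class))
  params$out <- list(
    W = matrix(rng$runif(spec$dense_units * spec$n_class, -lim, lim),
               spec$dense_units, spec$n_class),
    b = rep(0, spec$n_class)
  )

  model <- structure(
    list(spec = spec, input_len = as.integer(input_len), params = params,
         t_rnn = sc$t_rnn, pool_w = sc$pool_w, u_clip = u_clip,
         classes = NULL, seed = as.integer(seed)),
    class = "rcnn_model"
  )
  model$shapes <- model_layer_table(model)
  model$n_params <- rcnn_param_count(model)
  model
}

# flat parameter list in the order the compiled engine expects
flatten_params <- function(model) {
  out <- list()
  push <- function(prefix, p, fields) {
    for (f in fields) out[[paste(prefix, f, sep = "_")]] <<- p[[f]]
  }
  conv_fields <- c("W", "b", "gamma", "beta", "rm", "rv")
  for (i in seq_along(model$params$blocks)) {
    blk <- model$params$blocks[[i]]
    for (cn in c("conv1", "conv2", "conv3")) {
      push(sprintf("b%d_%s", i, cn), blk[[cn]], conv_fields)
    }
    if (!is.null(blk$proj)) push(sprintf("b%d_proj", i), blk$proj, conv_fields)
  }
  for (l in seq_along(model$params$rnn)) {
    push(sprintf("rnn%d", l), model$params$rnn[[l]],
         c("W", "u", "b", "gamma", "beta", "rm", "rv"))
  }
  push("dense", model$params$dense, c("W", "b"))
  push("out", model$params$out, c("W", "b"))
  out
}

unflatten_params <- function(model, flat) {
  i <- 0L
  take <- function() {
    i <<- i + 1L
    flat[[i]]
  }
  conv_fields <- c("W", "b", "gamma", "beta", "rm", "rv")
  p <- model$params
  for (bi in seq_along(p$blocks)) {
    for (cn in c("conv1", "conv2", "conv3")) {
      for (f in conv_fields) p$blocks[[bi]][[cn]][[f]] <- take()
    }
    if (!is.null(p$blocks[[bi]]$proj)) {
      for (f in conv_fields) p$blocks[[bi]]$proj[[f]] <- take()
    }
  }
  for (l in seq_along(p$rnn)) {
    for (f in c("W", "u", "b", "gamma", "beta", "rm", "rv")) {
      p$rnn[[l]][[f]] <- take()
    }
  }
  for (f in c("W", "b")) p$dense[[f]] <- take()
  for (f in c("W", "b")) p$out[[f]] <- take()
  p
}

# engine configuration mirroring the architecture
engine_cfg <- function(model) {
  spec <- model$spec
  cin <- 1L
  cins <- integer(0)
  projs <- integer(0)
  for (bs in spec$blocks) {
    cins <- c(cins, cin)
    projs <- c(projs, as.integer(block_uses_proj(bs, cin)))
    cin <- bs$filters
  }
  list(
    filters = vapply(spec$blocks, `[[`, 1L, "filters"),
    cin = cins,
    proj = projs,
    kernels = lapply(spec$blocks, `[[`, "kernels"),
    strides = lapply(spec$blocks, `[[`, "strides"),
    pool_w = as.integer(model$pool_w),
    rnn_units = spec$rnn_layers,
    dense_units = spec$dense_units,
    n_class = spec$n_class,
    leaky_slope = spec$leaky_slope,
    bn_eps = spec$bn_eps,
    bn_momentum = spec$bn_momentum,
    u_clip = model$u_clip
  )
}

#' Count model parameters
#'
#' @param model An `rcnn_model`.
#' @param trainable_only Exclude batch-norm running statistics (default
#'   TRUE; they are state, not trained weights).
#' @param include_bn Include batch-norm scale/shift parameters
#'   (default TRUE).
#' @return Integer parameter count.
#' @export
rcnn_param_count <- function(model, trainable_only = TRUE,
                             include_bn = TRUE) {
  flat <- flatten_params(model)
  keep <- names(flat)
  if (trainable_only) keep <- keep[!grepl("_(rm|rv)$", keep)]
  if (!include_bn) keep <- keep[!grepl("_(gamma|beta|rm|rv)$", keep)]
  sum(vapply(flat[keep], length, 1L))
}

model_layer_table <- function(model) {
  spec <- model$spec
  sc <- rcnn_shape_chain(spec, model$input_len)
  rows <- list()
  add <- function(layer, t, c, n_par) {
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, t = t,
                                             channels = c, params = n_par)
  }
  add("input", model$input_len, 1L, 0L)
  cin <- 1L
  for (i in seq_along(spec$blocks)) {
    bs <- spec$blocks[[i]]
    blk <- model$params$blocks[[i]]
    n_par <- sum(vapply(blk, function(cp) {
      length(cp$W) + length(cp$b) + length(cp$gamma) + length(cp$beta)
    }, 1))
    add(sprintf("block%d [%s x Conv1D(k=%s) %s]", i, 3,
                paste(bs$kernels, collapse = ","),
                if (block_uses_proj(bs, cin)) "+ proj(k=1)" else "+ identity"),
        sc$t_blocks[i], bs$filters, n_par)
    cin <- bs$filters
  }
  if (sc$pool_w > 1) add(sprintf("avgpool(w=%d)", sc$pool_w), sc$t_rnn, cin, 0L)
  d <- cin
  for (l in seq_along(spec$rnn_layers)) {
    u <- spec$rnn_layers[l]
    add(sprintf("indRNN%d + BN", l), sc$t_rnn, u,
        u * d + u + u + 2L * u)
    d <- u
  }
  add("dense + LeakyReLU", 1L, spec$dense_units,
      d * spec$dense_units + spec$dense_units)
  add("softmax head", 1L, spec$n_class,
      spec$dense_units * spec$n_class + spec$n_class)
  do.call(rbind, rows)
}

#' Plain-text model summary
#'
#' Layer table (output shapes and parameter counts) suitable for diffing.
#'
#' @param model An `rcnn_model`.
#' @return Character vector of lines, invisibly; printed as a side effect.
#' @export
model_summary <- function(model) {
  tab <- model$shapes
  lines <- c(
    sprintf("rcnn_model: input %d samples, %d classes, %d trainable parameters",
            model$input_len, model$spec$n_class, model$n_params),
    sprintf("%-36s %8s %9s %9s", "layer", "t", "channels", "params"),
    sprintf("%-36s %8d %9d %9d", tab$layer, tab$t, tab$channels, tab$params),
    sprintf("recurrent sequence length %d, |u| clipped at %.6f",
            model$t_rnn, model$u_clip)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.rcnn_model <- function(x, ...) {
  model_summary(x)
  invisible(x)
}

# per-window standardization: zero mean, unit variance
standardize_windows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  mu <- rowMeans(x)
  sd_ <- sqrt(pmax(rowMeans((x - mu)^2), 1e-12))
  (x - mu) / sd_
}

#' Class probabilities for EEG windows
#'
#' Runs the compiled inference path (batch norm with running statistics) on
#' one window or a matrix of windows. Each window is standardized to zero
#' mean and unit variance before the network.
#'
#' @param model A (typically trained) `rcnn_model`.
#' @param window Numeric vector of `model$input_len` samples, or a matrix
#'   with one window per row.
#' @param engine `"compiled"` (single-precision kernels) or `"reference"`
#'   (pure-R double-precision composition of the exported layer functions;
#'   slow, used for validation).
#' @param batch Chunk size for the compiled path (default 128).
#' @return Numeric matrix of probabilities (`n x n_class`), rows summing to
#'   1; a vector if a single window was supplied.
#' @export
predict_window <- function(model, window, engine = c("compiled", "reference"),
                           batch = 128) {
  engine <- match.arg(engine)
  single <- is.null(dim(window))
  x <- if (single) matrix(window, 1) else as.matrix(window)
  if (ncol(x) != model$input_len) {
    stop(sprintf("window has %d samples but the model expects %d",
                 ncol(x), model$input_len), call. = FALSE)
  }
  x <- standardize_windows(x)
  if (engine == "compiled") {
    cfg <- engine_cfg(model)
    flat <- flatten_params(model)
    out <- matrix(0, nrow(x), model$spec$n_class)
    for (start in seq(1, nrow(x), by = batch)) {
      idx <- start:min(start + batch - 1, nrow(x))
      out[idx, ] <- cpp_rcnn_forward(flat, cfg, t(x[idx, , drop = FALSE]),
                                     FALSE)
    }
  } else {
    out <- t(apply(x, 1, function(w) rcnn_forward_reference(model, w)))
  }
  colnames(out) <- model$classes
  if (single) out[1, ] else out
}

# double-precision reference forward for one standardized window
rcnn_forward_reference <- function(model, w) {
  spec <- model$spec
  a <- matrix(w, ncol = 1)
  for (i in seq_along(spec$blocks)) {
    bs <- spec$blocks[[i]]
    a <- residual_block_forward(a, model$params$blocks[[i]], bs$kernels,
                                bs$strides, spec$leaky_slope, spec$bn_eps)
  }
  if (model$pool_w > 1) {
    t_out <- nrow(a) %/% model$pool_w
    a <- sapply(seq_len(ncol(a)), function(cc) {
      colMeans(matrix(a[seq_len(t_out * model$pool_w), cc], model$pool_w))
    })
    if (t_out == 1) a <- matrix(a, nrow = 1)
  }
  layers <- lapply(model$params$rnn, function(p) {
    list(W = p$W, u = p$u, b = p$b,
         bn = list(gamma = p$gamma, beta = p$beta, rm = p$rm, rv = p$rv))
  })
  h <- indrnn_forward(a, layers, bn_eps = spec$bn_eps)
  d1 <- leaky_relu(as.numeric(h %*% model$params$dense$W) +
                     model$params$dense$b, spec$leaky_slope)
  softmax(as.numeric(d1 %*% model$params$out$W) + model$params$out$b)
}
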