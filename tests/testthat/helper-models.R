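# small architectures and datasets shared across tests; everything is
# generated in code, nothing is read from fixtures on disk

tiny_arch <- function(n_class = 3, f = c(4, 6, 4), rnn = c(5, 5), dense = 8) {
  architecture_spec(
    blocks = list(block_spec(f[1]), block_spec(f[2]),
                  block_spec(f[3], projection_shortcut = FALSE)),
    rnn_layers = rnn, dense_units = dense, n_class = n_class
  )
}

# low-rate synthetic windows: cheap to train on, still class-separable
tiny_windows <- function(n_per_class, classes = c("normal", "ictal"),
                         fs = 100, seed = 1) {
  gen_labeled_windows(n_per_class, classes, fs = fs, window_s = 10,
                      seed = seed)
}

expect_partition <- function(periods, duration_s, step = 0.5) {
  pts <- seq(0, duration_s - step, by = step)
  claims <- sapply(pts, function(t) {
    sum(vapply(c("preictal", "ictal", "interictal", "excluded"), function(f) {
      iv <- periods[[f]]
      any(iv$start_s <= t & t < iv$end_s)
    }, logical(1)))
  })
  expect_true(all(claims == 1L))
}
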