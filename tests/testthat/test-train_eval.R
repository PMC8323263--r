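test_that("fold assignment is balanced, exhaustive and seed-stable", {
  f <- make_folds(500, k = 10, seed = 1)
  expect_equal(as.integer(table(f)), rep(50L, 10))
  expect_equal(make_folds(500, 10, seed = 1), f)
  expect_false(identical(make_folds(500, 10, seed = 2), f))
  expect_equal(sort(unique(make_folds(10, 10, seed = 3))), 1:10)
  expect_error(make_folds(5, 10), "at least k")
})

test_that("stratified folds hold near-equal class counts", {
  labels <- rep(c("A", "E"), each = 100)
  f <- make_folds(200, k = 10, seed = 4, labels = labels)
  tab <- table(labels, f)
  expect_true(all(tab == 10L))
  # uneven classes: per-fold class counts differ by at most one
  labels2 <- rep(c("a", "b", "c"), c(47, 31, 22))
  f2 <- make_folds(100, k = 10, seed = 4, labels = labels2)
  expect_true(all(abs(diff(range(table(f2)))) <= 1))
  tab2 <- table(labels2, f2)
  expect_true(all(apply(tab2, 1, function(r) diff(range(r)) <= 1)))
})

test_that("metric formulas match their definitions exactly", {
  expect_equal(compute_metrics(confusion_counts(10, 0, 10, 0))[1:3],
               list(sen = 1, spe = 1, acc = 1))
  m <- compute_metrics(confusion_counts(45, 5, 40, 10))
  expect_equal(c(m$sen, m$spe, m$acc), c(0.90, 0.80, 0.85))
  und <- compute_metrics(confusion_counts(0, 0, 5, 5))
  expect_true(is.na(und$sen))
  expect_equal(und$undefined, "sen")
})

test_that("training runs the configured epochs and respects the u-clip", {
  lw <- tiny_windows(32, classes = c("normal", "ictal"), fs = 50, seed = 2)
  m <- build_rcnn(tiny_arch(n_class = 2), input_len = 500, seed = 1)
  fit <- train(m, lw, train_config(epochs = 2, batch_size = 64, seed = 3))
  expect_length(fit$history, 2L)
  expect_true(all(is.finite(fit$history)))
  expect_equal(fit$model$classes, c("ictal", "normal"))
  for (ly in fit$model$params$rnn) {
    expect_lte(max(abs(ly$u)), fit$model$u_clip + 1e-6)
  }
})

test_that("a zero learning rate leaves all weights untouched", {
  lw <- tiny_windows(8, classes = c("normal", "ictal"), fs = 50, seed = 5)
  m <- build_rcnn(tiny_arch(n_class = 2), input_len = 500, seed = 2)
  before <- rcnneeg:::flatten_params(m)
  fit <- train(m, lw, train_config(learning_rate = 0, epochs = 1, seed = 1))
  after <- rcnneeg:::flatten_params(fit$model)
  for (nm in names(before)) {
    if (grepl("_(rm|rv)$", nm)) next       # BN statistics may move
    expect_equal(after[[nm]], before[[nm]], tolerance = 1e-6, info = nm)
  }
})

test_that("training errors early on malformed inputs", {
  lw <- tiny_windows(4, classes = c("normal", "ictal"), fs = 50)
  m3 <- build_rcnn(tiny_arch(n_class = 3), input_len = 500)
  expect_error(train(m3, lw, train_config(epochs = 1)), "n_class")
  m_wrong <- build_rcnn(tiny_arch(n_class = 2), input_len = 400)
  expect_error(train(m_wrong, lw, train_config(epochs = 1)), "expects 400")
})

test_that("the model can overfit a small separable training set", {
  lw <- tiny_windows(20, classes = c("normal", "ictal"), fs = 100, seed = 8)
  m <- build_rcnn(tiny_arch(n_class = 2), input_len = 1000, seed = 3)
  fit <- train(m, lw, train_config(epochs = 25, batch_size = 32, seed = 4))
  ev <- evaluate(fit$model, lw)
  expect_gte(sum(diag(ev$confusion)) / sum(ev$confusion), 0.99)
})

test_that("evaluation tallies argmax predictions into consistent counts", {
  lw <- tiny_windows(12, classes = c("normal", "ictal"), fs = 50, seed = 6)
  m <- build_rcnn(tiny_arch(n_class = 2), input_len = 500, seed = 5)
  fit <- train(m, lw, train_config(epochs = 3, batch_size = 16, seed = 2))
  ev <- evaluate(fit$model, lw)
  expect_equal(rowSums(ev$confusion), c(ictal = 12, normal = 12))
  expect_equal(sum(ev$confusion), 24)
  # brute-force recount from the emitted predictions
  for (cl in fit$model$classes) {
    truth_pos <- lw$label == cl
    pred_pos <- ev$predicted == cl
    expect_equal(ev$counts[[cl]]$TP, sum(truth_pos & pred_pos))
    expect_equal(ev$counts[[cl]]$FN, sum(truth_pos & !pred_pos))
    expect_equal(ev$counts[[cl]]$FP, sum(!truth_pos & pred_pos))
    expect_equal(ev$counts[[cl]]$TN, sum(!truth_pos & !pred_pos))
  }
  expect_error(evaluate(fit$model, rcnneeg:::subset_labeled(lw, integer(0))),
               "empty test set")
})

test_that("cross-validation covers every window once and averages folds", {
  lw <- tiny_windows(15, classes = c("normal", "ictal"), fs = 50, seed = 9)
  rep_ <- cross_validate(lw, tiny_arch(n_class = 2, f = c(3, 4, 3), rnn = c(4, 4)),
                         train_config(epochs = 2, batch_size = 16, seed = 11),
                         k = 3)
  expect_equal(nrow(rep_$per_fold), 3L)
  expect_equal(unname(rep_$mean["acc"]), mean(rep_$per_fold$acc))
  expect_equal(unname(rep_$mean["sen"]), mean(rep_$per_fold$sen))
  expect_equal(length(rep_$fold_assignment), 30L)
  expect_equal(sort(unique(rep_$fold_assignment)), 1:3)
  # confusion conservation: entries sum to the fold's test-set size
  for (f in 1:3) {
    expect_equal(sum(rep_$confusions[[f]]), sum(rep_$fold_assignment == f))
  }
  expect_equal(rep_$positive, "ictal")
})

test_that("metrics tables render the Spec/Sen/Acc layout", {
  cm <- matrix(c(9, 1, 0, 10), 2, dimnames = list(c("ictal", "normal"),
                                                  c("ictal", "normal")))
  fake <- structure(list(per_fold = data.frame(fold = 1, sen = 0.9, spe = 1,
                                               acc = 0.95),
                         mean = c(sen = 0.9, spe = 1, acc = 0.95),
                         confusions = list(cm), classes = c("ictal", "normal"),
                         positive = "ictal", k = 1, fold_assignment = rep(1, 20)),
                    class = "metrics_report")
  tab <- metrics_table(list(rcnn = fake))
  expect_match(tab[1], "Method\\s+Spec\\s+Sen\\s+Acc")
  expect_match(tab[2], "rcnn\\s+100.00\\s+90.00\\s+95.00")
})
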