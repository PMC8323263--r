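#' Training configuration
#'
#' Mini-batch stochastic gradient descent with momentum and categorical
#' cross-entropy loss. The reference recipe trains with batch size 64 for
#' 512 iterations; `iterations_as` controls whether `epochs` counts full
#' passes over the training set (`"epochs"`, the default Keras-idiom
#' reading) or single batch steps (`"steps"`).
#'
#' @param learning_rate SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size Mini-batch size (default 64).
#' @param epochs Number of epochs (default 512).
#' @param iterations_as `"epochs"` or `"steps"` (see above).
#' @param seed Integer seed controlling shuffling (and, via [train()],
#'   everything stochastic in a run).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         batch_size = 64, epochs = 512,
                         iterations_as = c("epochs", "steps"), seed = 1) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate >= 0,
            momentum >= 0, momentum < 1)
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         iterations_as = match.arg(iterations_as), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Assign items to k cross-validation folds
#'
#' Seeded random assignment with fold sizes differing by at most one. When
#' `labels` are supplied the split is stratified: each class is dealt
#' round-robin (with a rotating offset so overall fold sizes stay balanced),
#' giving near-equal class counts per fold.
#'
#' @param n_items Number of items (>= k).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param labels Optional class labels (length `n_items`) for
#'   stratification.
#' @return Integer vector of fold indices in `1..k`, one per item.
#' @export
make_folds <- function(n_items, k = 10, seed = 1, labels = NULL) {
  if (n_items < k) {
    stop(sprintf("need at least k = %d items, got %d", k, n_items),
         call. = FALSE)
  }
  rng <- local_rng(seed)
  fold <- integer(n_items)
  if (is.null(labels)) {
    perm <- rng$permute(n_items)
    fold[perm] <- rep_len(seq_len(k), n_items)
  } else {
    stopifnot(length(labels) == n_items)
    offset <- 0L
    for (cl in sort(unique(as.character(labels)))) {
      idx <- which(labels == cl)
      idx <- idx[rng$permute(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  }
  fold
}

#' Train a model on labeled windows
#'
#' Standardizes each window (zero mean, unit variance), shuffles with the
#' configured seed, and runs mini-batch SGD with momentum through the
#' compiled single-precision engine. The recurrent-weight constraint
#' `|u| <= u_clip` is re-applied after every update.
#'
#' @param model An `rcnn_model` from [build_rcnn()].
#' @param data A `labeled_windows` object; window length must equal
#'   `model$input_len` and the number of distinct labels must equal the
#'   architecture's `n_class`.
#' @param config A [train_config()].
#' @return A list with `model` (trained; `model$classes` records the label
#'   order of the output units) and `history` (numeric vector, mean
#'   cross-entropy per epoch).
#' @export
train <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "rcnn_model"), inherits(data, "labeled_windows"),
            inherits(config, "train_config"))
  if (ncol(data$x) != model$input_len) {
    stop(sprintf("windows have %d samples but the model expects %d",
                 ncol(data$x), model$input_len), call. = FALSE)
  }
  classes <- sort(unique(data$label))
  if (length(classes) != model$spec$n_class) {
    stop(sprintf("found %d classes (%s) but the architecture has n_class = %d",
                 length(classes), paste(classes, collapse = ", "),
                 model$spec$n_class), call. = FALSE)
  }
  n <- nrow(data$x)
  y <- match(data$label, classes) - 1L
  x <- standardize_windows(data$x)

  if (config$iterations_as == "steps") {
    steps_per_epoch <- ceiling(n / config$batch_size)
    epochs <- max(1L, ceiling(config$epochs / steps_per_epoch))
  } else {
    epochs <- config$epochs
  }
  rng <- local_rng(config$seed)
  order_mat <- vapply(seq_len(epochs), function(e) rng$permute(n),
                      integer(n))

  fit <- cpp_rcnn_train(flatten_params(model), engine_cfg(model),
                        t(x), y, order_mat, config$batch_size,
                        config$learning_rate, config$momentum)
  model$params <- unflatten_params(model, fit$params)
  model$classes <- classes
  model$fs <- data$fs                 # for streaming-time validation
  list(model = model, history = as.numeric(fit$loss))
}

#' Confusion counts from a one-vs-rest quadruple
#'
#' @param TP,FN,TN,FP Non-negative integer counts.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FN, TN, FP) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Computes `sen = TP/(TP+FN)`, `spe = TN/(TN+FP)` and
#' `acc = (TP+TN)/(TP+FN+TN+FP)`. A metric whose denominator is zero is
#' undefined: it is returned as `NA` and named in the `undefined` field
#' rather than silently reported as 0.
#'
#' @param counts A [confusion_counts()] object (or list with TP/FN/TN/FP).
#' @return List with `sen`, `spe`, `acc` (each in `[0, 1]` or NA) and
#'   `undefined` (character vector of flagged metrics).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FN <- counts$FN; TN <- counts$TN; FP <- counts$FP
  undefined <- character(0)
  sen <- if (TP + FN > 0) TP / (TP + FN) else {
    undefined <- c(undefined, "sen"); NA_real_
  }
  spe <- if (TN + FP > 0) TN / (TN + FP) else {
    undefined <- c(undefined, "spe"); NA_real_
  }
  tot <- TP + FN + TN + FP
  acc <- if (tot > 0) (TP + TN) / tot else {
    undefined <- c(undefined, "acc"); NA_real_
  }
  list(sen = sen, spe = spe, acc = acc, undefined = undefined)
}

#' Evaluate a trained model on a labeled test set
#'
#' Predicts by argmax over the class probabilities and tallies a raw
#' confusion matrix (rows = true class, columns = predicted) plus per-class
#' one-vs-rest TP/FN/TN/FP counts.
#'
#' @param model A trained `rcnn_model`.
#' @param test_set A non-empty `labeled_windows` object whose labels are a
#'   subset of `model$classes`.
#' @return List with `confusion` (matrix), `counts` (named list of
#'   [confusion_counts()] per class) and `predicted` (character vector).
#' @export
evaluate <- function(model, test_set) {
  stopifnot(inherits(test_set, "labeled_windows"))
  if (nrow(test_set$x) == 0L) stop("empty test set", call. = FALSE)
  if (is.null(model$classes)) stop("model has not been trained", call. = FALSE)
  probs <- predict_window(model, test_set$x)
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  pred <- model$classes[max.col(probs, ties.method = "first")]
  cm <- table(factor(test_set$label, levels = model$classes),
              factor(pred, levels = model$classes))
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm),
               dimnames = list(true = model$classes, pred = model$classes))
  counts <- lapply(model$classes, function(cl) {
    i <- match(cl, model$classes)
    confusion_counts(TP = cm[i, i],
                     FN = sum(cm[i, -i]),
                     TN = sum(cm[-i, -i]),
                     FP = sum(cm[-i, i]))
  })
  names(counts) <- model$classes
  list(confusion = cm, counts = counts, predicted = pred)
}

# fold-level metrics: binary tasks use the designated positive class;
# multi-class sen/spe are macro-averaged one-vs-rest; acc is the overall
# correct fraction in both cases
fold_metrics <- function(cm, classes, positive) {
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  per_class <- lapply(seq_along(classes), function(i) {
    compute_metrics(confusion_counts(
      TP = cm[i, i], FN = sum(cm[i, -i]),
      TN = sum(cm[-i, -i]), FP = sum(cm[-i, i])
    ))
  })
  names(per_class) <- classes
  if (length(classes) == 2L && !is.null(positive)) {
    m <- per_class[[positive]]
    sen <- m$sen
    spe <- m$spe
  } else {
    sen <- mean(vapply(per_class, `[[`, 1, "sen"), na.rm = TRUE)
    spe <- mean(vapply(per_class, `[[`, 1, "spe"), na.rm = TRUE)
  }
  list(sen = sen, spe = spe, acc = acc)
}

default_positive <- function(classes) {
  if (length(classes) != 2L) return(NULL)
  cand <- intersect(c("epileptic", "ictal", "preictal", "seizure"), classes)
  if (length(cand) > 0) cand[1] else classes[1]
}

#' k-fold cross-validation of the classifier
#'
#' Splits the dataset into `k` stratified folds, trains one freshly
#' initialized model per held-out fold and reports per-fold and mean
#' sensitivity, specificity and accuracy. For binary tasks sensitivity is
#' computed with respect to `positive`; for multi-class tasks sensitivity
#' and specificity are macro-averaged one-vs-rest and accuracy is the
#' overall correct fraction.
#'
#' @param dataset A `labeled_windows` object (balanced per task design).
#' @param spec An [architecture_spec()] with `n_class` matching the labels.
#' @param config A [train_config()]; `config$seed` drives fold assignment,
#'   parameter initialization and shuffling.
#' @param k Number of folds (default 10).
#' @param positive Positive class for binary sensitivity/specificity
#'   (default: the seizure-like class if recognizable, else the first).
#' @param verbose Print per-fold progress (default FALSE).
#' @return A list of class `metrics_report`: `per_fold` (data frame with
#'   `fold`, `sen`, `spe`, `acc`), `mean` (named vector), `confusions`
#'   (list of matrices), `fold_assignment`, `classes`, `positive`.
#' @export
cross_validate <- function(dataset, spec, config = train_config(), k = 10,
                           positive = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_windows"))
  classes <- sort(unique(dataset$label))
  if (length(classes) != spec$n_class) {
    stop("architecture n_class does not match the dataset's class count",
         call. = FALSE)
  }
  if (is.null(positive)) positive <- default_positive(classes)
  n <- nrow(dataset$x)
  fold <- make_folds(n, k, seed = config$seed, labels = dataset$label)
  per_fold <- vector("list", k)
  confusions <- vector("list", k)
  for (f in seq_len(k)) {
    fold_seed <- (as.numeric(config$seed) * 1000 + f) %% 2147483647
    model <- build_rcnn(spec, input_len = ncol(dataset$x), seed = fold_seed)
    cfg_f <- config
    cfg_f$seed <- as.integer(fold_seed)
    fit <- train(model, subset_labeled(dataset, fold != f), cfg_f)
    ev <- evaluate(fit$model, subset_labeled(dataset, fold == f))
    confusions[[f]] <- ev$confusion
    m <- fold_metrics(ev$confusion, classes, positive)
    per_fold[[f]] <- data.frame(fold = f, sen = m$sen, spe = m$spe,
                                acc = m$acc)
    if (verbose) {
      message(sprintf("fold %2d/%d: sen %.3f spe %.3f acc %.3f",
                      f, k, m$sen, m$spe, m$acc))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  structure(
    list(per_fold = per_fold,
         mean = c(sen = mean(per_fold$sen), spe = mean(per_fold$spe),
                  acc = mean(per_fold$acc)),
         confusions = confusions,
         fold_assignment = fold,
         classes = classes,
         positive = positive,
         k = k),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over classes {%s}%s\n", x$k,
              paste(x$classes, collapse = ", "),
              if (!is.null(x$positive)) sprintf(" (positive: %s)", x$positive)
              else ""))
  cat(sprintf(" fold  %6s %6s %6s\n", "Sen", "Spe", "Acc"))
  for (i in seq_len(nrow(x$per_fold))) {
    cat(sprintf("  %2d   %6.2f %6.2f %6.2f\n", x$per_fold$fold[i],
                100 * x$per_fold$sen[i], 100 * x$per_fold$spe[i],
                100 * x$per_fold$acc[i]))
  }
  cat(sprintf(" mean  %6.2f %6.2f %6.2f  (percent)\n",
              100 * x$mean["sen"], 100 * x$mean["spe"], 100 * x$mean["acc"]))
  invisible(x)
}

#' Text report in the two-column evaluation layout
#'
#' Formats one or more cross-validation reports as a plain-text table with
#' Method / Spec / Sen / Acc columns (percentages).
#'
#' @param reports Named list of `metrics_report` objects (names become the
#'   Method column).
#' @return Character vector of table lines.
#' @export
metrics_table <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  lines <- sprintf("%-24s %8s %8s %8s", "Method", "Spec", "Sen", "Acc")
  for (nm in names(reports)) {
    m <- reports[[nm]]$mean
    lines <- c(lines, sprintf("%-24s %8.2f %8.2f %8.2f", nm,
                              100 * m["spe"], 100 * m["sen"], 100 * m["acc"]))
  }
  lines
}
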