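ev <- function(...) {
  v <- c(...)
  if (is.null(v)) return(data.frame(onset_s = numeric(0),
                                    offset_s = numeric(0)))
  m <- matrix(v, ncol = 2, byrow = TRUE)
  data.frame(onset_s = m[, 1], offset_s = m[, 2])
}

test_that("seizures closer than the merge gap collapse into one event", {
  out <- merge_seizures(ev(1000, 1060, 2500, 2590), gap_min = 30)
  expect_equal(out, ev(1000, 2590))          # gap 1440 s < 1800 s
  far <- ev(0, 60, 4000, 4060)
  expect_equal(merge_seizures(far), far)     # gap 3940 s >= 1800 s
})

test_that("merging is transitive, idempotent and validates its input", {
  chain <- ev(0, 60, 1500, 1560, 3000, 3060)
  merged <- merge_seizures(chain)
  expect_equal(merged, ev(0, 3060))
  # brute-force transitive closure of the pairwise rule
  brute <- chain
  repeat {
    gaps <- brute$onset_s[-1] - brute$offset_s[-nrow(brute)]
    i <- which(gaps < 1800)[1]
    if (is.na(i)) break
    brute$offset_s[i] <- max(brute$offset_s[i], brute$offset_s[i + 1])
    brute <- brute[-(i + 1), ]
    rownames(brute) <- NULL
  }
  expect_equal(merged, brute)
  expect_equal(merge_seizures(merged), merged)
  expect_error(merge_seizures(ev(100, 160, 10, 60)), "sorted")
})

test_that("periods around a single seizure follow the clearance rules", {
  per <- derive_periods(ev(7200, 7300), 36000)
  expect_equal(per$preictal, data.frame(start_s = 5100, end_s = 6900))
  expect_equal(per$ictal, data.frame(start_s = 7200, end_s = 7300))
  expect_equal(per$interictal,
               data.frame(start_s = c(0, 10900), end_s = c(4800, 36000)))
  # brute-force per-second classifier straight from the stated offsets
  for (t in seq(0, 35999, by = 7)) {
    truth <- if (t >= 7200 && t < 7300) "ictal"
    else if (t >= 7200 - 2100 && t < 7200 - 300) "preictal"
    else if (t < 7200 - 2400 || t >= 7300 + 3600) "interictal"
    else "excluded"
    got <- rcnneeg:::.contains_window(per, t, t + 1e-9)
    expect_equal(got, truth, info = sprintf("t = %d", t))
  }
  expect_partition(per, 36000)
})

test_that("preictal intervals clip at the record start and earlier events", {
  per <- derive_periods(ev(600, 660), 7200)
  expect_equal(per$preictal, data.frame(start_s = 0, end_s = 300))
  # second event's preictal truncated at the first event's offset (the first
  # event's own preictal window lies entirely before the record and drops)
  per2 <- derive_periods(ev(100, 160, 2000, 2060), 9000)
  expect_equal(per2$preictal, data.frame(start_s = 160, end_s = 2000 - 300))
})

test_that("with no seizures the whole record is interictal", {
  per <- derive_periods(ev(), 1000)
  expect_equal(per$interictal, data.frame(start_s = 0, end_s = 1000))
  expect_equal(nrow(per$preictal), 0L)
  expect_equal(nrow(per$excluded), 0L)
})

test_that("the four period sets partition the record for random event sets", {
  set.seed(11)
  for (rep in 1:10) {
    n_ev <- sample(1:4, 1)
    onsets <- sort(runif(n_ev, 0, 80000))
    events <- data.frame(onset_s = onsets, offset_s = onsets + runif(n_ev, 20, 200))
    events <- merge_seizures(events)
    events <- events[events$offset_s < 86400, , drop = FALSE]
    if (nrow(events) == 0) next
    per <- derive_periods(events, 86400)
    expect_partition(per, 86400, step = 97)
  }
})

test_that("windows are labeled only when fully inside one interval", {
  per <- derive_periods(ev(7200, 7300), 36000)
  w <- structure(list(
    x = matrix(0, 4, 10),
    t_start_s = c(5100, 6895, 7200, 7295),
    subject_id = "s", fs = 1, window_s = 10
  ), class = "eeg_windows")
  lw <- label_windows(w, per)
  # [5100,5110) preictal; [6895,6905) straddles and is dropped;
  # [7200,7210) ictal; [7295,7305) straddles ictal end and is dropped
  expect_equal(lw$label, c("preictal", "ictal"))
  expect_equal(lw$t_start_s, c(5100, 7200))
  # no labeled window overlaps an ictal span unless labeled ictal
  over_ictal <- lw$t_start_s < 7300 & lw$t_start_s + 10 > 7200
  expect_true(all(lw$label[over_ictal] == "ictal"))
})

test_that("class balancing undersamples to the minority deterministically", {
  lw <- labeled_windows(matrix(rnorm(500 * 4), 500),
                        rep(c("non_epileptic", "epileptic"), c(400, 100)),
                        "s", seq_len(500), fs = 1, window_s = 4)
  bal <- balance_classes(lw, seed = 5)
  expect_equal(unname(table(bal$label)["epileptic"]), 100L)
  expect_equal(unname(table(bal$label)["non_epileptic"]), 100L)
  bal2 <- balance_classes(lw, seed = 5)
  expect_identical(bal$t_start_s, bal2$t_start_s)
  bal3 <- balance_classes(lw, seed = 6)
  expect_false(identical(bal$t_start_s, bal3$t_start_s))
  # balancing never changes a window's label, only multiplicity
  key <- paste(lw$t_start_s, lw$label)
  expect_true(all(paste(bal$t_start_s, bal$label) %in% key))
})

test_that("balancing an already balanced set keeps every window", {
  lw <- labeled_windows(matrix(0, 6, 2), rep(c("a", "b"), each = 3),
                        "s", 1:6, fs = 1, window_s = 2)
  bal <- balance_classes(lw, seed = 1)
  expect_equal(sort(bal$t_start_s), 1:6)
  lw_missing <- labeled_windows(matrix(0, 3, 2), rep("a", 3), "s", 1:3,
                                fs = 1, window_s = 2)
  expect_error(balance_classes(lw_missing, seed = 1, class_set = c("a", "b")),
               "'b' absent")
})
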