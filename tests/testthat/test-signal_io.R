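test_that("plain-text records parse in file order with derived subject id", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "-2", "3"), p)
  rec <- read_bonn_ascii(p, fs = 100)
  expect_equal(rec$samples, c(1, -2, 3))
  expect_equal(duration_s(rec), 0.03)
  expect_equal(rec$subject_id, tools::file_path_sans_ext(basename(p)))
})

test_that("reader rejects empty and malformed files with located errors", {
  p <- withr::local_tempfile(fileext = ".txt")
  file.create(p)
  expect_error(read_bonn_ascii(p, fs = 100), "no samples")
  writeLines(c("1.5", "oops", "2"), p)
  expect_error(read_bonn_ascii(p, fs = 100), "line 2")
  expect_error(read_bonn_ascii(file.path(tempdir(), "absent.txt")),
               "no such file")
})

test_that("a 23.6 s benchmark-style record has 4097 samples at 173.61 Hz", {
  rec <- gen_class_record(synth_spec(fs = 173.61, duration_s = 23.6,
                                     class_name = "normal", seed = 3))
  p <- withr::local_tempfile(fileext = ".txt")
  write_bonn_ascii(rec, p)
  # independent oracle: count lines in the written file
  expect_equal(length(readLines(p)), 4097L)
  back <- read_bonn_ascii(p, fs = 173.61)
  expect_equal(length(back$samples), 4097L)
  expect_equal(duration_s(back), 23.6, tolerance = 1e-3)
})

test_that("ASCII round-trip reproduces samples to configured precision", {
  rec <- gen_class_record(synth_spec(fs = 100, duration_s = 2,
                                     class_name = "interictal", seed = 9))
  p <- withr::local_tempfile(fileext = ".txt")
  write_bonn_ascii(rec, p, digits = 15)
  back <- read_bonn_ascii(p, fs = 100)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
})

test_that("annotation tables group, sort and validate per subject", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,onset_s,offset_s",
               "s1,2500,2590", "s1,1000,1060", "s2,10,20"), p)
  ann <- read_annotations(p)
  expect_named(ann, c("s1", "s2"))
  expect_equal(ann$s1$onset_s, c(1000, 2500))

  writeLines(c("subject,onset_s,offset_s", "s1,50,40"), p)
  expect_error(read_annotations(p), "row 1")
  writeLines(c("subject,onset_s,offset_s", "s1,10,100", "s1,50,200"), p)
  expect_error(read_annotations(p), "overlapping")
})

test_that("a 15-subject / 168-event table round-trips through CSV", {
  set.seed(42)
  rows <- do.call(rbind, lapply(1:15, function(s) {
    n <- if (s <= 13) 11 else if (s == 14) 12 else 13   # 13*11 + 12 + 13 = 168
    onset <- cumsum(runif(n, 4000, 8000))
    data.frame(subject = sprintf("p%02d", s), onset_s = onset,
               offset_s = onset + runif(n, 30, 120))
  }))
  expect_equal(nrow(rows), 168L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_annotations(rows, p)
  ann <- read_annotations(p)
  expect_length(ann, 15L)
  expect_equal(sum(vapply(ann, nrow, 1L)), 168L)
})

test_that("segmentation yields fixed-size windows and drops the remainder", {
  rec <- eeg_record(seq_len(100 * 500), fs = 500, subject_id = "a")
  w <- segment_record(rec, window_s = 10, overlap_s = 0)
  expect_equal(dim(w$x), c(10L, 5000L))
  expect_equal(w$t_start_s, seq(0, 90, by = 10))

  rec2 <- eeg_record(seq_len(4097), fs = 173.61, subject_id = "b")
  w2 <- segment_record(rec2, window_s = 23.6)
  expect_equal(nrow(w2$x), 1L)

  w3 <- segment_record(rec, window_s = 10, overlap_s = 5)
  expect_equal(nrow(w3$x), 19L)     # floor((100 - 10)/5) + 1
})

test_that("segmentation with no overlap conserves the record prefix", {
  rec <- eeg_record(rnorm(1234), fs = 50, subject_id = "c")
  w <- segment_record(rec, window_s = 4)
  expect_equal(as.numeric(t(w$x)), rec$samples[seq_len(nrow(w$x) * ncol(w$x))])
})

test_that("window counts match brute-force start-time enumeration", {
  for (fs in c(50, 173.61)) {
    for (dur in c(20, 23.6, 61)) {
      rec <- eeg_record(rnorm(round(dur * fs)), fs = fs, subject_id = "p")
      for (win in c(5, 10)) {
        for (ov in c(0, 2, 4)) {
          w <- segment_record(rec, win, ov)
          # brute force: enumerate starts on the sample grid
          wl <- round(win * fs)
          step <- round((win - ov) * fs)
          starts <- seq(1, length(rec$samples), by = step)
          expected <- sum(starts + wl - 1 <= length(rec$samples))
          expect_equal(nrow(w$x), expected,
                       info = sprintf("fs=%g dur=%g win=%g ov=%g", fs, dur, win, ov))
        }
      }
    }
  }
})

test_that("a record shorter than one window warns and yields no windows", {
  rec <- eeg_record(rnorm(100), fs = 100, subject_id = "short")
  expect_warning(w <- segment_record(rec, window_s = 10), "shorter")
  expect_equal(nrow(w$x), 0L)
  expect_error(segment_record(rec, window_s = 1, overlap_s = 1), "overlap_s")
})

test_that("windowed datasets persist and restore through the container", {
  lw <- tiny_windows(3, classes = c("normal", "ictal"), fs = 50)
  p <- withr::local_tempfile(fileext = ".rds")
  write_windows(lw, p)
  back <- read_windows(p)
  expect_equal(back$x, lw$x)
  expect_equal(back$label, lw$label)
  expect_equal(back$fs, lw$fs)
})
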