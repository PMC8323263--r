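#' Construct a single-channel EEG record
#'
#' An `eeg_record` holds one single-channel recording: a numeric sample
#' vector, its sampling rate, a subject identifier and the offset of the
#' first sample from the nominal recording start. All time coordinates in
#' this package are seconds from record start, and intervals are half-open
#' `[start, end)`.
#'
#' @param samples Numeric vector of amplitudes (microvolts, arbitrary
#'   reference). Must be non-empty and finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Subject/record identifier string.
#' @param start_offset_s Offset of the first sample in seconds (default 0).
#' @return An object of class `eeg_record` with fields `samples`, `fs`,
#'   `subject_id`, `start_offset_s`.
#' @examples
#' rec <- eeg_record(sin(seq_len(1000) / 10), fs = 100, subject_id = "s1")
#' duration_s(rec)
#' @export
eeg_record <- function(samples, fs, subject_id = "record", start_offset_s = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      fs = fs,
      subject_id = as.character(subject_id),
      start_offset_s = as.numeric(start_offset_s)
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> subject '%s': %d samples @ %g Hz (%.2f s)\n",
    x$subject_id, length(x$samples), x$fs, duration_s(x)
  ))
  invisible(x)
}

#' Record duration in seconds
#'
#' @param record An [eeg_record()].
#' @return Duration `length(samples) / fs` in seconds.
#' @export
duration_s <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  length(record$samples) / record$fs
}

#' Read a plain-text single-channel EEG record
#'
#' Reads the ASCII dialect used by the public Bonn EEG benchmark: one numeric
#' sample value per line (LF or CRLF), no header. The sampling rate is not
#' stored in the file and is taken as an explicit argument; the default of
#' 173.61 Hz is the public dataset's convention (a 4097-sample series spans
#' about 23.6 s), not a value stored in the format.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz to attach to the record (default 173.61).
#' @return An [eeg_record()] whose `subject_id` is the file name without
#'   extension.
#' @export
read_bonn_ascii <- function(path, fs = 173.61) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read EEG file '%s': no such file", path), call. = FALSE)
  }
  lines <- tryCatch(
    readLines(path, warn = FALSE),
    error = function(e) {
      stop(sprintf("cannot read EEG file '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1L]]
    stop(sprintf("non-numeric sample at line %d of '%s'", bad, path),
         call. = FALSE)
  }
  if (length(vals) == 0L) {
    stop(sprintf("'%s' contains no samples", path), call. = FALSE)
  }
  eeg_record(vals, fs = fs,
             subject_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a record in the plain-text one-sample-per-line dialect
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#' @param digits Significant digits retained (default 15, round-trip safe for
#'   all practical amplitudes).
#' @return `path`, invisibly.
#' @export
write_bonn_ascii <- function(record, path, digits = 15) {
  stopifnot(inherits(record, "eeg_record"))
  writeLines(formatC(record$samples, digits = digits, format = "g"), path)
  invisible(path)
}

#' Read a seizure annotation table
#'
#' Annotations are a CSV with header `subject,onset_s,offset_s`, one row per
#' annotated seizure, times in seconds from the start of that subject's
#' record. Events are returned grouped per subject and sorted by onset.
#'
#' @param path Path to the CSV file.
#' @return Named list (one element per subject) of data frames with columns
#'   `onset_s`, `offset_s`, sorted by `onset_s`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read annotations '%s': no such file", path),
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "onset_s", "offset_s")
  if (!all(need %in% names(df))) {
    stop("annotation file must have header subject,onset_s,offset_s",
         call. = FALSE)
  }
  bad <- which(!(df$onset_s < df$offset_s))
  if (length(bad) > 0L) {
    stop(sprintf("annotation row %d: onset_s (%g) must be < offset_s (%g)",
                 bad[1L], df$onset_s[bad[1L]], df$offset_s[bad[1L]]),
         call. = FALSE)
  }
  out <- lapply(split(df[c("onset_s", "offset_s")], df$subject), function(d) {
    d <- d[order(d$onset_s), , drop = FALSE]
    rownames(d) <- NULL
    if (nrow(d) > 1L && any(d$onset_s[-1L] < d$offset_s[-nrow(d)])) {
      stop("overlapping seizure events within one subject", call. = FALSE)
    }
    d
  })
  out[order(names(out))]
}

#' Write a seizure annotation table
#'
#' @param events Either a data frame with columns `subject`, `onset_s`,
#'   `offset_s`, or a named list of per-subject data frames as returned by
#'   [read_annotations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  if (is.data.frame(events)) {
    df <- events[c("subject", "onset_s", "offset_s")]
  } else {
    df <- do.call(rbind, lapply(names(events), function(s) {
      data.frame(subject = s, onset_s = events[[s]]$onset_s,
                 offset_s = events[[s]]$offset_s)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cut a record into fixed-length windows
#'
#' Windows start at t = 0 and advance by `window_s - overlap_s`; a trailing
#' remainder shorter than one window is discarded (the classifier operates on
#' fixed 10-s segments; padding would fabricate signal).
#'
#' @param record An [eeg_record()].
#' @param window_s Window length in seconds (default 10).
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (default 0; must satisfy `0 <= overlap_s < window_s`).
#' @return An object of class `eeg_windows`: a list with `x` (matrix,
#'   `n_windows` rows by `round(window_s * fs)` columns), `t_start_s`
#'   (numeric vector), `subject_id`, `fs`, `window_s`. If the record is
#'   shorter than one window an empty (0-row) set is returned with a warning.
#' @export
segment_record <- function(record, window_s = 10, overlap_s = 0) {
  stopifnot(inherits(record, "eeg_record"))
  if (!(overlap_s >= 0 && overlap_s < window_s)) {
    stop("need 0 <= overlap_s < window_s", call. = FALSE)
  }
  wl <- as.integer(round(window_s * record$fs))
  step <- window_s - overlap_s
  step_n <- as.integer(round(step * record$fs))
  n <- length(record$samples)
  if (wl > n) {
    warning("record shorter than one window; returning empty window set")
    starts <- integer(0)
  } else {
    starts <- seq.int(1L, n - wl + 1L, by = step_n)
  }
  x <- matrix(0, nrow = length(starts), ncol = wl)
  for (i in seq_along(starts)) {
    x[i, ] <- record$samples[starts[i]:(starts[i] + wl - 1L)]
  }
  structure(
    list(
      x = x,
      t_start_s = (starts - 1L) / record$fs,
      subject_id = record$subject_id,
      fs = record$fs,
      window_s = window_s
    ),
    class = "eeg_windows"
  )
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %d windows x %d samples (%g s @ %g Hz), subject '%s'\n",
              nrow(x$x), ncol(x$x), x$window_s, x$fs, x$subject_id))
  invisible(x)
}

#' Persist a windowed dataset
#'
#' Stores a (possibly labeled) window set as a single-file container: an R
#' RDS serialization of a plain list with elements `x` (numeric matrix,
#' windows in rows), `label` (character vector or NULL), and `provenance`
#' (data frame with `subject_id` and `t_start_s` per window) plus `fs` and
#' `window_s`. [read_windows()] restores it.
#'
#' @param windows An `eeg_windows` or `labeled_windows` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  lw <- as_labeled_windows(windows)
  saveRDS(list(x = lw$x, label = lw$label,
               provenance = data.frame(subject_id = lw$subject_id,
                                       t_start_s = lw$t_start_s),
               fs = lw$fs, window_s = lw$window_s),
          path)
  invisible(path)
}

#' Restore a windowed dataset written by [write_windows()]
#'
#' @param path File written by [write_windows()].
#' @return A `labeled_windows` object (`label` may be NA if unlabeled).
#' @export
read_windows <- function(path) {
  obj <- readRDS(path)
  labeled_windows(
    x = obj$x,
    label = if (is.null(obj$label)) rep(NA_character_, nrow(obj$x)) else obj$label,
    subject_id = obj$provenance$subject_id,
    t_start_s = obj$provenance$t_start_s,
    fs = obj$fs, window_s = obj$window_s
  )
}
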