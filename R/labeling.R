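#' Labeled window set
#'
#' Container pairing each fixed-length window with a class label and its
#' provenance (subject and start time within the source record).
#'
#' @param x Numeric matrix, one window per row.
#' @param label Character vector of class labels, one per row.
#' @param subject_id Character vector (recycled if length 1).
#' @param t_start_s Numeric vector of window start times in seconds.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @return An object of class `labeled_windows`.
#' @export
labeled_windows <- function(x, label, subject_id, t_start_s, fs, window_s) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(subject_id) == 1L) subject_id <- rep(subject_id, n)
  stopifnot(length(label) == n, length(subject_id) == n,
            length(t_start_s) == n)
  structure(
    list(x = x, label = as.character(label),
         subject_id = as.character(subject_id),
         t_start_s = as.numeric(t_start_s),
         fs = fs, window_s = window_s),
    class = "labeled_windows"
  )
}

#' @export
print.labeled_windows <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<labeled_windows> %d windows x %d samples: %s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

as_labeled_windows <- function(w) {
  if (inherits(w, "labeled_windows")) return(w)
  stopifnot(inherits(w, "eeg_windows"))
  labeled_windows(w$x, rep(NA_character_, nrow(w$x)), w$subject_id,
                  w$t_start_s, w$fs, w$window_s)
}

subset_labeled <- function(lw, idx) {
  labeled_windows(lw$x[idx, , drop = FALSE], lw$label[idx],
                  lw$subject_id[idx], lw$t_start_s[idx], lw$fs, lw$window_s)
}

#' Concatenate labeled window sets
#'
#' @param ... `labeled_windows` objects with identical window length and
#'   sampling rate.
#' @return A single `labeled_windows` object.
#' @export
bind_labeled_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "labeled_windows")) {
    parts <- parts[[1L]]
  }
  stopifnot(length(parts) >= 1L)
  fs <- parts[[1L]]$fs
  ws <- parts[[1L]]$window_s
  for (p in parts) stopifnot(p$fs == fs, p$window_s == ws)
  labeled_windows(
    do.call(rbind, lapply(parts, `[[`, "x")),
    unlist(lapply(parts, `[[`, "label")),
    unlist(lapply(parts, `[[`, "subject_id")),
    unlist(lapply(parts, `[[`, "t_start_s")),
    fs, ws
  )
}

check_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("onset_s", "offset_s") %in% names(events)))
  if (nrow(events) == 0L) return(invisible(events))
  if (any(events$onset_s >= events$offset_s)) {
    stop("each event needs onset_s < offset_s", call. = FALSE)
  }
  if (is.unsorted(events$onset_s, strictly = FALSE)) {
    stop("events must be sorted by onset_s", call. = FALSE)
  }
  if (nrow(events) > 1L &&
      any(events$onset_s[-1L] < events$offset_s[-nrow(events)])) {
    stop("events must be non-overlapping", call. = FALSE)
  }
  invisible(events)
}

#' Merge seizures separated by short gaps
#'
#' Clinically, a seizure starting less than `gap_min` minutes after the end
#' of the previous one is treated as a continuation of the same seizure; the
#' merged event spans both. Merging is transitive (a chain of close events
#' collapses into one) and idempotent.
#'
#' @param events Data frame with `onset_s`, `offset_s`, sorted by onset and
#'   non-overlapping.
#' @param gap_min Merge threshold in minutes (default 30): gap measured from
#'   previous offset to next onset.
#' @return Data frame of merged events, same columns.
#' @export
merge_seizures <- function(events, gap_min = 30) {
  check_events(events)
  if (nrow(events) <= 1L) return(events)
  gap_s <- gap_min * 60
  onset <- events$onset_s
  offset <- events$offset_s
  m_on <- onset[1L]
  m_off <- offset[1L]
  out_on <- numeric(0)
  out_off <- numeric(0)
  for (i in 2L:nrow(events)) {
    if (onset[i] - m_off < gap_s) {
      m_off <- max(m_off, offset[i])
    } else {
      out_on <- c(out_on, m_on)
      out_off <- c(out_off, m_off)
      m_on <- onset[i]
      m_off <- offset[i]
    }
  }
  data.frame(onset_s = c(out_on, m_on), offset_s = c(out_off, m_off))
}

#' Period-derivation parameters
#'
#' Defaults follow the labeling rules used throughout: the preictal segment
#' is the earliest 30 min of the 35 min before onset (leaving a 5-min guard
#' gap just before the seizure); interictal data must be at least 1 h past
#' the previous seizure's offset and at least 40 min before the next onset;
#' seizures closer than 30 min are merged.
#'
#' @param preictal_lead_min Start of the preictal segment, minutes before
#'   onset (default 35).
#' @param preictal_len_min Length of the preictal segment in minutes
#'   (default 30).
#' @param merge_gap_min Seizure merge threshold in minutes (default 30).
#' @param post_offset_clear_min Interictal clearance after a seizure offset,
#'   minutes (default 60).
#' @param pre_onset_clear_min Interictal clearance before a seizure onset,
#'   minutes (default 40).
#' @param window_s Analysis window length in seconds (default 10).
#' @return A list of class `period_params`.
#' @export
period_params <- function(preictal_lead_min = 35, preictal_len_min = 30,
                          merge_gap_min = 30, post_offset_clear_min = 60,
                          pre_onset_clear_min = 40, window_s = 10) {
  stopifnot(preictal_len_min <= preictal_lead_min,
            pre_onset_clear_min >= preictal_lead_min)
  structure(
    list(preictal_lead_min = preictal_lead_min,
         preictal_len_min = preictal_len_min,
         merge_gap_min = merge_gap_min,
         post_offset_clear_min = post_offset_clear_min,
         pre_onset_clear_min = pre_onset_clear_min,
         window_s = window_s),
    class = "period_params"
  )
}

# intersect a single [start, end) interval with the complement of a set of
# intervals, all within [0, dur)
clip_intervals <- function(iv, dur) {
  iv <- iv[iv[, 2L] > 0 & iv[, 1L] < dur, , drop = FALSE]
  iv[, 1L] <- pmax(iv[, 1L], 0)
  iv[, 2L] <- pmin(iv[, 2L], dur)
  iv[iv[, 1L] < iv[, 2L], , drop = FALSE]
}

interval_df <- function(m) {
  data.frame(start_s = m[, 1L], end_s = m[, 2L])
}

#' Derive preictal/ictal/interictal period intervals
#'
#' Partitions `[0, record_duration_s)` into four interval sets from merged
#' seizure annotations:
#' * **ictal** — the annotated event spans;
#' * **preictal** — `[onset - lead, onset - (lead - len))` before each event,
#'   clipped to the record and truncated at any earlier event's offset (with
#'   defaults: the earliest 30 of the 35 min before onset);
#' * **interictal** — time at least `post_offset_clear_min` after every
#'   previous offset and at least `pre_onset_clear_min` before every next
#'   onset;
#' * **excluded** — everything else (postictal recovery and guard gaps).
#'
#' The four sets are disjoint, sorted, and jointly cover the record.
#'
#' @param events Data frame of merged events (`onset_s`, `offset_s`), sorted.
#' @param record_duration_s Record duration in seconds.
#' @param params A [period_params()] object.
#' @return A list of class `period_intervals` with data-frame fields
#'   `preictal`, `ictal`, `interictal`, `excluded` (columns `start_s`,
#'   `end_s`).
#' @export
derive_periods <- function(events, record_duration_s,
                           params = period_params()) {
  check_events(events)
  stopifnot(inherits(params, "period_params"), record_duration_s > 0)
  dur <- record_duration_s
  if (nrow(events) > 0L && any(events$offset_s > dur)) {
    stop("events must lie within [0, record_duration_s)", call. = FALSE)
  }
  lead_s <- params$preictal_lead_min * 60
  len_s <- params$preictal_len_min * 60
  post_s <- params$post_offset_clear_min * 60
  pre_s <- params$pre_onset_clear_min * 60

  n <- nrow(events)
  if (n == 0L) {
    return(structure(
      list(preictal = interval_df(matrix(numeric(0), ncol = 2)),
           ictal = interval_df(matrix(numeric(0), ncol = 2)),
           interictal = interval_df(matrix(c(0, dur), ncol = 2)),
           excluded = interval_df(matrix(numeric(0), ncol = 2)),
           record_duration_s = dur),
      class = "period_intervals"
    ))
  }

  ictal <- cbind(events$onset_s, events$offset_s)

  pre <- cbind(events$onset_s - lead_s, events$onset_s - (lead_s - len_s))
  # truncate each preictal run at the previous event's offset
  if (n > 1L) {
    prev_off <- c(-Inf, events$offset_s[-n])
    pre[, 1L] <- pmax(pre[, 1L], prev_off)
  }
  pre <- clip_intervals(pre, dur)

  # interictal: gaps between events shrunk by the two clearances
  gap_lo <- c(0, events$offset_s + post_s)
  gap_hi <- c(events$onset_s - pre_s, dur)
  inter <- clip_intervals(cbind(gap_lo, gap_hi), dur)

  # excluded = complement of the union of the other three
  claimed <- rbind(ictal, pre, inter)
  claimed <- claimed[order(claimed[, 1L]), , drop = FALSE]
  excl <- matrix(numeric(0), ncol = 2)
  cursor <- 0
  for (i in seq_len(nrow(claimed))) {
    if (claimed[i, 1L] > cursor) {
      excl <- rbind(excl, c(cursor, claimed[i, 1L]))
    }
    cursor <- max(cursor, claimed[i, 2L])
  }
  if (cursor < dur) excl <- rbind(excl, c(cursor, dur))

  structure(
    list(preictal = interval_df(pre),
         ictal = interval_df(ictal),
         interictal = interval_df(inter),
         excluded = interval_df(excl),
         record_duration_s = dur),
    class = "period_intervals"
  )
}

#' @export
print.period_intervals <- function(x, ...) {
  for (f in c("preictal", "ictal", "interictal", "excluded")) {
    iv <- x[[f]]
    cat(sprintf("%-11s %s\n", f,
                if (nrow(iv) == 0) "(none)" else
                  paste(sprintf("[%g, %g)", iv$start_s, iv$end_s),
                        collapse = " ")))
  }
  invisible(x)
}

# which single interval set fully contains [t0, t1)? returns name or NA
.contains_window <- function(periods, t0, t1) {
  for (f in c("preictal", "ictal", "interictal", "excluded")) {
    iv <- periods[[f]]
    if (any(iv$start_s <= t0 & t1 <= iv$end_s)) {
      return(f)
    }
  }
  NA_character_
}

#' Label windows by period containment
#'
#' A window receives a class label iff it lies entirely inside one interval
#' of that class and the class belongs to `class_set`; windows that straddle
#' interval boundaries, fall in excluded regions, or carry a class outside
#' `class_set` are dropped (not majority-voted), avoiding label noise at
#' state transitions.
#'
#' @param windows An `eeg_windows` object from [segment_record()].
#' @param periods A `period_intervals` object from [derive_periods()].
#' @param class_set Character vector of admissible classes, e.g.
#'   `c("interictal", "preictal", "ictal")`.
#' @return A `labeled_windows` object containing only the retained windows.
#' @export
label_windows <- function(windows, periods,
                          class_set = c("interictal", "preictal", "ictal")) {
  stopifnot(inherits(windows, "eeg_windows"),
            inherits(periods, "period_intervals"))
  t0 <- windows$t_start_s
  t1 <- t0 + windows$window_s
  lab <- vapply(seq_along(t0), function(i) {
    .contains_window(periods, t0[i], t1[i])
  }, character(1))
  keep <- !is.na(lab) & lab %in% class_set
  labeled_windows(windows$x[keep, , drop = FALSE], lab[keep],
                  windows$subject_id, windows$t_start_s[keep],
                  windows$fs, windows$window_s)
}

#' Balance classes by seeded undersampling
#'
#' Down-samples every class, uniformly at random, to the minority class
#' count. Deterministic for a given seed; labels are never altered, only
#' multiplicity.
#'
#' @param items A `labeled_windows` object.
#' @param seed Integer seed for the sampling RNG.
#' @param class_set Classes that must all be present (default: the classes
#'   observed in `items`).
#' @return A `labeled_windows` object with equal class counts.
#' @export
balance_classes <- function(items, seed,
                            class_set = sort(unique(items$label))) {
  stopifnot(inherits(items, "labeled_windows"))
  counts <- table(factor(items$label, levels = class_set))
  if (any(counts == 0)) {
    stop(sprintf("class '%s' absent from input",
                 names(counts)[which(counts == 0)[1L]]), call. = FALSE)
  }
  n_min <- min(counts)
  keep <- integer(0)
  rng <- local_rng(seed)
  for (cl in class_set) {
    idx <- which(items$label == cl)
    if (length(idx) > n_min) {
      idx <- sort(rng$sample(idx, n_min))
    }
    keep <- c(keep, idx)
  }
  subset_labeled(items, sort(keep))
}

# Small seeded RNG scope: all randomness in the package funnels through
# explicit seeds without disturbing the caller's .Random.seed.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  use <- function(f) {
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      restore()
    })
    f()
  }
  list(
    sample = function(x, size) use(function() sample(x, size)),
    runif = function(n, min = 0, max = 1) use(function() runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) use(function() rnorm(n, mean, sd)),
    rpois = function(n, lambda) use(function() rpois(n, lambda)),
    permute = function(n) use(function() sample.int(n))
  )
}
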