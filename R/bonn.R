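#' External validation on the public Bonn EEG benchmark
#'
#' Runs the two-class (non-epileptic A-D undersampled vs seizure E) or
#' three-class (A/B normal, C/D interictal, E ictal) experiment with the
#' full default architecture on a locally downloaded copy of the public
#' five-group benchmark. The data are not redistributed with this package;
#' `data_dir` must contain one subdirectory per group (`A`..`E` or the
#' original `Z`/`O`/`N`/`F`/`S` names), each holding the 100 plain-text
#' records. See `scripts/bonn_experiment.R` for a runnable entry point.
#'
#' @param data_dir Directory containing the five group subdirectories.
#' @param task `"two_class"` or `"three_class"`.
#' @param fs Sampling rate to attach (default 173.61 Hz, the benchmark
#'   convention).
#' @param config A [train_config()]; the default mirrors the reference
#'   recipe (batch 64, 512 epochs).
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @return A `metrics_report` from [cross_validate()].
#' @export
run_bonn_experiment <- function(data_dir, task = c("two_class", "three_class"),
                                fs = 173.61, config = train_config(),
                                k = 10, seed = 1) {
  task <- match.arg(task)
  group_alias <- c(A = "Z", B = "O", C = "N", D = "F", E = "S")
  groups <- names(group_alias)
  dirs <- vapply(groups, function(g) {
    for (cand in c(g, group_alias[[g]], tolower(g), tolower(group_alias[[g]]))) {
      p <- file.path(data_dir, cand)
      if (dir.exists(p)) return(p)
    }
    NA_character_
  }, character(1))
  if (anyNA(dirs)) {
    stop(sprintf(
      paste("Bonn benchmark not found under '%s': missing group directories %s.",
            "Download the five-group public dataset and unpack each group",
            "(A-E or Z/O/N/F/S) into its own subdirectory."),
      data_dir, paste(groups[is.na(dirs)], collapse = ", ")), call. = FALSE)
  }
  class_of <- c(A = "normal", B = "normal", C = "interictal",
                D = "interictal", E = "ictal")
  parts <- lapply(groups, function(g) {
    files <- list.files(dirs[[g]], pattern = "\\.(txt|TXT)$", full.names = TRUE)
    if (length(files) == 0L) {
      stop(sprintf("group %s directory '%s' holds no .txt records",
                   g, dirs[[g]]), call. = FALSE)
    }
    recs <- lapply(files, read_bonn_ascii, fs = fs)
    x <- do.call(rbind, lapply(recs, function(r) {
      w <- segment_record(r, duration_s(r))
      w$x
    }))
    labeled_windows(x, rep(class_of[[g]], nrow(x)),
                    vapply(recs, `[[`, "", "subject_id"),
                    rep(0, nrow(x)), fs, ncol(x) / fs)
  })
  lw <- bind_labeled_windows(parts)
  lw <- make_task_dataset(lw, task)
  lw <- balance_classes(lw, seed = seed)
  spec <- architecture_spec(n_class = length(unique(lw$label)))
  config$seed <- as.integer(seed)
  cross_validate(lw, spec, config, k = k, verbose = TRUE)
}
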