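#' Synthetic EEG specification
#'
#' Parameters for the seeded single-channel EEG generator. The generator
#' produces caricatures with class-distinct temporal/spectral structure —
#' tuned for testability, not biophysical realism:
#' * **normal** — 1/f background noise plus a 10 Hz alpha rhythm;
#' * **interictal** — background plus sporadic (Poisson-timed) biphasic
#'   spikes;
#' * **preictal** — background with alpha power reduced by 30% and twice the
#'   interictal spike rate;
#' * **ictal** — background plus a continuous high-amplitude spike-wave
#'   train at `sw_freq_hz`.
#'
#' @param fs Sampling rate in Hz (default 500, the clinical-recording
#'   convention; Bonn-style series use 173.61).
#' @param duration_s Record duration in seconds.
#' @param class_name One of `"normal"`, `"interictal"`, `"preictal"`,
#'   `"ictal"`.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec and seed.
#' @param amp_background Background RMS amplitude in microvolts (default 20).
#' @param alpha_hz Alpha-rhythm frequency in Hz (default 10).
#' @param alpha_amp Alpha-rhythm amplitude in microvolts (default 10).
#' @param spike_rate_hz Interictal spike rate, events per second
#'   (default 0.5).
#' @param sw_freq_hz Ictal spike-wave frequency in Hz (default 3).
#' @param sw_amp_mult Spike and spike-wave amplitude as a multiple of the
#'   background RMS (default 5).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 500, duration_s = 10, class_name = "normal",
                       seed = 1, amp_background = 20, alpha_hz = 10,
                       alpha_amp = 10, spike_rate_hz = 0.5, sw_freq_hz = 3,
                       sw_amp_mult = 5) {
  stopifnot(fs > 0, duration_s > 0, spike_rate_hz >= 0, sw_freq_hz > 0,
            sw_amp_mult >= 0, amp_background >= 0, alpha_amp >= 0)
  class_name <- match.arg(class_name,
                          c("normal", "interictal", "preictal", "ictal"))
  structure(
    list(fs = fs, duration_s = duration_s, class_name = class_name,
         seed = as.integer(seed), amp_background = amp_background,
         alpha_hz = alpha_hz, alpha_amp = alpha_amp,
         spike_rate_hz = spike_rate_hz, sw_freq_hz = sw_freq_hz,
         sw_amp_mult = sw_amp_mult),
    class = "synth_spec"
  )
}

# 1/f ("pink") noise via spectral shaping of seeded white noise, scaled to
# a target RMS
pink_noise <- function(n, rms, rng) {
  if (rms <= 0) return(numeric(n))
  w <- rng$rnorm(n)
  spec <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)              # two-sided frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Generate background EEG (1/f noise + alpha rhythm)
#'
#' @param spec A [synth_spec()].
#' @return An [eeg_record()]; deterministic given `spec$seed`.
#' @export
gen_background <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  rng <- local_rng(spec$seed)
  n <- round(spec$fs * spec$duration_s)
  t <- (seq_len(n) - 1) / spec$fs
  phase <- rng$runif(1, 0, 2 * pi)
  x <- pink_noise(n, spec$amp_background, rng) +
    spec$alpha_amp * sin(2 * pi * spec$alpha_hz * t + phase)
  eeg_record(x, spec$fs,
             subject_id = sprintf("synth_%s_%d", spec$class_name, spec$seed))
}

# one biphasic transient of the given total duration (s), unit peak
biphasic_spike <- function(fs, dur = 0.07) {
  n <- max(3L, round(fs * dur))
  u <- seq(0, 1, length.out = n)
  w <- sin(2 * pi * u) * sin(pi * u)^2   # one full cycle, Hann-squared taper
  w / max(abs(w))
}

add_at <- function(x, wave, start_idx) {
  idx <- start_idx + seq_along(wave) - 1L
  ok <- idx >= 1L & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + wave[ok]
  x
}

# continuous spike-wave train: slow wave at f plus a sharp spike each cycle
spike_wave_train <- function(n, fs, f, amp) {
  t <- (seq_len(n) - 1) / fs
  slow <- 0.6 * sin(2 * pi * f * t)
  x <- slow
  spk <- biphasic_spike(fs) * 1.2
  starts <- round(seq(0, n / fs, by = 1 / f) * fs) + 1L
  for (s in starts) x <- add_at(x, spk, s)
  x * amp
}

#' Generate a single-class synthetic EEG record
#'
#' Adds the class-specific component described in [synth_spec()] to the
#' seeded background. For spike-bearing classes the realized spike onset
#' times (seconds) are attached as attribute `"spike_times"` for use in
#' generator-statistics checks.
#'
#' @param spec A [synth_spec()]; `spec$class_name` selects the texture.
#' @return An [eeg_record()].
#' @export
gen_class_record <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$fs * spec$duration_s)
  t <- (seq_len(n) - 1) / spec$fs
  rng <- local_rng(spec$seed)
  phase <- rng$runif(1, 0, 2 * pi)
  bg_noise <- pink_noise(n, spec$amp_background, rng)
  alpha_amp <- spec$alpha_amp
  rate <- 0
  if (spec$class_name == "preictal") {
    alpha_amp <- alpha_amp * sqrt(0.7)       # 30% power reduction
    rate <- 2 * spec$spike_rate_hz
  } else if (spec$class_name == "interictal") {
    rate <- spec$spike_rate_hz
  }
  x <- bg_noise + alpha_amp * sin(2 * pi * spec$alpha_hz * t + phase)
  bg_rms <- max(stats::sd(bg_noise), 1e-12)
  amp <- spec$sw_amp_mult * bg_rms
  spike_times <- numeric(0)
  if (rate > 0) {
    n_spk <- rng$rpois(1, rate * spec$duration_s)
    if (n_spk > 0) {
      spike_times <- sort(rng$runif(n_spk, 0, spec$duration_s - 0.07))
      spk <- biphasic_spike(spec$fs) * amp
      for (s in spike_times) x <- add_at(x, spk, round(s * spec$fs) + 1L)
    }
  }
  if (spec$class_name == "ictal") {
    x <- x + spike_wave_train(n, spec$fs, spec$sw_freq_hz, amp)
  }
  rec <- eeg_record(x, spec$fs,
                    subject_id = sprintf("synth_%s_%d", spec$class_name,
                                         spec$seed))
  attr(rec, "spike_times") <- spike_times
  rec
}

#' Band power of a signal
#'
#' Mean squared amplitude contributed by Fourier components within
#' `[band[1], band[2]]` Hz (raw periodogram integration). Used, e.g., to
#' verify that a simple 3 Hz band-energy threshold separates ictal from
#' normal synthetic records.
#'
#' @param samples Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric vector of band edges in Hz.
#' @return Scalar band power (amplitude-squared units).
#' @export
band_power <- function(samples, fs, band) {
  n <- length(samples)
  sp <- stats::fft(samples - mean(samples))
  freq <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1L)
  pow <- Mod(sp[half])^2 / n^2
  sel <- freq[half] >= band[1] & freq[half] <= band[2]
  2 * sum(pow[sel])
}

#' Generate a labeled synthetic window set
#'
#' Convenience builder for classifier experiments: `n_per_class` independent
#' fixed-length records per class, each generated with its own derived seed
#' and returned as one `labeled_windows` object.
#'
#' @param n_per_class Windows per class.
#' @param classes Character vector of class names (see [synth_spec()]).
#' @param fs Sampling rate in Hz (default 500).
#' @param window_s Window length in seconds (default 10).
#' @param seed Master integer seed.
#' @param ... Further arguments passed to [synth_spec()].
#' @return A `labeled_windows` object with `n_per_class * length(classes)`
#'   rows.
#' @export
gen_labeled_windows <- function(n_per_class,
                                classes = c("normal", "interictal", "ictal"),
                                fs = 500, window_s = 10, seed = 1, ...) {
  wl <- round(fs * window_s)
  x <- matrix(0, n_per_class * length(classes), wl)
  lab <- character(nrow(x))
  subj <- character(nrow(x))
  i <- 0L
  for (ci in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      # derive in double precision: exact below 2^53, no integer overflow
      sd_i <- (as.numeric(seed) * 1009 + ci * 131071 + j * 7919) %% 2147483647
      spec <- synth_spec(fs = fs, duration_s = window_s,
                         class_name = classes[ci], seed = sd_i, ...)
      x[i, ] <- gen_class_record(spec)$samples
      lab[i] <- classes[ci]
      subj[i] <- sprintf("synth_%s_%03d", classes[ci], j)
    }
  }
  labeled_windows(x, lab, subj, t_start_s = rep(0, nrow(x)),
                  fs = fs, window_s = window_s)
}

#' Generate a clinical-style session with annotated seizures
#'
#' Builds one long record by concatenating class textures consistent with
#' the returned annotation table: each seizure is preceded by a preictal
#' texture occupying the pre-onset labeling segment, surrounded by guard
#' gaps (background texture) and interictal texture elsewhere, so that
#' [derive_periods()] on the returned events labels the generated textures
#' correctly.
#'
#' @param n_seizures Number of seizures (>= 2, mirroring clinical records
#'   that contain at least two).
#' @param duration_s Total session duration in seconds.
#' @param fs Sampling rate in Hz (default 500).
#' @param seed Integer seed.
#' @param ictal_len_s Seizure duration in seconds (default 60).
#' @param params [period_params()] controlling the layout clearances.
#' @param ... Further texture arguments passed to [synth_spec()].
#' @return A list with `record` (an [eeg_record()]), `events` (data frame
#'   `onset_s`, `offset_s`) and `timeline` (data frame `class`, `start_s`,
#'   `end_s`: the texture each region was generated with — ground truth for
#'   labeling round-trip checks).
#' @export
gen_clinical_session <- function(n_seizures, duration_s, fs = 500, seed = 1,
                                 ictal_len_s = 60, params = period_params(),
                                 ...) {
  stopifnot(n_seizures >= 2)
  lead_s <- params$preictal_lead_min * 60
  pre_clear <- params$pre_onset_clear_min * 60
  post_clear <- params$post_offset_clear_min * 60
  # per-seizure footprint: pre-onset clearance + seizure + post-offset
  # clearance, plus one interictal block per gap so every state occurs
  inter_min <- 4 * params$window_s
  need <- n_seizures * (pre_clear + ictal_len_s + post_clear + inter_min)
  if (duration_s < need) {
    stop(sprintf(
      "duration_s too short for %d seizures: need at least %g s",
      n_seizures, need), call. = FALSE)
  }
  slack <- duration_s - need
  inter_len <- inter_min + slack / n_seizures
  onsets <- numeric(n_seizures)
  cursor <- 0
  segs <- list()
  ev_on <- numeric(0)
  gen <- function(class_name, dur, k) {
    sd_k <- (as.numeric(seed) * 2654435 + k * 97) %% 2147483647
    gen_class_record(synth_spec(fs = fs, duration_s = dur,
                                class_name = class_name, seed = sd_k,
                                ...))$samples
  }
  k <- 0L
  tl_class <- character(0)
  tl_start <- numeric(0)
  tl_end <- numeric(0)
  for (i in seq_len(n_seizures)) {
    # interictal block, then [onset - pre_clear, onset) split into
    # background guard / preictal / background guard, then the seizure,
    # then the postictal clearance (background texture)
    for (part in list(
      list("interictal", inter_len),
      list("normal", pre_clear - lead_s),
      list("preictal", params$preictal_len_min * 60),
      list("normal", lead_s - params$preictal_len_min * 60),
      list("ictal", ictal_len_s),
      list("normal", post_clear)
    )) {
      if (part[[2]] <= 0) next
      if (part[[1]] == "ictal") ev_on <- c(ev_on, cursor)
      k <- k + 1L
      segs[[k]] <- gen(part[[1]], part[[2]], k)
      tl_class <- c(tl_class, part[[1]])
      tl_start <- c(tl_start, cursor)
      tl_end <- c(tl_end, cursor + part[[2]])
      cursor <- cursor + part[[2]]
    }
  }
  samples <- unlist(segs)
  n_target <- round(duration_s * fs)
  if (length(samples) > n_target) samples <- samples[seq_len(n_target)]
  record <- eeg_record(samples, fs,
                       subject_id = sprintf("synth_session_%d", seed))
  events <- data.frame(onset_s = ev_on, offset_s = ev_on + ictal_len_s)
  list(record = record, events = events,
       timeline = data.frame(class = tl_class, start_s = tl_start,
                             end_s = tl_end))
}

#' Write a simulated Bonn-style dataset to disk
#'
#' Writes `n` single-class ASCII records per class (one sample per line)
#' plus a JSON manifest recording the seed and generator parameters.
#'
#' @param out_dir Output directory (created if needed).
#' @param classes Classes to simulate.
#' @param n Records per class.
#' @param fs Sampling rate in Hz (default 173.61, the Bonn-style rate).
#' @param duration_s Record length in seconds (default 23.6).
#' @param seed Master seed.
#' @param ... Further arguments to [synth_spec()].
#' @return Character vector of written record paths, invisibly.
#' @export
simulate_bonn_dir <- function(out_dir,
                              classes = c("normal", "interictal", "ictal"),
                              n = 10, fs = 173.61, duration_s = 23.6,
                              seed = 1, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ci in seq_along(classes)) {
    for (j in seq_len(n)) {
      sd_i <- (as.numeric(seed) * 1009 + ci * 131071 + j * 7919) %% 2147483647
      rec <- gen_class_record(synth_spec(fs = fs, duration_s = duration_s,
                                         class_name = classes[ci],
                                         seed = sd_i, ...))
      p <- file.path(out_dir, sprintf("%s_%03d.txt", classes[ci], j))
      write_bonn_ascii(rec, p)
      paths <- c(paths, p)
    }
  }
  manifest <- list(generator = "rcnneeg::simulate_bonn_dir", seed = seed,
                   classes = classes, n_per_class = n, fs = fs,
                   duration_s = duration_s)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
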