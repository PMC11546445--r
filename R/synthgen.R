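#' Per-class pulse morphology
#'
#' Describes the beat-level shape of a synthetic PPG class: heart-rate range,
#' systolic peak width, dicrotic-notch amplitude (as a fraction of the
#' systolic peak), the delay of the reflected (diastolic) wave, and per-beat
#' amplitude jitter. These defaults are fixtures that give the four
#' blood-pressure stages a learnable, physiologically flavored morphology
#' gradient; they are not calibrated claims about hemodynamics.
#'
#' @param heart_rate_range length-2 numeric, beats/min, within \[40, 180\].
#' @param systolic_width systolic Gaussian width (seconds).
#' @param notch_amplitude dicrotic bump amplitude, fraction of systolic peak in \[0, 1\].
#' @param reflection_delay delay of the dicrotic bump after the systolic peak (seconds).
#' @param amplitude_jitter per-beat multiplicative amplitude jitter fraction in \[0, 1\].
#' @return an object of class `class_morphology`.
#' @export
class_morphology <- function(heart_rate_range = c(60, 70),
                             systolic_width = 0.09,
                             notch_amplitude = 0.5,
                             reflection_delay = 0.28,
                             amplitude_jitter = 0.05) {
  stopifnot(length(heart_rate_range) == 2L, heart_rate_range[1] <= heart_rate_range[2])
  if (heart_rate_range[1] < 40 || heart_rate_range[2] > 180)
    stop("heart_rate_range must lie within [40, 180] bpm", call. = FALSE)
  for (f in c(notch_amplitude, amplitude_jitter))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  stopifnot(systolic_width > 0, reflection_delay > 0)
  structure(list(heart_rate_range = as.numeric(heart_rate_range),
                 systolic_width = systolic_width,
                 notch_amplitude = notch_amplitude,
                 reflection_delay = reflection_delay,
                 amplitude_jitter = amplitude_jitter),
            class = "class_morphology")
}

#' Default morphologies for the four blood-pressure stages
#'
#' A monotone gradient across N, P, S1, S2: decreasing dicrotic-notch
#' amplitude (0.5 / 0.35 / 0.2 / 0.1), rising heart-rate centers
#' (65 / 72 / 80 / 88 bpm, each subject drawn within +/-1.5 bpm of its
#' class center) and narrowing systolic width -- loosely echoing the
#' stiffening-artery phenotype. The ranges are deliberately narrower than
#' the gaps between class centers so that, even after the +/-3% per-beat
#' period jitter, adjacent classes stay separated in effective pulse rate:
#' the cohort's classes are well separated *by design*, which is the
#' premise of the end-to-end learnability checks.
#'
#' @return named list of four `class_morphology` objects (N, P, S1, S2).
#' @export
default_morphologies <- function() {
  list(
    N  = class_morphology(c(63.5, 66.5), systolic_width = 0.095, notch_amplitude = 0.50,
                          reflection_delay = 0.30, amplitude_jitter = 0.05),
    P  = class_morphology(c(70.5, 73.5), systolic_width = 0.085, notch_amplitude = 0.35,
                          reflection_delay = 0.27, amplitude_jitter = 0.05),
    S1 = class_morphology(c(78.5, 81.5), systolic_width = 0.075, notch_amplitude = 0.20,
                          reflection_delay = 0.24, amplitude_jitter = 0.05),
    S2 = class_morphology(c(86.5, 89.5), systolic_width = 0.065, notch_amplitude = 0.10,
                          reflection_delay = 0.21, amplitude_jitter = 0.05)
  )
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the acquisition design the pipeline targets: 1000 Hz
#' sampling, three 2.1-s segments per subject, four stage classes.
#'
#' @param n_subjects number of subjects.
#' @param class_proportions four nonnegative reals summing to 1 (N, P, S1, S2),
#'   or `NULL` with explicit `class_counts`.
#' @param class_counts optional explicit per-class subject counts (overrides
#'   proportions).
#' @param fs sampling rate, Hz.
#' @param segment_seconds segment duration, seconds.
#' @param segments_per_subject segments recorded per subject.
#' @param noise_sd white-noise standard deviation (signal units; systolic peak is ~1).
#' @param baseline_wander_amp amplitude of the sinusoidal baseline wander.
#' @param seed integer RNG seed.
#' @return an object of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_subjects,
                                class_proportions = c(0.365, 0.388, 0.155, 0.092),
                                class_counts = NULL,
                                fs = 1000, segment_seconds = 2.1,
                                segments_per_subject = 3,
                                noise_sd = 0.03, baseline_wander_amp = 0.15,
                                seed = 1L) {
  stopifnot(n_subjects >= 0, fs > 0, segment_seconds > 0, segments_per_subject >= 1,
            noise_sd >= 0, baseline_wander_amp >= 0)
  if (is.null(class_counts)) {
    stopifnot(length(class_proportions) == 4L, all(class_proportions >= 0))
    if (abs(sum(class_proportions) - 1) > 1e-9)
      stop("class_proportions must sum to 1 (within 1e-9)", call. = FALSE)
    # largest-remainder apportionment so counts sum exactly to n_subjects
    raw <- class_proportions * n_subjects
    cnt <- floor(raw)
    rem <- n_subjects - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    class_counts <- as.integer(cnt)
  } else {
    class_counts <- as.integer(class_counts)
    stopifnot(length(class_counts) == 4L, all(class_counts >= 0))
    if (sum(class_counts) != n_subjects)
      stop("class_counts must sum to n_subjects", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), class_counts = class_counts,
                 fs = fs, segment_seconds = segment_seconds,
                 segments_per_subject = as.integer(segments_per_subject),
                 noise_sd = noise_sd, baseline_wander_amp = baseline_wander_amp,
                 seed = as.integer(seed)),
            class = "synth_cohort_config")
}

#' Generate one quasi-periodic PPG pulse train
#'
#' Each beat is a two-Gaussian waveform: a systolic peak of unit nominal
#' amplitude plus a delayed, scaled dicrotic bump, laid down at a per-beat
#' period drawn from the morphology's heart-rate range with +/-3% beat-to-beat
#' jitter. Sinusoidal baseline wander and white Gaussian noise are added on
#' top. Deterministic given the RNG state.
#'
#' @param morph a [class_morphology()].
#' @param duration signal duration, seconds.
#' @param fs sampling rate, Hz.
#' @param noise_sd white-noise sd.
#' @param baseline_wander_amp baseline wander amplitude.
#' @param phase_offset beat-phase offset in seconds (shifts the beat grid;
#'   used by the SQI-gated cohort generator to resample rejected segments).
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
generate_pulse_train <- function(morph, duration, fs,
                                 noise_sd = 0, baseline_wander_amp = 0,
                                 phase_offset = 0) {
  stopifnot(inherits(morph, "class_morphology"), duration > 0, fs > 0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  hr <- runif(1, morph$heart_rate_range[1], morph$heart_rate_range[2])
  period <- 60 / hr
  x <- numeric(n)
  # lay beats from before the window start so edge beats are complete
  beat_t <- -period + phase_offset
  while (beat_t < duration + period) {
    amp <- 1 + runif(1, -morph$amplitude_jitter, morph$amplitude_jitter)
    x <- x + amp * exp(-(t - beat_t)^2 / (2 * morph$systolic_width^2))
    if (morph$notch_amplitude > 0) {
      x <- x + amp * morph$notch_amplitude *
        exp(-(t - beat_t - morph$reflection_delay)^2 /
              (2 * (1.6 * morph$systolic_width)^2))
    }
    beat_t <- beat_t + period * (1 + runif(1, -0.03, 0.03))
  }
  if (baseline_wander_amp > 0) {
    f_w <- runif(1, 0.15, 0.35)  # respiratory-band drift
    x <- x + baseline_wander_amp * sin(2 * pi * f_w * t + runif(1, 0, 2 * pi))
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  x
}

#' Generate a seeded synthetic PPG cohort
#'
#' Emulates the target acquisition design: `n_subjects` subjects, each
#' assigned one of the four stage classes, each contributing
#' `segments_per_subject` consecutive segments of `segment_seconds` at `fs`.
#' Every emitted segment is gated on the skewness signal-quality index
#' (kept only if sample skewness > 0, mirroring the saving rule of the
#' acquisition protocol); rejected segments are regenerated with a fresh
#' beat-phase offset, up to `max_retries` attempts.
#'
#' @param config a [synth_cohort_config()].
#' @param morphologies named list of four `class_morphology` objects
#'   (N, P, S1, S2); defaults to [default_morphologies()].
#' @param dir output directory for signal files; `NULL` keeps signals in
#'   memory only.
#' @param max_retries bound on SQI-gate resampling attempts per segment.
#' @return list with elements `manifest` (a `ppg_manifest` data.frame) and
#'   `records` (list of [ppg_record()]s).
#' @export
generate_cohort <- function(config, morphologies = default_morphologies(),
                            dir = NULL, max_retries = 100L) {
  stopifnot(inherits(config, "synth_cohort_config"))
  stopifnot(all(PPG_LABELS %in% names(morphologies)))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  withr::with_seed(config$seed, {
    labels <- rep(PPG_LABELS, times = config$class_counts)
    records <- vector("list", config$n_subjects * config$segments_per_subject)
    rows <- vector("list", length(records))
    k <- 0L
    for (s in seq_len(config$n_subjects)) {
      sid <- sprintf("subj%04d", s)
      lab <- labels[s]
      morph <- morphologies[[lab]]
      for (seg in seq_len(config$segments_per_subject)) {
        x <- NULL
        for (attempt in seq_len(max_retries)) {
          cand <- generate_pulse_train(
            morph, config$segment_seconds, config$fs,
            noise_sd = config$noise_sd,
            baseline_wander_amp = config$baseline_wander_amp,
            phase_offset = runif(1, 0, 60 / morph$heart_rate_range[1]))
          if (skewness_sqi(cand) > 0) { x <- cand; break }
        }
        if (is.null(x))
          stop("SQI gate not passed after ", max_retries,
               " attempts for class ", lab, call. = FALSE)
        k <- k + 1L
        path <- if (is.null(dir)) "" else file.path(dir, sprintf("%s_seg%d.txt", sid, seg - 1L))
        if (!is.null(dir)) write_signal(x, path)
        records[[k]] <- ppg_record(sid, lab, seg - 1L, x, config$fs)
        rows[[k]] <- data.frame(path = path, subject_id = sid, label = lab,
                                segment_index = seg - 1L, synthetic = FALSE,
                                source_subject_id = sid, stringsAsFactors = FALSE)
      }
    }
    manifest <- if (k == 0L) {
      data.frame(path = character(), subject_id = character(), label = character(),
                 segment_index = integer(), synthetic = logical(),
                 source_subject_id = character(), stringsAsFactors = FALSE)
    } else do.call(rbind, rows[seq_len(k)])
    list(manifest = validate_manifest(manifest), records = records[seq_len(k)])
  })
}
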