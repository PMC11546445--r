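#' Wavelet denoising specification
#'
#' Adaptive multilevel wavelet denoising: the signal is decomposed with the
#' sym8 wavelet, every detail band is soft-thresholded at the universal
#' threshold `lambda = sigma * sqrt(2 ln n)` with the robust noise estimate
#' `sigma = median(|d1|) / 0.6745` taken from the finest detail band, and
#' the approximation band is left untouched.
#'
#' @param wavelet_name wavelet family (only `"sym8"` is built in).
#' @param levels decomposition depth; `NULL` picks
#'   `min(5, floor(log2(n)) - 2)` at call time.
#' @param threshold_rule thresholding rule (universal, per level).
#' @param threshold_mode `"soft"` shrinkage.
#' @return an object of class `denoise_spec`.
#' @export
denoise_spec <- function(wavelet_name = "sym8", levels = NULL,
                         threshold_rule = "universal-per-level",
                         threshold_mode = "soft") {
  wavelet_name <- match.arg(wavelet_name, "sym8")
  threshold_rule <- match.arg(threshold_rule, "universal-per-level")
  threshold_mode <- match.arg(threshold_mode, "soft")
  if (!is.null(levels) && levels < 1) stop("levels must be >= 1", call. = FALSE)
  structure(list(wavelet_name = wavelet_name, levels = levels,
                 threshold_rule = threshold_rule, threshold_mode = threshold_mode),
            class = "denoise_spec")
}

soft_threshold <- function(d, lambda) sign(d) * pmax(abs(d) - lambda, 0)

#' Adaptive wavelet denoising
#'
#' @param x numeric signal, length >= `2^levels`.
#' @param spec a [denoise_spec()].
#' @return denoised signal, same length as `x`.
#' @export
denoise_wavelet <- function(x, spec = denoise_spec()) {
  stopifnot(inherits(spec, "denoise_spec"))
  n <- length(x)
  if (n < 4L) stop("signal too short to denoise", call. = FALSE)
  max_lev <- floor(log2(n))
  levels <- if (is.null(spec$levels)) min(5L, max_lev - 2L) else spec$levels
  if (n < 2^levels)
    stop("signal of length ", n, " supports at most ", max_lev,
         " decomposition levels, got ", levels, call. = FALSE)
  dec <- dwt_multilevel(x, levels)
  # noise scale from the finest detail band only: coarse bands carry genuine
  # signal, whose median would inflate sigma and shrink real content away
  sigma <- median(abs(dec$details[[1L]])) / 0.6745
  lambda <- sigma * sqrt(2 * log(n))
  for (lev in seq_along(dec$details))
    dec$details[[lev]] <- soft_threshold(dec$details[[lev]], lambda)
  idwt_multilevel(dec)
}

#' Apply an FIR filter with zero net phase
#'
#' The filter is linear-phase (symmetric), so a single convolution followed
#' by compensation of the constant group delay `(numtaps - 1) / 2` yields a
#' zero-phase result with no waveform distortion of pulse landmarks. Edges
#' are zero-padded; the output has the length of the input.
#'
#' @param x numeric signal, longer than the filter.
#' @param coefficients FIR coefficients (odd length, symmetric).
#' @return filtered signal, same length as `x`.
#' @export
apply_filter <- function(x, coefficients) {
  h <- as.numeric(coefficients)
  n <- length(x); L <- length(h)
  if (n <= L) stop("signal (", n, ") must be longer than the filter (", L, ")",
                   call. = FALSE)
  full <- convolve(x, rev(h), type = "open")   # x * h, length n + L - 1
  gd <- (L - 1L) / 2L
  full[gd + seq_len(n)]
}

#' 0--1 min-max normalization
#'
#' @param x numeric signal, length >= 2.
#' @return `(x - min x) / (max x - min x)`; range exactly \[0, 1\].
#' @export
normalize_minmax <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate segment: constant signal cannot be min-max normalized",
         call. = FALSE)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Skewness signal-quality index
#'
#' Sample skewness `m3 / m2^(3/2)` with biased central moments. A segment
#' passes the quality gate iff its skewness exceeds zero (PPG pulses are
#' right-skewed; flat or inverted segments fail).
#'
#' @param x numeric signal, length >= 3, nonconstant.
#' @return the sample skewness.
#' @export
skewness_sqi <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (max(x) == min(x)) stop("constant input has undefined skewness", call. = FALSE)
  e1071::skewness(x, type = 1)
}

#' Cut a recording into fixed-length consecutive segments
#'
#' @param x numeric recording.
#' @param fs sampling rate, Hz.
#' @param segment_seconds segment duration (default 2.1 s).
#' @param n_segments number of segments to cut.
#' @return list of `n_segments` numeric vectors of exactly
#'   `round(segment_seconds * fs)` samples; any trailing remainder is
#'   discarded.
#' @export
segment_recording <- function(x, fs, segment_seconds = 2.1, n_segments) {
  len <- round(segment_seconds * fs)
  need <- n_segments * len
  if (length(x) < need)
    stop("recording of ", length(x), " samples is too short: ",
         n_segments, " segments of ", len, " samples require ", need,
         call. = FALSE)
  lapply(seq_len(n_segments), function(i) x[((i - 1L) * len + 1L):(i * len)])
}

#' Full preprocessing of one PPG segment
#'
#' Denoise (adaptive wavelet), bandpass (equiripple FIR, zero net phase),
#' then 0--1 min-max normalize -- in that order, so the output always lies
#' in \[0, 1\].
#'
#' @param x numeric segment.
#' @param coefficients FIR coefficients from [design_remez_bandpass()];
#'   pass `NULL` to skip filtering (e.g. for very short inputs).
#' @param dn_spec a [denoise_spec()].
#' @return preprocessed segment, same length as `x`, in \[0, 1\].
#' @export
preprocess_segment <- function(x, coefficients, dn_spec = denoise_spec()) {
  y <- denoise_wavelet(x, dn_spec)
  if (!is.null(coefficients)) y <- apply_filter(y, coefficients)
  normalize_minmax(y)
}
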