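#' Continuous wavelet transform configuration
#'
#' Analysis frequencies are laid on a logarithmic grid with
#' `voices_per_octave` frequencies per octave between `freq_min` and
#' `freq_max`. Each frequency `f` maps to the Morlet scale
#' `a = omega0 / (2 pi f)`.
#'
#' @param omega0 dimensionless Morlet center frequency (default 6, the
#'   standard admissibility choice).
#' @param voices_per_octave frequencies per octave (>= 1).
#' @param freq_min,freq_max analysis band, Hz; must satisfy
#'   `0 < freq_min < freq_max <= fs/2`.
#' @param fs sampling rate, Hz.
#' @return an object of class `cwt_config`.
#' @export
cwt_config <- function(omega0 = 6, voices_per_octave = 12,
                       freq_min = 0.1, freq_max = 50, fs = 1000) {
  stopifnot(omega0 > 0, voices_per_octave >= 1, fs > 0)
  if (!(0 < freq_min && freq_min < freq_max && freq_max <= fs / 2))
    stop("need 0 < freq_min < freq_max <= fs/2", call. = FALSE)
  structure(list(omega0 = omega0, voices_per_octave = as.integer(voices_per_octave),
                 freq_min = freq_min, freq_max = freq_max, fs = fs),
            class = "cwt_config")
}

cwt_freq_grid <- function(cfg) {
  n_oct <- log2(cfg$freq_max / cfg$freq_min)
  k <- 0:floor(n_oct * cfg$voices_per_octave + 1e-9)
  f <- cfg$freq_min * 2^(k / cfg$voices_per_octave)
  if (length(f) == 0L) stop("empty frequency grid", call. = FALSE)
  rev(f)                                 # descending, matching the image axis
}

#' Analytic Morlet continuous wavelet transform
#'
#' For each analysis frequency the signal is convolved (via FFT) with the
#' conjugated, time-reversed, scaled analytic Morlet wavelet
#' `psi(t) = pi^(-1/4) exp(i omega0 t) exp(-t^2 / 2)`, L2-normalized per
#' scale (`a^(-1/2) psi(t/a)`), with zero-padded edges. The magnitude of the
#' coefficients forms the scalogram.
#'
#' @param x numeric signal, length >= 16.
#' @param cfg a [cwt_config()].
#' @return an object of class `scalogram`: list with `magnitude`
#'   (n_freq x n_time, nonnegative), `freqs_hz` (descending) and `times_s`.
#' @export
cwt_morlet <- function(x, cfg = cwt_config()) {
  stopifnot(inherits(cfg, "cwt_config"))
  n <- length(x)
  if (n < 16L) stop("signal too short for CWT (need >= 16 samples)", call. = FALSE)
  freqs <- cwt_freq_grid(cfg)
  dt <- 1 / cfg$fs
  # zero-pad to cover the widest wavelet support and avoid circular wrap
  a_max <- cfg$omega0 / (2 * pi * min(freqs))          # seconds
  half_max <- min(ceiling(4 * a_max / dt), 4L * n)
  nfft <- nextn(n + 2L * half_max, 2)
  X <- fft(c(x, numeric(nfft - n)))
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    a <- cfg$omega0 / (2 * pi * freqs[i])              # scale, seconds
    half <- min(ceiling(4 * a / dt), half_max)
    tt <- (-half:half) * dt
    psi <- pi^(-0.25) * exp(1i * cfg$omega0 * tt / a) * exp(-(tt / a)^2 / 2)
    psi <- psi / a^0.5 * dt                            # L2 scale norm, Riemann dt
    # correlation of x with psi centered at each b: conv with conj reversed psi
    kern <- Conj(rev(psi))
    K <- fft(c(kern, numeric(nfft - length(kern))))
    w <- fft(X * K, inverse = TRUE) / nfft
    # full convolution index of center: shift by half (kernel center offset)
    mag[i, ] <- Mod(w[(half + 1L):(half + n)])
  }
  structure(list(magnitude = mag, freqs_hz = freqs,
                 times_s = (seq_len(n) - 1) * dt),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d freqs (%.3g-%.3g Hz) x %d times (%.3g s)\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s), max(x$times_s)))
  invisible(x)
}

# block-average one axis down to <= target bins (antialiasing prefilter for
# large downscales); a no-op when the axis is already within 2x of target
shrink_axis <- function(m, target, rows) {
  n <- if (rows) nrow(m) else ncol(m)
  if (n <= target) return(m)
  grp <- ceiling(seq_len(n) / (n / target))
  if (rows) {
    rowsum(m, grp) / as.vector(table(grp))
  } else {
    t(rowsum(t(m), grp) / as.vector(table(grp)))
  }
}

scalogram_palette <- function(n = 256L) {
  t(grDevices::col2rgb(grDevices::hcl.colors(n, "viridis")))
}

#' Render a scalogram to a fixed-size RGB image
#'
#' The magnitude matrix is min-max scaled per image to \[0, 1\], mapped
#' through a fixed perceptually-ordered colormap (viridis) and bilinearly
#' resized to `out_size`. Axes that shrink by more than a factor of two
#' are first block-averaged to about twice the target resolution: without
#' that antialiasing step, interpolating a 2100-column magnitude matrix
#' down to 64 columns subsamples the beat-synchronous texture and aliases
#' it into noise. A constant magnitude matrix renders as a uniform image
#' of the colormap floor. Deterministic: the same scalogram always yields
#' identical bytes.
#'
#' @param s a [cwt_morlet()] scalogram.
#' @param out_size integer `(H, W)` output size (default 224 x 224).
#' @return H x W x 3 integer array with values in 0..255.
#' @export
render_scalogram <- function(s, out_size = c(224L, 224L)) {
  stopifnot(inherits(s, "scalogram"), length(out_size) == 2L, all(out_size >= 1L))
  m <- s$magnitude
  m <- shrink_axis(m, 2L * out_size[1L], rows = TRUE)
  m <- shrink_axis(m, 2L * out_size[2L], rows = FALSE)
  rng <- range(m)
  m01 <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  pal <- scalogram_palette(256L)
  idx <- pmin(255L, as.integer(floor(m01 * 256))) + 1L
  rgb <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[idx, ch], nrow(m), ncol(m)) / 255
  img <- EBImage::resize(EBImage::Image(aperm(rgb, c(2, 1, 3)), colormode = "Color"),
                         w = out_size[2L], h = out_size[1L], filter = "bilinear")
  out <- aperm(EBImage::imageData(img), c(2, 1, 3))
  array(as.integer(round(pmin(pmax(out, 0), 1) * 255)), dim(out))
}

#' Time-averaged CWT spectrum and its peak frequency
#'
#' Convenience used by tests and class-prototype diagnostics: averages the
#' scalogram magnitude over time and reports the frequency of its maximum.
#'
#' @param s a scalogram.
#' @return list with `spectrum` (named by frequency) and `peak_hz`.
#' @export
scalogram_peak <- function(s) {
  avg <- rowMeans(s$magnitude)
  list(spectrum = setNames(avg, signif(s$freqs_hz, 6)),
       peak_hz = s$freqs_hz[which.max(avg)])
}
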