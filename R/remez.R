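# Parks-McClellan (Remez exchange) equiripple FIR design, type-I linear phase.
# Authored here because the design must stay numerically stable for long
# (~1000-tap) filters with narrow normalized bands; validated in the test
# suite against a direct Fourier-sum evaluation of the frequency response.

#' FIR bandpass filter specification
#'
#' Passband defaults follow the physiologic PPG band (0.05--16 Hz). With a
#' 1000 Hz sampling rate and a filter of ~1 s duration, no FIR can realize a
#' stopband between DC and 0.05 Hz (the two are inside one resolution cell),
#' so by default the region below `pass_lo` is left as a don't-care region
#' and the filter is equiripple over the passband and the upper stopband.
#' A genuine lower stopband can be requested via `stop_lo` when the tap
#' budget supports it (e.g. at lower sampling rates).
#'
#' @param fs sampling rate, Hz.
#' @param pass_lo,pass_hi passband edges, Hz.
#' @param transition width of the upper transition band, Hz.
#' @param numtaps odd number of taps (type-I linear phase).
#' @param weights length-2 (or 3 with `stop_lo`) band error weights
#'   (pass, upper stop) -- relative emphasis in the minimax error.
#' @param stop_lo upper edge of an optional DC stopband, Hz; 0 disables it.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(fs = 1000, pass_lo = 0.05, pass_hi = 16,
                        transition = 2, numtaps = 1001,
                        weights = NULL, stop_lo = 0) {
  stopifnot(fs > 0, numtaps >= 7)
  if (numtaps %% 2 == 0) stop("numtaps must be odd (type-I linear phase)", call. = FALSE)
  if (!(0 < pass_lo && pass_lo < pass_hi && pass_hi < fs / 2))
    stop("band edges must satisfy 0 < pass_lo < pass_hi < fs/2", call. = FALSE)
  if (pass_hi + transition >= fs / 2)
    stop("infeasible band edges: upper transition crosses Nyquist", call. = FALSE)
  if (stop_lo < 0 || (stop_lo > 0 && stop_lo >= pass_lo))
    stop("infeasible band edges: stop_lo must lie in [0, pass_lo)", call. = FALSE)
  nb <- if (stop_lo > 0) 3L else 2L
  if (is.null(weights)) weights <- rep(1, nb)
  stopifnot(length(weights) == nb, all(weights > 0))
  structure(list(fs = fs, pass_lo = pass_lo, pass_hi = pass_hi,
                 transition = transition, numtaps = as.integer(numtaps),
                 weights = as.numeric(weights), stop_lo = stop_lo),
            class = "filter_spec")
}

# Barycentric weights over nodes x (log-scaled to avoid overflow at high order).
bary_weights <- function(x) {
  r <- length(x)
  lw <- numeric(r); sg <- numeric(r)
  for (k in seq_len(r)) {
    d <- x[k] - x[-k]
    lw[k] <- -sum(log(abs(d)))
    sg[k] <- prod(sign(d))
  }
  sg * exp(lw - max(lw))
}

# Evaluate barycentric interpolant with nodes x, weights w, values v at points xq.
bary_eval <- function(xq, x, w, v) {
  out <- numeric(length(xq))
  hit <- match(xq, x)
  exact <- !is.na(hit)
  out[exact] <- v[hit[exact]]
  if (any(!exact)) {
    dq <- outer(xq[!exact], x, "-")
    C <- w / t(dq)                      # r x nq
    out[!exact] <- colSums(C * v) / colSums(C)
  }
  out
}

#' Design an equiripple linear-phase FIR bandpass filter
#'
#' Implements the Parks-McClellan exchange: minimax approximation of the
#' desired response by a cosine polynomial on a dense frequency grid,
#' exchanging extremal frequencies until the equiripple condition holds.
#' The returned impulse response is exactly symmetric
#' (`h[k] == h[numtaps-1-k]`).
#'
#' @param spec a [filter_spec()].
#' @param density grid points per extremal (grid resolution multiplier).
#' @param maxiter exchange iteration bound.
#' @return numeric vector of `spec$numtaps` coefficients, with attributes
#'   `ripple` (converged weighted ripple) and `spec`.
#' @export
design_remez_bandpass <- function(spec, density = 16, maxiter = 60) {
  stopifnot(inherits(spec, "filter_spec"))
  N <- spec$numtaps
  M <- (N - 1L) / 2L
  r <- M + 1L                           # cosine coefficients; r+1 extremals
  nyq <- spec$fs / 2
  bands <- list()
  if (spec$stop_lo > 0)
    bands[[length(bands) + 1L]] <- list(lo = 0, hi = spec$stop_lo, d = 0)
  bands[[length(bands) + 1L]] <- list(lo = spec$pass_lo, hi = spec$pass_hi, d = 1)
  bands[[length(bands) + 1L]] <- list(lo = spec$pass_hi + spec$transition, hi = nyq, d = 0)
  wts <- spec$weights

  # dense grid: allocate ~density*(r+1) points across bands by width
  widths <- vapply(bands, function(b) b$hi - b$lo, 0)
  total <- sum(widths)
  gf <- list(); gd <- list(); gw <- list()
  for (i in seq_along(bands)) {
    npt <- max(8L, round(density * (r + 1L) * widths[i] / total))
    f <- seq(bands[[i]]$lo, bands[[i]]$hi, length.out = npt)
    gf[[i]] <- f
    gd[[i]] <- rep(bands[[i]]$d, npt)
    gw[[i]] <- rep(wts[i], npt)
  }
  f <- unlist(gf); D <- unlist(gd); W <- unlist(gw)
  om <- pi * f / nyq
  xg <- cos(om)
  ng <- length(f)
  if (ng < r + 1L)
    stop("frequency grid too sparse for ", N, " taps; increase density", call. = FALSE)

  ext <- round(seq(1, ng, length.out = r + 1L))   # initial extremal guess
  delta <- 0
  for (iter in seq_len(maxiter)) {
    xe <- xg[ext]
    gam <- bary_weights(xe)
    signs <- (-1)^(seq_len(r + 1L) - 1L)
    delta <- sum(gam * D[ext]) / sum(gam * signs / W[ext])
    ce <- D[ext] - signs * delta / W[ext]
    H <- bary_eval(xg, xe, gam, ce)
    E <- W * (D - H)

    # candidate extremals: local maxima of |E| plus band edges
    aE <- abs(E)
    loc <- which(diff(sign(diff(aE))) < 0) + 1L
    edges <- cumsum(vapply(gf, length, 0L))
    cand <- sort(unique(c(1L, loc, edges, head(edges, -1L) + 1L)))
    # enforce sign alternation: among same-sign runs keep the largest |E|
    keep <- integer(0)
    for (i in cand) {
      if (length(keep) == 0L || sign(E[i]) != sign(E[tail(keep, 1L)])) {
        keep <- c(keep, i)
      } else if (aE[i] > aE[tail(keep, 1L)]) {
        keep[length(keep)] <- i
      }
    }
    # trim to exactly r+1, dropping the weaker end point each time
    while (length(keep) > r + 1L) {
      if (aE[keep[1L]] <= aE[keep[length(keep)]]) keep <- keep[-1L]
      else keep <- keep[-length(keep)]
    }
    if (length(keep) < r + 1L) break    # converged (no richer extremal set)
    conv <- max(aE[keep]) - abs(delta)
    ext_new <- keep
    if (all(ext_new == ext) || conv <= 1e-6 * max(abs(delta), 1e-12)) {
      ext <- ext_new
      break
    }
    ext <- ext_new
  }

  # final cosine polynomial -> impulse response by inverse DFT of A(omega)
  xe <- xg[ext[seq_len(min(length(ext), r + 1L))]]
  gam <- bary_weights(xe)
  signs <- (-1)^(seq_along(xe) - 1L)
  ce <- D[ext[seq_along(xe)]] - signs * delta / W[ext[seq_along(xe)]]
  omj <- 2 * pi * (0:M) / N
  Aj <- bary_eval(cos(omj), xe, gam, ce)
  m <- 0:(N - 1L)
  h <- vapply(m, function(mm) {
    (Aj[1L] + 2 * sum(Aj[-1L] * cos(2 * pi * (1:M) * (mm - M) / N))) / N
  }, 0)
  h <- (h + rev(h)) / 2                 # enforce exact symmetry
  structure(h, ripple = abs(delta), spec = spec)
}

#' Evaluate an FIR filter's frequency response by direct Fourier sum
#'
#' `|H(f)| = |sum_k h[k] exp(-i 2 pi f k / fs)|`, evaluated directly.
#'
#' @param h FIR coefficients.
#' @param freqs_hz frequencies at which to evaluate, Hz.
#' @param fs sampling rate, Hz.
#' @return numeric vector of response magnitudes.
#' @export
fir_response <- function(h, freqs_hz, fs) {
  k <- seq_along(h) - 1
  vapply(freqs_hz, function(f) Mod(sum(h * exp(-2i * pi * f * k / fs))), 0)
}
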