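# Multilevel orthogonal DWT with circular (periodized) boundary handling.
# Written here because the R stack carries no discrete-wavelet package; the
# filters below are the published sym8 (Daubechies least-asymmetric, 8
# vanishing moments) decomposition coefficients. Perfect reconstruction is
# asserted in the test suite.

SYM8_LO <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
   0.007607487324917605,  -0.1432942383508097,   -0.061273359067658524,
   0.4813596512583722,     0.7771857517005235,    0.3644418948353314,
  -0.05194583810770904,   -0.027219029917056003,  0.049137179673607506,
   0.003808752013890615,  -0.01495225833704823,  -0.0003029205147213668,
   0.0018899503327594609)

# alternating flip: g[m] = (-1)^m h[L-1-m]
qmf_highpass <- function(lo) {
  L <- length(lo)
  rev(lo) * (-1)^(seq_len(L) - 1L)
}

# one periodized analysis step; x must have even length
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  n2 <- n %/% 2L
  L <- length(lo)
  a <- numeric(n2); d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L) + 1L          # 2k+1, k = 0..n2-1 (0-based)
  for (m in seq_len(L)) {
    idx <- ((base - (m - 1L)) %% n) + 1L
    a <- a + lo[m] * x[idx]
    d <- d + hi[m] * x[idx]
  }
  list(a = a, d = d)
}

# adjoint (synthesis) of dwt_step
idwt_step <- function(a, d, lo, hi) {
  n2 <- length(a)
  n <- 2L * n2
  L <- length(lo)
  y <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L) + 1L
  for (m in seq_len(L)) {
    idx <- ((base - (m - 1L)) %% n) + 1L
    y[idx] <- y[idx] + lo[m] * a + hi[m] * d
  }
  y
}

#' Multilevel periodized DWT (sym8)
#'
#' Decomposes `x` into `levels` detail bands plus a final approximation,
#' using circular boundary extension; odd-length intermediates are padded by
#' repeating their last sample (the pad is removed on reconstruction).
#'
#' @param x numeric vector.
#' @param levels decomposition depth (>= 1).
#' @return list with `approx`, `details` (list, level 1 = finest) and
#'   book-keeping lengths.
#' @keywords internal
dwt_multilevel <- function(x, levels) {
  lo <- SYM8_LO; hi <- qmf_highpass(lo)
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- x
  for (lev in seq_len(levels)) {
    lens[lev] <- length(cur)
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    s <- dwt_step(cur, lo, hi)
    details[[lev]] <- s$d
    cur <- s$a
  }
  list(approx = cur, details = details, lens = lens)
}

#' @rdname dwt_multilevel
#' @param dec result of [dwt_multilevel()].
#' @keywords internal
idwt_multilevel <- function(dec) {
  lo <- SYM8_LO; hi <- qmf_highpass(lo)
  cur <- dec$approx
  for (lev in rev(seq_along(dec$details))) {
    cur <- idwt_step(cur, dec$details[[lev]], lo, hi)
    cur <- cur[seq_len(dec$lens[lev])]   # drop odd-length pad
  }
  cur
}
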