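test_that("the periodized DWT reconstructs exactly", {
  set.seed(1)
  for (n in c(64, 1024, 2100)) {
    x <- rnorm(n)
    dec <- ppgnet:::dwt_multilevel(x, 5)
    expect_equal(ppgnet:::idwt_multilevel(dec), x, tolerance = 1e-9)
  }
})

test_that("denoising reduces MSE on a noisy sinusoid and spares a clean one", {
  t <- (0:1023) / 100
  clean <- sin(2 * pi * 1.2 * t)
  noisy <- clean + withr::with_seed(2, rnorm(1024, sd = 0.3))
  den <- denoise_wavelet(noisy)
  expect_identical(length(den), length(noisy))
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))

  # high-SNR limit: soft-thresholding bias stays below 5% of the amplitude
  pure <- denoise_wavelet(clean)
  expect_lt(max(abs(pure - clean)), 0.05 * max(abs(clean)))

  expect_equal(denoise_wavelet(numeric(1024)), numeric(1024))
  expect_error(denoise_wavelet(rnorm(16), denoise_spec(levels = 10)), "levels")
})

test_that("equiripple bandpass meets its response bounds (direct Fourier sum)", {
  h <- design_remez_bandpass(filter_spec())
  # independent response oracle, written out in full
  resp <- function(f) {
    k <- seq_along(h) - 1
    Mod(sum(unclass(h) * exp(-2i * pi * f * k / 1000)))
  }
  expect_gte(resp(8), 0.9)
  expect_lte(resp(100), 0.05)
  # equiripple deviations stay within the converged ripple (small headroom
  # because the response is evaluated off the design grid)
  rip <- attr(h, "ripple")
  for (f in c(1, 4, 12, 15)) expect_lt(abs(resp(f) - 1), rip * 1.05)
  for (f in c(30, 60, 250, 480)) expect_lt(resp(f), rip * 1.05)
})

test_that("FIR coefficients are exactly symmetric (linear phase)", {
  h <- as.numeric(design_remez_bandpass(filter_spec(numtaps = 201, transition = 8)))
  expect_identical(h, rev(h))
})

test_that("infeasible band edges are rejected", {
  expect_error(filter_spec(pass_hi = 499, transition = 2), "Nyquist")
  expect_error(filter_spec(pass_lo = 20, pass_hi = 16), "band edges")
  expect_error(filter_spec(numtaps = 100), "odd")
})

test_that("zero-phase filtering preserves passband and kills stopband tones", {
  h <- design_remez_bandpass(filter_spec())
  t <- (0:2099) / 1000
  ctr <- 600:1500   # central window clear of edge transients
  x8 <- sin(2 * pi * 8 * t)
  y8 <- apply_filter(x8, h)
  expect_identical(length(y8), length(x8))
  expect_lt(abs(sqrt(mean(y8[ctr]^2)) / sqrt(mean(x8[ctr]^2)) - 1), 0.1)

  x100 <- sin(2 * pi * 100 * t)
  y100 <- apply_filter(x100, h)
  expect_lt(sqrt(mean(y100[ctr]^2)), 0.1 * sqrt(mean(x100[ctr]^2)))

  expect_equal(apply_filter(numeric(2100), h), numeric(2100))
  expect_error(apply_filter(numeric(100), h), "longer than the filter")
})

test_that("min-max normalization maps to [0,1], is idempotent, rejects constants", {
  expect_equal(normalize_minmax(c(1, 2, 3)), c(0, 0.5, 1))
  set.seed(3)
  x <- rnorm(100)
  y <- normalize_minmax(x)
  expect_identical(range(y), c(0, 1))
  expect_equal(normalize_minmax(y), y)
  expect_error(normalize_minmax(c(5, 5, 5)), "degenerate")
})

test_that("skewness SQI matches the moment definition and its symmetries", {
  expect_equal(skewness_sqi(c(-1, 0, 1)), 0)
  # direct moment computation for the derived case
  x <- c(0, 0, 0, 10)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  expect_equal(skewness_sqi(x), m3 / m2^1.5)
  expect_gt(skewness_sqi(x), 0)
  set.seed(4)
  r <- rexp(50)                      # right-skewed
  expect_equal(skewness_sqi(-r), -skewness_sqi(r))
  expect_error(skewness_sqi(c(2, 2, 2)), "constant")
})

test_that("segmentation cuts exact non-overlapping windows and drops remainders", {
  x <- seq_len(6300)
  segs <- segment_recording(x, fs = 1000, n_segments = 3)
  expect_identical(lengths(segs), rep(2100L, 3L))
  expect_identical(segs[[2]][1], 2101L)
  expect_identical(segment_recording(seq_len(2100), 1000, n_segments = 1)[[1]],
                   seq_len(2100))
  expect_error(segment_recording(seq_len(2099), 1000, n_segments = 1), "too short")
})

test_that("the full preprocessing chain preserves length and lands in [0,1]", {
  h <- design_remez_bandpass(filter_spec())
  coh <- tiny_cohort()
  for (r in coh$records[1:3]) {
    y <- preprocess_segment(r$samples, h)
    expect_identical(length(y), length(r$samples))
    expect_gte(min(y), 0)
    expect_lte(max(y), 1)
  }
})
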