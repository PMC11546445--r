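# Direct numerical integration of the CWT definition on a coarse grid:
# CWT(a, b) = a^(-1/2) * integral x(t) conj(psi((t - b)/a)) dt,
# psi(t) = pi^(-1/4) exp(i w0 t) exp(-t^2/2). Used as the independent oracle.
oracle_cwt_peak <- function(x, fs, freqs, omega0 = 6) {
  t <- (seq_along(x) - 1) / fs
  b_grid <- t[seq(100, length(x) - 100, by = 100)]
  avg <- vapply(freqs, function(f) {
    a <- omega0 / (2 * pi * f)
    mean(vapply(b_grid, function(b) {
      arg <- (t - b) / a
      psi <- pi^(-0.25) * exp(1i * omega0 * arg) * exp(-arg^2 / 2)
      Mod(sum(x * Conj(psi)) / fs / sqrt(a))
    }, 0))
  }, 0)
  freqs[which.max(avg)]
}

test_that("the CWT localizes random in-band sinusoids, agreeing with direct integration", {
  cfg <- cwt_config(freq_min = 0.5, freq_max = 20, voices_per_octave = 8, fs = 250)
  grid <- ppgnet:::cwt_freq_grid(cfg)
  t <- (0:1049) / 250
  withr::with_seed(31, {
    for (i in 1:10) {
      f_true <- runif(1, 0.8, 15)
      x <- sin(2 * pi * f_true * t)
      peak <- scalogram_peak(cwt_morlet(x, cfg))$peak_hz
      # the direct-integration oracle must give the same argmax frequency
      expect_equal(oracle_cwt_peak(x, 250, grid), peak)
      # and the peak sits within one voice of the true frequency
      expect_lte(abs(log2(peak / f_true)) * cfg$voices_per_octave, 1)
    }
  })
})

test_that("a grid-aligned tone localizes to exactly the nearest grid frequency", {
  # 1.2 Hz falls within 0.05 voices of a default-grid frequency, so the
  # small low-frequency bias of the energy-normalized transform cannot
  # move the argmax off the nearest grid point
  cfg <- cwt_config()
  grid <- ppgnet:::cwt_freq_grid(cfg)
  x <- sin(2 * pi * 1.2 * (0:2099) / 1000)
  nearest <- grid[which.min(abs(log(grid) - log(1.2)))]
  expect_equal(scalogram_peak(cwt_morlet(x, cfg))$peak_hz, nearest)
})

test_that("CWT magnitude is linear in amplitude and invariant to sign", {
  t <- (0:2099) / 1000
  x <- sin(2 * pi * 3 * t) + 0.3 * sin(2 * pi * 7 * t)
  cfg <- cwt_config()
  s1 <- cwt_morlet(x, cfg)
  expect_equal(cwt_morlet(2 * x, cfg)$magnitude, 2 * s1$magnitude, tolerance = 1e-12)
  expect_equal(cwt_morlet(-x, cfg)$magnitude, s1$magnitude, tolerance = 1e-12)
  expect_true(all(cwt_morlet(numeric(2100), cfg)$magnitude == 0))
  expect_true(all(is.finite(s1$magnitude)) && all(s1$magnitude >= 0))
  expect_identical(dim(s1$magnitude),
                   c(length(s1$freqs_hz), length(s1$times_s)))
})

test_that("scalogram axes are a descending log-frequency grid", {
  cfg <- cwt_config(freq_min = 1, freq_max = 16, voices_per_octave = 2, fs = 100)
  g <- ppgnet:::cwt_freq_grid(cfg)
  expect_true(all(diff(g) < 0))
  expect_equal(min(g), 1)
  expect_equal(max(g), 16)
  expect_equal(length(g), 9L)   # 4 octaves x 2 voices + endpoint
})

test_that("class prototypes with higher heart rates peak at higher frequencies", {
  m <- default_morphologies()
  cfg <- cwt_config(freq_min = 0.5, freq_max = 30, fs = 1000)
  pk <- vapply(c("N", "S2"), function(cl) {
    mm <- m[[cl]]
    mm$heart_rate_range <- rep(mean(mm$heart_rate_range), 2)
    mm$amplitude_jitter <- 0
    x <- withr::with_seed(6, generate_pulse_train(mm, 2.1, 1000))
    scalogram_peak(cwt_morlet(x, cfg))$peak_hz
  }, 0)
  expect_lt(pk[["N"]], pk[["S2"]])
})

test_that("rendering is deterministic, shape-correct, and handles flat input", {
  t <- (0:2099) / 1000
  s <- cwt_morlet(sin(2 * pi * 2 * t), cwt_config())
  img <- render_scalogram(s, c(224, 224))
  expect_identical(dim(img), c(224L, 224L, 3L))
  expect_true(all(img >= 0 & img <= 255))
  expect_identical(render_scalogram(s, c(224, 224)), img)

  z <- cwt_morlet(numeric(2100), cwt_config())
  uni <- render_scalogram(z, c(8, 8))
  # all pixels identical: the colormap floor color
  expect_identical(length(unique(as.vector(uni[, , 1]))), 1L)
  expect_identical(length(unique(as.vector(uni[, , 2]))), 1L)
  small <- render_scalogram(s, c(64, 64))
  expect_identical(dim(small), c(64L, 64L, 3L))
})
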