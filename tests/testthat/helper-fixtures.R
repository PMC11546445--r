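# Shared fixtures, built in code at test time.

# a small, fast cohort used by several files (memoised per test run)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(synth_cohort_config(
        n_subjects = 8, class_proportions = c(0.25, 0.25, 0.25, 0.25),
        seed = 42))
    cache
  }
})

# manifest data.frame without files on disk
make_manifest <- function(subjects, labels, segments_per_subject = 3L,
                          synthetic = FALSE, source = subjects) {
  do.call(rbind, lapply(seq_along(subjects), function(i)
    data.frame(path = "", subject_id = subjects[i], label = labels[i],
               segment_index = seq_len(segments_per_subject) - 1L,
               synthetic = synthetic,
               source_subject_id = source[i], stringsAsFactors = FALSE)))
}

# tiny network configuration for fast model tests
tiny_ppgnet_config <- function(use_bn = TRUE) {
  ppgnet_config(input_size = c(16L, 16L, 2L), stem_widths = c(3L, 4L),
                entry_widths = c(5L), middle_blocks = 1L, middle_width = 6L,
                exit_widths = c(7L), use_batch_normalization = use_bn)
}

# Independent closed-form parameter count for the PPG-NET graph. Mirrors the
# architecture definition arithmetically: standard conv Dk^2*M*N, separable
# conv Dk^2*M + M*N, 1x1 shortcut M*N, dense M*N + N; conv biases only when
# batch normalization is off; batch-norm gamma/beta counted separately.
closed_form_counts <- function(cfg) {
  bn <- cfg$use_batch_normalization
  main <- 0; bnp <- 0
  conv <- function(k, M, N) k * k * M * N + if (bn) 0 else N
  sep  <- function(M, N) 9 * M + M * N + if (bn) 0 else N
  C <- cfg$input_size[3]
  s <- cfg$stem_widths
  main <- main + conv(3, C, s[1]) + conv(3, s[1], s[2])
  bnp <- bnp + 2 * (s[1] + s[2])
  cur <- s[2]
  for (w in cfg$entry_widths) {
    main <- main + sep(cur, w) + sep(w, w) + conv(1, cur, w)
    bnp <- bnp + 2 * 3 * w
    cur <- w
  }
  if (cfg$middle_width != cur) {
    main <- main + cur * cfg$middle_width + if (bn) 0 else cfg$middle_width
    bnp <- bnp + 2 * cfg$middle_width
    cur <- cfg$middle_width
  }
  main <- main + cfg$middle_blocks * 3 * sep(cur, cur)
  bnp <- bnp + cfg$middle_blocks * 3 * 2 * cur
  for (w in cfg$exit_widths) {
    main <- main + sep(cur, w)
    bnp <- bnp + 2 * w
    cur <- w
  }
  main <- main + cur * cfg$n_classes + cfg$n_classes
  list(main = main, bn = if (bn) bnp else 0)
}

rand_images <- function(n, hw = 16L, ch = 2L, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    array(runif(hw * hw * ch) * 255, c(hw, hw, ch))))
}

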