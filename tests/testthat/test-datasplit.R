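test_that("balancing the study's class counts yields the target everywhere", {
  # class counts 240/255/102/60 balanced to 250 per class: the prehypertension
  # class is undersampled, the two hypertension stages are SMOTE-oversampled
  withr::with_seed(10, {
    counts <- c(N = 240, P = 255, S1 = 102, S2 = 60)
    labels <- rep(names(counts), counts)
    vectors <- lapply(seq_along(labels), function(i) rnorm(12))
  })
  bal <- balance_classes(vectors, labels, balance_spec(per_class_target = 250, seed = 3))
  expect_true(all(table(bal$labels) == 250))
  # originals among the prehypertension survivors, none duplicated
  expect_identical(sum(bal$labels == "P" & !bal$synthetic), 250L)
})

test_that("every SMOTE vector lies exactly on a parent-neighbor segment", {
  withr::with_seed(12, {
    vectors <- lapply(1:8, function(i) rnorm(20))
    labels <- rep("S2", 8)
  })
  out <- smote_oversample(vectors, labels, balance_spec(per_class_target = 30, seed = 5))
  X <- do.call(rbind, vectors)
  syn <- which(out$synthetic)
  expect_identical(length(syn), 22L)
  for (s in syn) {
    v <- out$vectors[[s]]
    # distance from v to the closest segment between any two originals
    seg_dist <- function(p, q) {
      d <- q - p; tt <- sum((v - p) * d) / sum(d * d)
      tt <- min(max(tt, 0), 1)
      sqrt(sum((v - (p + tt * d))^2))
    }
    dists <- apply(utils::combn(8, 2), 2, function(ij) seg_dist(X[ij[1], ], X[ij[2], ]))
    expect_lt(min(dists), 1e-9)
    # provenance: the parent is one of the two segment endpoints
    p <- out$parent_index[s]
    expect_false(is.na(p))
    expect_identical(out$source_subject_id[s], paste0("v", p))
  }
})

test_that("SMOTE refuses singleton classes and leaves full classes alone", {
  vectors <- lapply(1:5, function(i) rnorm(4))
  expect_error(
    smote_oversample(vectors, c("N", "N", "N", "N", "S2"),
                     balance_spec(per_class_target = 4)),
    "fewer than 2")
  out <- smote_oversample(vectors[1:4], rep("N", 4), balance_spec(per_class_target = 4))
  expect_identical(length(out$vectors), 4L)
  expect_false(any(out$synthetic))
})

test_that("undersampling is exact, duplicate-free and seed-deterministic", {
  vectors <- as.list(seq_len(255))
  labels <- rep("P", 255)
  a <- undersample(vectors, labels, 250, seed = 8)
  expect_identical(length(a$keep), 250L)
  expect_false(anyDuplicated(a$keep) > 0)
  expect_true(all(a$keep %in% seq_len(255)))
  b <- undersample(vectors, labels, 250, seed = 8)
  expect_identical(a$keep, b$keep)
  expect_identical(undersample(vectors, labels, 255, seed = 1)$keep, seq_len(255))
  expect_error(undersample(vectors, labels, 300, seed = 1), "target")
})

test_that("subject-aware splits put whole subjects (and their synthetics) on one side", {
  man <- make_manifest(sprintf("s%02d", 1:10), rep(c("N", "P", "S1", "S2", "N"), 2))
  syn <- make_manifest("s03", "S1", segments_per_subject = 2L,
                       synthetic = TRUE, source = "s03")
  man <- rbind(man, syn)
  # with this draw every S1 subject lands in test: that is a warning, not
  # an error - the split itself must still be valid
  expect_warning(plan <- subject_aware_split(man, test_fraction = 0.2, seed = 4),
                 "absent from the training side")
  expect_identical(length(plan$test_subjects), 2L)
  expect_length(intersect(plan$test_subjects, plan$train_subjects), 0L)
  expect_true(assert_no_leakage(plan, man))
  # the synthetic child of s03 follows s03 wherever it goes
  side <- if ("s03" %in% plan$test_subjects) plan$test_subjects else plan$train_subjects
  expect_true("s03" %in% side)

  empty_test <- subject_aware_split(man, test_fraction = 0, seed = 4)
  expect_length(empty_test$test_subjects, 0L)
})

test_that("k-fold plans partition subjects with sizes differing by at most one", {
  subj25 <- sprintf("s%02d", 1:25)
  f <- kfold_plan(subj25, k = 5, seed = 2)
  expect_identical(lengths(f), rep(5L, 5L))
  expect_setequal(unlist(f), subj25)

  subj26 <- sprintf("s%02d", 1:26)
  f26 <- kfold_plan(subj26, k = 5, seed = 2)
  expect_setequal(sort(lengths(f26)), c(5L, 5L, 5L, 5L, 6L))
  expect_setequal(unlist(f26), subj26)
  expect_false(anyDuplicated(unlist(f26)) > 0)

  expect_error(kfold_plan(sprintf("s%d", 1:3), k = 5), "exceeds")
})

test_that("split plans are pure functions of (manifest, seed) and survive JSON", {
  man <- make_manifest(sprintf("s%02d", 1:12), rep(c("N", "P", "S1", "S2"), 3))
  p1 <- subject_aware_split(man, seed = 99)
  p2 <- subject_aware_split(man, seed = 99)
  expect_identical(p1, p2)
  f <- withr::local_tempfile(fileext = ".json")
  write_split_plan(p1, f)
  expect_identical(read_split_plan(f), p1)
})

test_that("no leakage across 200 random manifests with synthetic children", {
  withr::with_seed(1234, {
    for (i in 1:200) {
      n_sub <- sample(6:30, 1)
      subs <- sprintf("r%03d", seq_len(n_sub))
      labs <- sample(c("N", "P", "S1", "S2"), n_sub, replace = TRUE)
      man <- make_manifest(subs, labs, segments_per_subject = sample(1:3, 1))
      n_syn <- sample(0:10, 1)
      if (n_syn > 0) {
        parents <- sample(subs, n_syn, replace = TRUE)
        syn <- do.call(rbind, lapply(seq_len(n_syn), function(j)
          data.frame(path = "", subject_id = parents[j],
                     label = labs[match(parents[j], subs)],
                     segment_index = 0L, synthetic = TRUE,
                     source_subject_id = parents[j], stringsAsFactors = FALSE)))
        man <- rbind(man, syn)
      }
      plan <- suppressWarnings(   # rare classes may be absent from training
        subject_aware_split(man, test_fraction = runif(1, 0.1, 0.4),
                            seed = i, k = 3L))
      expect_true(assert_no_leakage(plan, man))
      test_src <- man$source_subject_id[man$source_subject_id %in% plan$test_subjects]
      train_src <- man$source_subject_id[man$source_subject_id %in% plan$train_subjects]
      expect_length(intersect(test_src, train_src), 0L)
    }
  })
})
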