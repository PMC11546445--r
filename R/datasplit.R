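#' Class-balancing specification
#'
#' @param per_class_target target count per class after balancing (default
#'   250, the bookkeeping the pipeline's study design reports: class counts
#'   240/255/102/60 are balanced to 250 each).
#' @param smote_k number of same-class nearest neighbors SMOTE interpolates
#'   toward (default 5).
#' @param seed integer RNG seed.
#' @return an object of class `balance_spec`.
#' @export
balance_spec <- function(per_class_target = 250L, smote_k = 5L, seed = 1L) {
  stopifnot(per_class_target >= 1, smote_k >= 1)
  structure(list(per_class_target = as.integer(per_class_target),
                 smote_k = as.integer(smote_k), seed = as.integer(seed)),
            class = "balance_spec")
}

#' SMOTE oversampling in signal space
#'
#' For every class below `spec$per_class_target`, synthetic vectors are
#' created as `x_new = x + lambda * (x_nn - x)` with `lambda ~ U[0, 1]` and
#' `x_nn` one of the `smote_k` Euclidean nearest same-class neighbors of a
#' randomly chosen parent `x`. Each synthetic record inherits the
#' `source_subject_id` of its parent, so subject-aware splitting keeps it on
#' the parent's side.
#'
#' @param vectors list (or matrix rows) of equal-length numeric vectors.
#' @param labels character or integer class labels, one per vector.
#' @param spec a [balance_spec()].
#' @param subject_ids per-vector subject ids (provenance); defaults to
#'   `"v<i>"`.
#' @return list with `vectors`, `labels`, `synthetic` (logical),
#'   `source_subject_id`, `parent_index` (NA for originals).
#' @export
smote_oversample <- function(vectors, labels, spec = balance_spec(),
                             subject_ids = NULL) {
  if (is.matrix(vectors)) vectors <- asplit(vectors, 1L)
  vectors <- lapply(vectors, as.numeric)
  n <- length(vectors)
  stopifnot(length(labels) == n)
  lens <- lengths(vectors)
  if (length(unique(lens)) > 1L) stop("vectors must have equal length", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- paste0("v", seq_len(n))
  counts <- table(labels)
  below <- names(counts)[counts < spec$per_class_target]
  short <- names(counts)[counts < 2L & counts < spec$per_class_target]
  if (length(short))
    stop("class(es) ", paste(short, collapse = ", "),
         " have fewer than 2 members and cannot be SMOTE-interpolated",
         call. = FALSE)
  out_v <- vectors; out_l <- as.character(labels)
  out_syn <- rep(FALSE, n); out_src <- as.character(subject_ids)
  out_par <- rep(NA_integer_, n)
  withr::with_seed(spec$seed, {
    for (cl in below) {
      idx <- which(labels == cl)
      X <- do.call(rbind, vectors[idx])
      D <- as.matrix(dist(X))
      diag(D) <- Inf
      k <- min(spec$smote_k, length(idx) - 1L)
      need <- spec$per_class_target - length(idx)
      for (j in seq_len(need)) {
        pi_local <- sample.int(length(idx), 1L)
        nn_local <- order(D[pi_local, ])[sample.int(k, 1L)]
        lam <- runif(1)
        newv <- X[pi_local, ] + lam * (X[nn_local, ] - X[pi_local, ])
        parent <- idx[pi_local]
        out_v[[length(out_v) + 1L]] <- newv
        out_l <- c(out_l, cl)
        out_syn <- c(out_syn, TRUE)
        out_src <- c(out_src, as.character(subject_ids[parent]))
        out_par <- c(out_par, parent)
      }
    }
  })
  list(vectors = out_v, labels = out_l, synthetic = out_syn,
       source_subject_id = out_src, parent_index = out_par)
}

#' Uniform majority undersampling
#'
#' Keeps a uniform random subset (without replacement) of exactly `target`
#' members of the given set; deterministic given `seed`.
#'
#' @param vectors list of vectors (or any list of records).
#' @param labels per-record labels.
#' @param target per-class target count.
#' @param seed integer RNG seed.
#' @return list with `keep` (indices into the input, sorted), plus the
#'   subsetted `vectors` and `labels`.
#' @export
undersample <- function(vectors, labels, target, seed = 1L) {
  n <- length(vectors)
  stopifnot(length(labels) == n)
  keep <- integer(0)
  withr::with_seed(seed, {
    for (cl in sort(unique(as.character(labels)))) {
      idx <- which(labels == cl)
      if (length(idx) < target)
        stop("class ", cl, " has ", length(idx), " < target ", target, call. = FALSE)
      keep <- c(keep, if (length(idx) == target) idx else sort(sample(idx, target)))
    }
  })
  keep <- sort(keep)
  list(keep = keep, vectors = vectors[keep], labels = labels[keep])
}

#' Balance all classes to a common target
#'
#' Classes above `spec$per_class_target` are undersampled, classes below are
#' SMOTE-oversampled; after balancing, every class count equals the target.
#'
#' @inheritParams smote_oversample
#' @return as [smote_oversample()], on the balanced set.
#' @export
balance_classes <- function(vectors, labels, spec = balance_spec(),
                            subject_ids = NULL) {
  if (is.matrix(vectors)) vectors <- asplit(vectors, 1L)
  n <- length(vectors)
  if (is.null(subject_ids)) subject_ids <- paste0("v", seq_len(n))
  over <- table(labels) > spec$per_class_target
  if (any(over)) {
    labs <- as.character(labels)
    keep <- integer(0)
    for (cl in sort(unique(labs))) {
      idx <- which(labs == cl)
      if (length(idx) > spec$per_class_target) {
        u <- undersample(vectors[idx], labs[idx], spec$per_class_target,
                         seed = spec$seed + match(cl, sort(unique(labs))))
        keep <- c(keep, idx[u$keep])
      } else keep <- c(keep, idx)
    }
    keep <- sort(keep)
    vectors <- vectors[keep]; labels <- labels[keep]; subject_ids <- subject_ids[keep]
  }
  smote_oversample(vectors, labels, spec, subject_ids)
}

#' Subject-aware train/test split
#'
#' Subjects (grouped by `source_subject_id`, so synthetic records travel
#' with their parent subject) are shuffled with `seed` and
#' `round(test_fraction * n_subjects)` of them form the test side. Every
#' record follows its subject: no subject contributes to both sides.
#'
#' @param manifest a `ppg_manifest` data.frame.
#' @param test_fraction fraction of subjects assigned to test (default 0.2).
#' @param seed integer RNG seed.
#' @param k number of cross-validation folds over the training subjects.
#' @return an object of class `split_plan`: list with `test_subjects`,
#'   `train_subjects`, `folds` (list of k disjoint subject sets) and `seed`.
#' @export
subject_aware_split <- function(manifest, test_fraction = 0.2, seed = 1L, k = 5L) {
  manifest <- validate_manifest(manifest)
  subjects <- sort(unique(manifest$source_subject_id))
  if (length(subjects) < 5L) stop("need at least 5 subjects", call. = FALSE)
  n_test <- round(test_fraction * length(subjects))
  withr::with_seed(seed, {
    shuffled <- sample(subjects)
    test_subjects <- sort(head(shuffled, n_test))
    train_subjects <- sort(setdiff(subjects, test_subjects))
    for (cl in PPG_LABELS) {
      in_train <- any(manifest$label == cl &
                        manifest$source_subject_id %in% train_subjects)
      if (any(manifest$label == cl) && !in_train)
        warning("class ", cl, " absent from the training side", call. = FALSE)
    }
    folds <- kfold_plan(train_subjects, k = k, seed = seed + 1L)
  })
  structure(list(test_subjects = test_subjects, train_subjects = train_subjects,
                 folds = folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' Partition subjects into k near-equal folds
#'
#' @param train_subjects character vector of subject ids.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return list of k disjoint subject sets whose union is `train_subjects`,
#'   sizes differing by at most 1.
#' @export
kfold_plan <- function(train_subjects, k = 5L, seed = 1L) {
  n <- length(train_subjects)
  if (k > n) stop("k = ", k, " exceeds the ", n, " available subjects", call. = FALSE)
  withr::with_seed(seed, {
    shuffled <- sample(train_subjects)
  })
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) sort(shuffled[starts[i]:ends[i]]))
}

#' Serialize / read a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path JSON path.
#' @return `path` invisibly; `read_split_plan()` returns the `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(
    list(test_subjects = plan$test_subjects, train_subjects = plan$train_subjects,
         folds = plan$folds, seed = plan$seed),
    path, auto_unbox = FALSE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path)   # no simplification: folds stay a list
  structure(list(test_subjects = as.character(unlist(x$test_subjects)),
                 train_subjects = as.character(unlist(x$train_subjects)),
                 folds = lapply(x$folds, function(f) as.character(unlist(f))),
                 seed = as.integer(x$seed[[1L]])),
            class = "split_plan")
}

#' Leakage guard: verify a split plan against a manifest
#'
#' Asserts that no `source_subject_id` (including those of synthetic
#' records) appears on both sides of the train/test split, and that the
#' folds exactly partition the training subjects.
#'
#' @param plan a `split_plan`.
#' @param manifest a `ppg_manifest`.
#' @return `TRUE` invisibly; errors on any leakage.
#' @export
assert_no_leakage <- function(plan, manifest) {
  manifest <- validate_manifest(manifest)
  te <- manifest$source_subject_id[manifest$source_subject_id %in% plan$test_subjects]
  tr <- manifest$source_subject_id[manifest$source_subject_id %in% plan$train_subjects]
  if (length(intersect(te, tr)))
    stop("subject leakage across train/test: ",
         paste(intersect(te, tr), collapse = ", "), call. = FALSE)
  if (length(intersect(plan$test_subjects, plan$train_subjects)))
    stop("split sides overlap", call. = FALSE)
  fold_union <- sort(unlist(plan$folds))
  if (!identical(fold_union, sort(plan$train_subjects)))
    stop("folds do not partition the training subjects", call. = FALSE)
  if (anyDuplicated(fold_union)) stop("folds overlap", call. = FALSE)
  invisible(TRUE)
}
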