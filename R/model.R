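#' PPG-NET architecture configuration
#'
#' Describes the three-flow depthwise-separable convolutional network used
#' to classify scalogram images: a stem of two standard 3x3 convolutions
#' (the first with stride 2), an entry flow of downsampling residual blocks
#' (separable convolutions + stride-2 max pooling, with 1x1 stride-2
#' convolution shortcuts), a middle flow of identity-shortcut residual
#' blocks of three separable convolutions each, an exit flow of separable
#' convolutions, then global average pooling and a fully-connected softmax
#' head over the four blood-pressure stages.
#'
#' @param input_size `(H, W, C)` input image size, default `c(224, 224, 3)`.
#' @param stem_widths channel widths of the two stem convolutions.
#' @param entry_widths channel width per entry-flow downsampling block.
#' @param middle_blocks number of middle-flow residual blocks.
#' @param middle_width middle-flow channel width (a pointwise transition is
#'   inserted when it differs from the last entry width).
#' @param exit_widths channel widths of the exit-flow separable convolutions.
#' @param n_classes number of output classes (4 blood-pressure stages).
#' @param use_batch_normalization add batch normalization after every
#'   convolution (default `TRUE`).
#' @return an object of class `ppgnet_config`.
#' @export
ppgnet_config <- function(input_size = c(224L, 224L, 3L),
                          stem_widths = c(32L, 64L),
                          entry_widths = c(128L, 256L, 256L),
                          middle_blocks = 4L,
                          middle_width = 256L,
                          exit_widths = c(384L, 512L),
                          n_classes = 4L,
                          use_batch_normalization = TRUE) {
  stopifnot(length(input_size) == 3L, all(input_size >= 1L),
            length(stem_widths) == 2L, all(stem_widths >= 1L),
            length(entry_widths) >= 1L, all(entry_widths >= 1L),
            middle_blocks >= 0L, middle_width >= 1L,
            all(exit_widths >= 1L), n_classes == 4L)
  if (input_size[1L] != input_size[2L])
    stop("square inputs required (H == W)", call. = FALSE)
  down <- 2^(1L + length(entry_widths))   # stem stride 2 + one pool per entry block
  if (input_size[1L] < down)
    stop("input of ", input_size[1L], " px is smaller than the total ",
         "downsampling factor ", down, call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 stem_widths = as.integer(stem_widths),
                 entry_widths = as.integer(entry_widths),
                 middle_blocks = as.integer(middle_blocks),
                 middle_width = as.integer(middle_width),
                 exit_widths = as.integer(exit_widths),
                 n_classes = as.integer(n_classes),
                 use_batch_normalization = isTRUE(use_batch_normalization)),
            class = "ppgnet_config")
}

#' Reduced PPG-NET for desk-scale (single CPU) experiments
#'
#' Same three-flow topology at 64x64 input and narrow widths, small enough
#' to train on one CPU in minutes.
#'
#' @param input_hw input height/width (default 64).
#' @return a [ppgnet_config()].
#' @export
reduced_ppgnet_config <- function(input_hw = 64L) {
  ppgnet_config(input_size = c(input_hw, input_hw, 3L),
                stem_widths = c(16L, 32L),
                entry_widths = c(48L, 64L),
                middle_blocks = 3L,
                middle_width = 64L,
                exit_widths = c(96L))
}

#' Closed-form convolution parameter counts
#'
#' A depthwise separable convolution factorizes a standard `Dk x Dk x M x N`
#' convolution into a per-channel spatial filter (`Dk^2 M` parameters) and a
#' 1x1 cross-channel mix (`M N` parameters): `Dk^2 M + M N` versus
#' `Dk^2 M N`, a large reduction whenever `Dk > 1` and `N > 1`.
#'
#' @param Dk spatial kernel size.
#' @param M input channels.
#' @param N output channels.
#' @return parameter count (weights only, no bias).
#' @export
separable_conv_params <- function(Dk, M, N) Dk * Dk * M + M * N

#' @rdname separable_conv_params
#' @export
standard_conv_params <- function(Dk, M, N) Dk * Dk * M * N

#' Build a PPG-NET model
#'
#' Instantiates the layer graph described by the configuration and
#' initializes all convolution and dense weights with He-style random
#' normals (`sd = sqrt(2 / fan_in)`), batch-norm scale/shift at 1/0.
#' Initialization is deterministic given `seed`.
#'
#' @param cfg a [ppgnet_config()].
#' @param seed integer RNG seed for the initialization.
#' @return an object of class `ppgnet_model`: list with `cfg`, `weights`
#'   (named list of arrays in canonical layer order) and `seed`.
#' @export
build_ppgnet <- function(cfg = ppgnet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "ppgnet_config"))
  tmpl <- cpp_weight_template(unclass(cfg))
  weights <- withr::with_seed(seed, {
    lapply(seq_along(tmpl), function(i) {
      w <- tmpl[[i]]
      nm <- names(tmpl)[i]
      d <- dim(w)
      if (grepl("_bngamma$|_bnrvar$", nm)) {
        array(1, dim = if (is.null(d)) length(w) else d)
      } else if (grepl("_bnbeta$|_bnrmean$|b$", nm)) {
        array(0, dim = if (is.null(d)) length(w) else d)
      } else {
        fan_in <- if (is.null(d)) length(w) else d[1L]
        array(rnorm(length(w), sd = sqrt(2 / fan_in)), dim = if (is.null(d)) length(w) else d)
      }
    })
  })
  names(weights) <- names(tmpl)
  structure(list(cfg = cfg, weights = weights, seed = as.integer(seed)),
            class = "ppgnet_model")
}

#' @export
print.ppgnet_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf(paste0("<ppgnet_model> input %dx%dx%d, entry [%s], middle %d x %d, ",
                     "exit [%s]: %d conv/dense parameters (+%d batch-norm)\n"),
              x$cfg$input_size[1], x$cfg$input_size[2], x$cfg$input_size[3],
              paste(x$cfg$entry_widths, collapse = ","),
              x$cfg$middle_blocks, x$cfg$middle_width,
              paste(x$cfg$exit_widths, collapse = ","),
              pc, attr(pc, "bn_params")))
  invisible(x)
}

#' Count model parameters
#'
#' Sums the elements of every convolutional, pointwise-shortcut and dense
#' weight (and bias) array of the built model. Batch-normalization
#' scale/shift parameters are counted separately and reported in the
#' `bn_params` attribute (running statistics are not parameters).
#'
#' @param model a [build_ppgnet()] model.
#' @return integer count of conv/dense parameters, with attribute
#'   `bn_params`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ppgnet_model"))
  nm <- names(model$weights)
  sizes <- vapply(model$weights, length, 0L)
  main <- grepl("_convW$|_convb$|_dwW$|_pwW$|_pwb$|^dense_", nm)
  bn <- grepl("_bngamma$|_bnbeta$", nm)
  structure(sum(sizes[main]), bn_params = sum(sizes[bn]))
}

#' Training configuration
#'
#' Defaults are the tuning parameters of the reference protocol: SGD with
#' learning rate 0.01, batch size 12, 100 epochs, 5 folds, cross-entropy
#' loss, early stopping on the validation-accuracy plateau.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum (protocol does not fix it; 0.9 standard).
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param folds number of cross-validation folds.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param snapshot_k keep the weights of the last `snapshot_k` epochs and
#'   average their softmax outputs at prediction time (0 disables).
#' @param seed integer RNG seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         batch_size = 12L, epochs = 100L, folds = 5L,
                         early_stop_patience = 10L, snapshot_k = 0L, seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            batch_size >= 1, epochs >= 1, folds >= 1, early_stop_patience >= 1,
            snapshot_k >= 0)
  structure(list(optimizer = "SGD", loss = "cross-entropy",
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 folds = as.integer(folds),
                 early_stop_patience = as.integer(early_stop_patience),
                 snapshot_k = as.integer(snapshot_k),
                 seed = as.integer(seed)),
            class = "train_config")
}

# stack a list of HxWx3 images in 0..255 into the engine's HxWxCxN array,
# rescaled to roughly zero-centered inputs
stack_images <- function(images, expected = NULL) {
  d <- dim(images[[1L]])
  if (!is.null(expected) && !identical(as.integer(d), as.integer(expected)))
    stop("image shape ", paste(d, collapse = "x"),
         " does not match the model input ", paste(expected, collapse = "x"),
         call. = FALSE)
  X <- array(0, c(d[1L], d[2L], d[3L], length(images)))
  for (i in seq_along(images)) {
    di <- dim(images[[i]])
    if (!identical(di, d)) stop("images differ in shape", call. = FALSE)
    X[, , , i] <- images[[i]] / 255 - 0.5
  }
  X
}

#' Train a PPG-NET model on one train/validation split
#'
#' Minimizes the cross-entropy loss with SGD(+momentum), shuffling only the
#' training indices each epoch. Validation accuracy is monitored for early
#' stopping; the returned weights are those of the best validation epoch
#' (never a later one).
#'
#' @param model a [build_ppgnet()] model.
#' @param images list of H x W x 3 arrays in 0..255 (as produced by
#'   [render_scalogram()]).
#' @param labels integer class codes 0..3 (see [label_code()]).
#' @param train_idx,val_idx 1-based indices into `images`.
#' @param tc a [train_config()].
#' @param verbose print per-epoch progress.
#' @return the model with trained `weights`, plus `history` (per-epoch loss
#'   and accuracies), `best_epoch`, `best_val_accuracy`, `stopped_epoch`.
#' @export
train_ppgnet <- function(model, images, labels, train_idx, val_idx,
                         tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "ppgnet_model"), inherits(tc, "train_config"))
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(images),
            all(labels >= 0L), all(labels < model$cfg$n_classes))
  if (length(train_idx) == 0L) stop("empty training fold", call. = FALSE)
  X <- stack_images(images, expected = model$cfg$input_size)
  fit <- cpp_train(unclass(model$cfg), model$weights, X, labels,
                   as.integer(train_idx) - 1L, as.integer(val_idx) - 1L,
                   list(learning_rate = tc$learning_rate, momentum = tc$momentum,
                        batch_size = tc$batch_size, epochs = tc$epochs,
                        early_stop_patience = tc$early_stop_patience,
                        snapshot_k = tc$snapshot_k,
                        seed = tc$seed, verbose = verbose))
  model$weights <- fit$weights
  if (tc$snapshot_k > 0L) model$snapshots <- fit$snapshots
  model$history <- as.data.frame(fit$history)
  model$best_epoch <- fit$best_epoch
  model$best_val_accuracy <- fit$best_val_accuracy
  model$best_val_loss <- fit$best_val_loss
  model$stopped_epoch <- fit$stopped_epoch
  model
}

#' Subject-aware k-fold cross-validated training
#'
#' For each fold of the split plan, trains on the other folds' subjects and
#' validates on the fold's subjects (all grouped by `source_subject_id`),
#' then reports per-fold metrics on the validation fold.
#'
#' @param model a [build_ppgnet()] model (re-initialized per fold from its
#'   seed so folds are independent).
#' @param images list of H x W x 3 arrays.
#' @param labels integer codes 0..3.
#' @param subjects per-image `source_subject_id`.
#' @param plan a [subject_aware_split()] plan (its `folds` are used).
#' @param tc a [train_config()].
#' @param verbose print progress.
#' @return list of per-fold results: trained model, `report`
#'   (a [metrics_report()]) and the fold's subject set.
#' @export
crossval_ppgnet <- function(model, images, labels, subjects, plan,
                            tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  labels <- as.integer(labels)
  folds <- plan$folds[seq_len(min(tc$folds, length(plan$folds)))]
  lapply(seq_along(folds), function(f) {
    val_sub <- folds[[f]]
    val_idx <- which(subjects %in% val_sub)
    train_idx <- which(subjects %in% setdiff(unlist(folds), val_sub))
    if (length(val_idx) == 0L || length(train_idx) == 0L)
      stop("fold ", f, " is empty", call. = FALSE)
    m0 <- build_ppgnet(model$cfg, seed = model$seed + f)
    tcf <- tc; tcf$seed <- tc$seed + f
    fit <- train_ppgnet(m0, images, labels, train_idx, val_idx, tcf, verbose)
    pred <- predict_ppgnet(fit, images[val_idx])
    list(fold = f, model = fit, subjects = val_sub,
         report = metrics_report(confusion_matrix(labels[val_idx], pred$labels,
                                                  K = model$cfg$n_classes)))
  })
}

#' Predict stage labels for scalogram images
#'
#' Deterministic: softmax probabilities with ties at the argmax broken
#' toward the lowest class index.
#'
#' @param model a trained `ppgnet_model`.
#' @param images list of H x W x 3 arrays in 0..255.
#' @return list with `labels` (integer codes), `stage` (decoded labels) and
#'   `probabilities` (N x 4 matrix; rows sum to 1).
#' @export
predict_ppgnet <- function(model, images) {
  stopifnot(inherits(model, "ppgnet_model"))
  X <- stack_images(images, expected = model$cfg$input_size)
  if (!is.null(model$snapshots) && length(model$snapshots) > 0L) {
    # snapshot averaging: mean softmax over the final training epochs'
    # weights smooths late-SGD oscillation of the decision boundary
    p <- Reduce(`+`, lapply(model$snapshots, function(w)
      cpp_predict(unclass(model$cfg), w, X))) / length(model$snapshots)
  } else {
    p <- cpp_predict(unclass(model$cfg), model$weights, X)
  }
  colnames(p) <- PPG_LABELS[seq_len(ncol(p))]
  lab <- max.col(p, ties.method = "first") - 1L
  list(labels = lab, stage = label_decode(lab), probabilities = p)
}

#' Save / load trained weights
#'
#' Weights are saved in R's standard serialized form with a JSON sidecar
#' recording the configuration and seed.
#'
#' @param model a `ppgnet_model`.
#' @param path output `.rds` path; the sidecar is `<path>.json`.
#' @return `path` invisibly; `load_ppgnet()` returns the model.
#' @export
save_ppgnet <- function(model, path) {
  stopifnot(inherits(model, "ppgnet_model"))
  saveRDS(model, path)
  jsonlite::write_json(list(cfg = unclass(model$cfg), seed = model$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_ppgnet
#' @export
load_ppgnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ppgnet_model"))
  model
}
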