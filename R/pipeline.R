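#' Pipeline configuration
#'
#' Nested configuration for the full three-step flow: synthetic cohort
#' generation (optional), preprocessing, scalogram rendering, subject-aware
#' splitting with class balancing, network training, and evaluation.
#' Unknown keys in any section are rejected, so config files fail loudly
#' rather than silently ignoring a typo.
#'
#' @param synth list of [synth_cohort_config()] arguments, or `NULL` to read
#'   an existing manifest instead (`input_manifest` must then be set).
#' @param input_manifest path to an existing manifest CSV (used when
#'   `synth` is `NULL`).
#' @param preprocess list with optional keys `filter` ([filter_spec()]
#'   arguments) and `denoise` ([denoise_spec()] arguments).
#' @param scalogram list with optional keys from [cwt_config()] plus
#'   `out_size` (length-2 integer).
#' @param split list with optional keys `test_fraction`, `k`.
#' @param balance list of [balance_spec()] arguments, or `NULL` to skip the
#'   balancing stage. Balancing is applied to the training side only, after
#'   the subject-aware split.
#' @param model list of [ppgnet_config()] arguments, or the string
#'   `"reduced"` for [reduced_ppgnet_config()].
#' @param train list of [train_config()] arguments.
#' @param seed global seed; stage seeds are derived from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = list(n_subjects = 40,
                                         class_proportions = c(0.25, 0.25, 0.25, 0.25)),
                            input_manifest = NULL,
                            preprocess = list(),
                            scalogram = list(out_size = c(64L, 64L)),
                            split = list(test_fraction = 0.2, k = 5L),
                            balance = list(per_class_target = 72L),
                            model = "reduced",
                            train = list(epochs = 20L),
                            seed = 1L) {
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown key(s) in ", section, " config: ",
           paste(bad, collapse = ", "), call. = FALSE)
    x
  }
  if (!is.null(synth))
    check_keys(synth, names(formals(synth_cohort_config)), "synth")
  if (is.null(synth) && is.null(input_manifest))
    stop("either a synth section or input_manifest is required", call. = FALSE)
  check_keys(preprocess, c("filter", "denoise"), "preprocess")
  if (!is.null(preprocess$filter))
    check_keys(preprocess$filter, names(formals(filter_spec)), "preprocess$filter")
  if (!is.null(preprocess$denoise))
    check_keys(preprocess$denoise, names(formals(denoise_spec)), "preprocess$denoise")
  check_keys(scalogram, c(names(formals(cwt_config)), "out_size"), "scalogram")
  check_keys(split, c("test_fraction", "k"), "split")
  if (!is.null(balance))
    check_keys(balance, names(formals(balance_spec)), "balance")
  if (is.character(model)) {
    model <- match.arg(model, c("reduced", "full"))
  } else check_keys(model, names(formals(ppgnet_config)), "model")
  check_keys(train, c(names(formals(train_config)), "run_cv"), "train")
  structure(list(synth = synth, input_manifest = input_manifest,
                 preprocess = preprocess, scalogram = scalogram,
                 split = split, balance = balance, model = model,
                 train = train, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown key(s) in pipeline config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

pipeline_stage_seed <- function(seed, stage) {
  # small fixed offsets keep stage streams distinct yet reproducible
  offsets <- c(synth = 101L, split = 211L, balance = 307L,
               model = 401L, train = 503L)
  seed + offsets[[stage]]
}

#' Run the full pipeline
#'
#' Executes synthesis (optional) -> preprocessing -> scalograms ->
#' subject-aware split -> training-side balancing -> training ->
#' evaluation, writing every stage's artifacts under `out_dir`:
#' `manifest.csv`, preprocessed signals, scalogram PNGs + `images.csv`,
#' `split_plan.json`, `weights.rds` (+ JSON sidecar), `metrics.json`,
#' `metrics.txt`, and `run.json` (config hash, seed, stage log). Reruns
#' with the same config reproduce the manifest and split bit-exactly.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config.
#' @param out_dir artifact directory (created if needed).
#' @param verbose log stage progress to stderr.
#' @return list with `manifest`, `plan`, `model`, `report`,
#'   `test_accuracy`, `cv` (per-fold reports, when `split$k > 1`) and
#'   `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ppgnet_run_"),
                         verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message("[ppgnet] ", sprintf(...))
  cfg_hash <- substr(digest_config(config), 1, 16)
  log <- list()

  # --- stage: synth / ingest ------------------------------------------
  stage <- "synth"
  result <- tryCatch({
    if (!is.null(config$synth)) {
      sargs <- config$synth
      if (is.null(sargs$seed)) sargs$seed <- pipeline_stage_seed(config$seed, "synth")
      scfg <- do.call(synth_cohort_config, sargs)
      say("generating synthetic cohort: %d subjects x %d segments",
          scfg$n_subjects, scfg$segments_per_subject)
      coh <- generate_cohort(scfg, dir = file.path(out_dir, "signals"))
      manifest <- coh$manifest
      records <- coh$records
    } else {
      say("reading manifest %s", config$input_manifest)
      manifest <- read_manifest(config$input_manifest)
      records <- lapply(seq_len(nrow(manifest)), function(i)
        ppg_record(manifest$subject_id[i], manifest$label[i],
                   manifest$segment_index[i],
                   as.numeric(read_signal(manifest$path[i])), fs = 1000,
                   synthetic = manifest$synthetic[i],
                   source_subject_id = manifest$source_subject_id[i]))
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    log$synth <- sprintf("%d records, %d subjects", nrow(manifest),
                         length(unique(manifest$subject_id)))

    # --- stage: preprocess --------------------------------------------
    stage <- "preprocess"
    fs <- records[[1L]]$fs
    fargs <- config$preprocess$filter
    if (is.null(fargs)) fargs <- list()
    if (is.null(fargs$fs)) fargs$fs <- fs
    fspec <- do.call(filter_spec, fargs)
    say("designing equiripple bandpass (%d taps, %g-%g Hz)",
        fspec$numtaps, fspec$pass_lo, fspec$pass_hi)
    coefs <- design_remez_bandpass(fspec)
    dn <- do.call(denoise_spec, if (is.null(config$preprocess$denoise))
      list() else config$preprocess$denoise)
    say("preprocessing %d segments", length(records))
    pre <- lapply(records, function(r) preprocess_segment(r$samples, coefs, dn))
    log$preprocess <- sprintf("%d segments, filter ripple %.4g",
                              length(pre), attr(coefs, "ripple"))

    # --- stage: scalogram ---------------------------------------------
    stage <- "scalogram"
    sargs <- config$scalogram
    out_size <- sargs$out_size %||% c(64L, 64L)
    sargs$out_size <- NULL
    if (is.null(sargs$fs)) sargs$fs <- fs
    ccfg <- do.call(cwt_config, sargs)
    say("rendering %d scalograms at %dx%d", length(pre), out_size[1], out_size[2])
    img_dir <- file.path(out_dir, "scalograms")
    if (!dir.exists(img_dir)) dir.create(img_dir)
    images <- vector("list", length(pre))
    img_paths <- character(length(pre))
    for (i in seq_along(pre)) {
      images[[i]] <- render_scalogram(cwt_morlet(pre[[i]], ccfg), out_size)
      img_paths[i] <- file.path(img_dir, sprintf("scal_%04d.png", i))
      write_scalogram_image(images[[i]], img_paths[i])
    }
    img_manifest <- manifest
    img_manifest$path <- img_paths
    write_manifest(img_manifest, file.path(out_dir, "images.csv"))
    log$scalogram <- sprintf("%d images", length(images))

    # --- stage: split + balance ---------------------------------------
    stage <- "split"
    labels <- label_code(manifest$label)
    subjects <- manifest$source_subject_id
    plan <- subject_aware_split(manifest,
                                test_fraction = config$split$test_fraction %||% 0.2,
                                seed = pipeline_stage_seed(config$seed, "split"),
                                k = config$split$k %||% 5L)
    assert_no_leakage(plan, manifest)
    write_split_plan(plan, file.path(out_dir, "split_plan.json"))
    test_idx <- which(subjects %in% plan$test_subjects)
    train_idx <- which(subjects %in% plan$train_subjects)
    log$split <- sprintf("%d train / %d test subjects",
                         length(plan$train_subjects), length(plan$test_subjects))

    stage <- "balance"
    if (!is.null(config$balance)) {
      bargs <- config$balance
      if (is.null(bargs$seed)) bargs$seed <- pipeline_stage_seed(config$seed, "balance")
      bspec <- do.call(balance_spec, bargs)
      say("balancing training side to %d per class", bspec$per_class_target)
      bal <- balance_classes(pre[train_idx], manifest$label[train_idx], bspec,
                             subject_ids = subjects[train_idx])
      tr_images <- lapply(bal$vectors, function(x)
        render_scalogram(cwt_morlet(x, ccfg), out_size))
      tr_labels <- label_code(bal$labels)
      tr_subjects <- bal$source_subject_id
      log$balance <- sprintf("training side balanced: %s",
                             paste(table(bal$labels), collapse = "/"))
    } else {
      tr_images <- images[train_idx]
      tr_labels <- labels[train_idx]
      tr_subjects <- subjects[train_idx]
      log$balance <- "skipped"
    }

    # --- stage: train --------------------------------------------------
    stage <- "train"
    mcfg <- if (identical(config$model, "reduced")) {
      reduced_ppgnet_config(out_size[1L])
    } else if (identical(config$model, "full")) {
      ppgnet_config()
    } else do.call(ppgnet_config, config$model)
    targs <- config$train
    targs$run_cv <- NULL
    if (is.null(targs$seed)) targs$seed <- pipeline_stage_seed(config$seed, "train")
    tc <- do.call(train_config, targs)
    model <- build_ppgnet(mcfg, seed = pipeline_stage_seed(config$seed, "model"))
    say("training PPG-NET (%d parameters) for up to %d epochs",
        count_parameters(model), tc$epochs)
    n_tr <- length(tr_images)
    fit <- train_ppgnet(model, c(tr_images, images[test_idx]),
                        c(tr_labels, labels[test_idx]),
                        train_idx = seq_len(n_tr), val_idx = seq_len(n_tr), tc)
    save_ppgnet(fit, file.path(out_dir, "weights.rds"))
    log$train <- sprintf("best epoch %d (train acc %.3f), stopped at %d",
                         fit$best_epoch, fit$best_val_accuracy, fit$stopped_epoch)

    # --- stage: evaluate -----------------------------------------------
    stage <- "evaluate"
    pred <- predict_ppgnet(fit, images[test_idx])
    cm <- confusion_matrix(labels[test_idx], pred$labels)
    report <- metrics_report(cm)
    write_metrics_report(report, file.path(out_dir, "metrics.json"))
    writeLines(format_metrics_table(report), file.path(out_dir, "metrics.txt"))
    say("held-out accuracy: %.4f", report$overall_accuracy)

    cv <- NULL
    if ((config$split$k %||% 5L) > 1L && isTRUE(config$train$run_cv)) {
      stage <- "crossval"
      cv <- crossval_ppgnet(model, images[train_idx], labels[train_idx],
                            subjects[train_idx], plan, tc)
    }
    log$evaluate <- sprintf("held-out accuracy %.4f", report$overall_accuracy)

    jsonlite::write_json(list(config_hash = cfg_hash, seed = config$seed,
                              stages = log),
                         file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(manifest = manifest, plan = plan, model = fit, report = report,
         test_accuracy = report$overall_accuracy, cv = cv, out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_config <- function(config) {
  # content hash without external digest packages: serialize canonically
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x%08x", utils::head(sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt)) %% 2038074743), 1) %% .Machine$integer.max,
          nchar(txt))
}
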