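#' @useDynLib ppgnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft convolve sd runif rnorm median quantile setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# Blood-pressure stage labels, in fixed order; internal codes 0-3.
PPG_LABELS <- c("N", "P", "S1", "S2")

#' Encode / decode blood-pressure stage labels
#'
#' Stages are serialized as the strings `N`, `P`, `S1`, `S2` (normal,
#' prehypertension, stage 1, stage 2 hypertension) and carried internally as
#' integer codes 0--3 in that order.
#'
#' @param label character vector of stage labels.
#' @return `label_code()` returns integer codes 0--3; `label_decode()` the
#'   inverse.
#' @export
label_code <- function(label) {
  idx <- match(label, PPG_LABELS)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed labels are {N, P, S1, S2}", call. = FALSE)
  }
  as.integer(idx - 1L)
}

#' @rdname label_code
#' @param code integer vector of codes in 0--3.
#' @export
label_decode <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 3L)) stop("label codes must lie in 0..3", call. = FALSE)
  PPG_LABELS[code + 1L]
}

#' Construct a PPG record
#'
#' A `ppg_record` holds one labeled PPG segment together with its subject
#' provenance. Synthetic records (SMOTE interpolants) keep the
#' `source_subject_id` of the record they were interpolated from, so that
#' subject-aware splitting can keep them on the same side as their parent.
#'
#' @param subject_id subject identifier (string).
#' @param label stage label, one of `"N"`, `"P"`, `"S1"`, `"S2"`.
#' @param segment_index non-negative integer segment index within the subject.
#' @param samples numeric vector of dimensionless PPG amplitudes (length >= 2).
#' @param fs sampling rate in Hz (> 0).
#' @param synthetic logical; `TRUE` for SMOTE-generated records.
#' @param source_subject_id provenance subject id; defaults to `subject_id`.
#' @return an object of class `ppg_record`.
#' @export
ppg_record <- function(subject_id, label, segment_index, samples, fs,
                       synthetic = FALSE, source_subject_id = subject_id) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  label <- match.arg(label, PPG_LABELS)
  segment_index <- as.integer(segment_index)
  if (segment_index < 0L) stop("segment_index must be >= 0", call. = FALSE)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a PPG record needs at least 2 samples", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate in Hz", call. = FALSE)
  structure(
    list(subject_id = subject_id, label = label, segment_index = segment_index,
         samples = samples, fs = as.numeric(fs), synthetic = isTRUE(synthetic),
         source_subject_id = source_subject_id),
    class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> subject %s seg %d label %s: %d samples @ %g Hz%s\n",
              x$subject_id, x$segment_index, x$label, length(x$samples), x$fs,
              if (x$synthetic) sprintf(" (synthetic, from %s)", x$source_subject_id) else ""))
  invisible(x)
}

#' Read a PPG signal from a one-column text/CSV file
#'
#' The signal dialect is one numeric value per line; a single leading
#' non-numeric header line is skipped. No resampling is performed: samples
#' are returned in file order.
#'
#' @param path path to the signal file.
#' @param fs sampling rate in Hz, attached as the `fs` attribute.
#' @return numeric vector of samples with attribute `fs`.
#' @export
read_signal <- function(path, fs = 1000) {
  if (!file.exists(path)) stop("signal file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty signal file: ", path, call. = FALSE)
  suppressWarnings(vals <- as.numeric(lines))
  if (is.na(vals[1L]) && length(lines) > 1L) {
    # single header line tolerated
    lines <- lines[-1L]
    suppressWarnings(vals <- as.numeric(lines))
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("non-numeric content in ", path, " at data line ", bad,
         " (", sQuote(lines[bad]), ")", call. = FALSE)
  }
  structure(vals, fs = fs)
}

#' Write a PPG signal as one value per line
#'
#' @param samples numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(samples, path) {
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  writeLines(formatC(samples, format = "g", digits = 17), path)
  invisible(path)
}

MANIFEST_COLS <- c("path", "subject_id", "label", "segment_index",
                   "synthetic", "source_subject_id")

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with columns `path, subject_id, label, segment_index`
#' and optional `synthetic, source_subject_id`. Each row describes one PPG
#' segment file. Rows must be unique on (subject_id, segment_index,
#' synthetic ordinal): the same subject may contribute several real segments
#' and several synthetic derivatives, but not two identical triples.
#'
#' @param path CSV path.
#' @return a `data.frame` of class `ppg_manifest` with the columns above.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("path", "subject_id", "label", "segment_index")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (!"synthetic" %in% names(df)) df$synthetic <- "FALSE"
  if (!"source_subject_id" %in% names(df)) df$source_subject_id <- df$subject_id
  df$segment_index <- as.integer(df$segment_index)
  df$synthetic <- as.logical(df$synthetic)
  df <- df[, MANIFEST_COLS]
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest a manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a manifest data.frame
#'
#' Checks labels against the allowed set and enforces uniqueness of
#' (subject_id, segment_index, synthetic-ordinal) triples.
#'
#' @param manifest a data.frame with the manifest columns.
#' @return the manifest, with class `ppg_manifest` attached.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  if (!"synthetic" %in% names(manifest)) manifest$synthetic <- FALSE
  if (!"source_subject_id" %in% names(manifest))
    manifest$source_subject_id <- manifest$subject_id
  label_code(manifest$label)  # errors on unknown labels
  if (nrow(manifest) > 0) {
    # synthetic rows are disambiguated by an implicit ordinal (their row order),
    # so only real records can collide on (subject_id, segment_index)
    real <- !manifest$synthetic
    triple <- paste(manifest$subject_id, manifest$segment_index, sep = "\r")[real]
    if (anyDuplicated(triple))
      stop("duplicate (subject_id, segment_index) among real records: ",
           paste(unique(gsub("\r", "/", triple[duplicated(triple)])), collapse = ", "),
           call. = FALSE)
  }
  class(manifest) <- unique(c("ppg_manifest", class(manifest)))
  manifest
}

#' Write an 8-bit RGB scalogram image as a lossless PNG
#'
#' @param image H x W x 3 integer array with values in 0..255.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_scalogram_image <- function(image, path) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  if (any(dim(image)[1:2] == 0L)) stop("image height and width must be positive", call. = FALSE)
  if (!all(is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  if (min(image) < 0 || max(image) > 255)
    stop("image values must lie in 0..255", call. = FALSE)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read a scalogram PNG back as an 8-bit RGB array
#'
#' Inverse of [write_scalogram_image()]: the round-trip is bit-exact.
#'
#' @param path PNG path.
#' @return H x W x 3 integer array in 0..255.
#' @export
read_scalogram_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3L] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  array(as.integer(round(arr * 255)), dim(arr))
}
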