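#' Two-class expression dataset
#'
#' The internal container for a binary-labelled feature matrix: a numeric
#' matrix with features as rows and samples as columns, per-sample class
#' labels, and the mapping of the two observed label values onto the
#' positive/negative roles used by sensitivity and specificity.
#'
#' @param matrix numeric matrix, features as rows, samples as columns.
#' @param labels character or factor vector of per-sample labels, length
#'   `ncol(matrix)`; exactly two distinct values must be present.
#' @param positive_label the label value to treat as the positive class.
#'   Sensitivity/specificity are asymmetric, so this is never guessed.
#' @param feature_ids unique feature identifiers; defaults to
#'   `rownames(matrix)` or `f1..fn`.
#' @param sample_ids sample identifiers; defaults to `colnames(matrix)` or
#'   `s1..sm`.
#' @param allow_missing if `TRUE`, missing values are tolerated (so that
#'   [drop_missing_features()] can be applied afterwards); the default is to
#'   reject them.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `y` (integer 0/1, 1 = positive), `positive_label`,
#'   `negative_label`, `feature_ids`, `sample_ids`, `P` and `N` (class
#'   sizes).
#' @export
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' ds <- expression_dataset(x, c("a", "a", "b", "b"), positive_label = "a")
#' ds$P
expression_dataset <- function(matrix, labels, positive_label,
                               feature_ids = NULL, sample_ids = NULL,
                               allow_missing = FALSE) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  m <- ncol(matrix)
  if (n < 1L || m < 2L)
    rifs_stop("rifs_parse_error", "matrix must have >= 1 feature and >= 2 samples")

  labels <- as.character(labels)
  if (length(labels) != m)
    rifs_stop("rifs_alignment_error", sprintf(
      "got %d labels for %d samples", length(labels), m))
  if (anyNA(labels))
    rifs_stop("rifs_label_error", "labels contain missing values")
  lev <- unique(labels)
  if (length(lev) != 2L)
    rifs_stop("rifs_label_error", sprintf(
      "expected exactly 2 distinct labels, found %d (%s)",
      length(lev), paste(utils::head(lev, 5), collapse = ", ")))
  if (missing(positive_label) || is.null(positive_label))
    rifs_stop("rifs_label_error", "positive_label must be given explicitly")
  positive_label <- as.character(positive_label)
  if (!positive_label %in% lev)
    rifs_stop("rifs_label_error", sprintf(
      "positive_label '%s' not among observed labels (%s)",
      positive_label, paste(lev, collapse = ", ")))
  negative_label <- setdiff(lev, positive_label)

  feature_ids <- feature_ids %||% rownames(matrix) %||% paste0("f", seq_len(n))
  sample_ids <- sample_ids %||% colnames(matrix) %||% paste0("s", seq_len(m))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != n)
    rifs_stop("rifs_parse_error", "feature_ids length does not match matrix")
  if (anyDuplicated(feature_ids))
    rifs_stop("rifs_parse_error", "feature_ids must be unique")
  if (length(sample_ids) != m)
    rifs_stop("rifs_alignment_error", "sample_ids length does not match matrix")
  rownames(matrix) <- feature_ids
  colnames(matrix) <- sample_ids

  if (!allow_missing && anyNA(matrix))
    rifs_stop("rifs_parse_error",
              "matrix contains missing values; see drop_missing_features()")

  y <- as.integer(labels == positive_label)
  ds <- structure(list(
    matrix = matrix,
    y = y,
    positive_label = positive_label,
    negative_label = negative_label,
    feature_ids = feature_ids,
    sample_ids = sample_ids,
    P = sum(y == 1L),
    N = sum(y == 0L)
  ), class = "ExpressionDataset")
  ds
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "ExpressionDataset: %d features x %d samples (P=%d '%s', N=%d '%s')\n",
    nrow(x$matrix), ncol(x$matrix), x$P, x$positive_label, x$N,
    x$negative_label))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

#' Per-sample labels of a dataset
#' @param ds an `ExpressionDataset`.
#' @return character vector of original label values.
#' @export
dataset_labels <- function(ds) {
  ifelse(ds$y == 1L, ds$positive_label, ds$negative_label)
}

#' Remove features carrying missing values
#'
#' Any feature (row) with one or more missing entries is excluded wholesale;
#' samples are never dropped.  The removal is reported via [message()] with
#' the affected feature identifiers.  Idempotent.
#'
#' @param ds an `ExpressionDataset` (possibly built with
#'   `allow_missing = TRUE`).
#' @return An `ExpressionDataset` with complete features only.
#' @export
drop_missing_features <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  bad <- rowSums(is.na(ds$matrix)) > 0L
  if (!any(bad)) return(ds)
  if (all(bad))
    rifs_stop("rifs_empty_dataset_error",
              "every feature has missing data; nothing left to analyse")
  dropped <- ds$feature_ids[bad]
  message(sprintf("drop_missing_features: excluding %d feature(s): %s",
                  length(dropped),
                  paste(utils::head(dropped, 10), collapse = ", ")))
  expression_dataset(ds$matrix[!bad, , drop = FALSE], dataset_labels(ds),
                     positive_label = ds$positive_label,
                     sample_ids = ds$sample_ids)
}

.na_strings <- c("", "NA", "NaN", "nan", "na", "NAN")

#' Load a delimited feature matrix and label file
#'
#' Reads a rectangular numeric matrix with a header of identifiers and a
#' two-column label table (`sample_id`, `label`), aligns samples by
#' identifier, maps the two label values onto positive/negative via
#' `positive_label`, and (by default) excludes features with missing data.
#'
#' @param matrix_path path to the delimited matrix.  With
#'   `orientation = "features_as_rows"` (the microarray convention and the
#'   default) the header row holds sample identifiers and the first column
#'   holds feature identifiers; `"samples_as_rows"` is the transpose.
#' @param labels_path path to a delimited two-column file with a header;
#'   column 1 is the sample identifier, column 2 the class label.
#' @param positive_label the label value to treat as positive.
#' @param orientation `"features_as_rows"` or `"samples_as_rows"`.
#' @param delimiter field separator for both files (default `","`).
#' @param drop_missing apply [drop_missing_features()] after ingestion
#'   (default `TRUE`).  Empty cells, `NA`, and `NaN` (case-insensitive) are
#'   read as missing.
#' @return An `ExpressionDataset`.
#' @export
load_dataset <- function(matrix_path, labels_path, positive_label,
                         orientation = c("features_as_rows", "samples_as_rows"),
                         delimiter = ",", drop_missing = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(matrix_path))
    rifs_stop("rifs_parse_error", paste("matrix file not found:", matrix_path))
  if (!file.exists(labels_path))
    rifs_stop("rifs_parse_error", paste("labels file not found:", labels_path))

  raw <- tryCatch(
    utils::read.table(matrix_path, header = TRUE, sep = delimiter,
                      check.names = FALSE, na.strings = .na_strings,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) rifs_stop("rifs_parse_error", paste(
      "failed to parse matrix file:", conditionMessage(e))))
  if (ncol(raw) < 2L)
    rifs_stop("rifs_parse_error", "matrix file needs an id column plus data")
  ids <- as.character(raw[[1L]])
  num <- raw[, -1L, drop = FALSE]
  if (!all(vapply(num, function(col) is.numeric(col) || all(is.na(col)),
                  logical(1))))
    rifs_stop("rifs_parse_error", "non-numeric cells in matrix body")
  mat <- as.matrix(num)
  storage.mode(mat) <- "double"
  rownames(mat) <- ids

  if (orientation == "samples_as_rows") mat <- t(mat)
  # now features are rows, columns are samples

  lab <- tryCatch(
    utils::read.table(labels_path, header = TRUE, sep = delimiter,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) rifs_stop("rifs_parse_error", paste(
      "failed to parse labels file:", conditionMessage(e))))
  if (ncol(lab) < 2L)
    rifs_stop("rifs_parse_error", "labels file needs columns sample_id,label")
  lab_ids <- as.character(lab[[1L]])
  lab_val <- as.character(lab[[2L]])
  if (anyDuplicated(lab_ids))
    rifs_stop("rifs_alignment_error", "duplicate sample ids in labels file")

  smp <- colnames(mat)
  if (!setequal(smp, lab_ids))
    rifs_stop("rifs_alignment_error", sprintf(
      "sample ids differ between matrix and labels (e.g. %s)",
      paste(utils::head(c(setdiff(smp, lab_ids), setdiff(lab_ids, smp)), 3),
            collapse = ", ")))
  labels <- lab_val[match(smp, lab_ids)]

  ds <- expression_dataset(mat, labels, positive_label = positive_label,
                           allow_missing = TRUE)
  if (drop_missing) ds <- drop_missing_features(ds)
  ds
}

#' Write a dataset back to delimited files
#'
#' Values are written with 17 significant digits so that a write/load
#' round-trip reproduces the matrix exactly.
#'
#' @param ds an `ExpressionDataset`.
#' @param matrix_path,labels_path output paths.
#' @param delimiter field separator (default `","`).
#' @return Invisibly, `ds`.
#' @export
write_dataset <- function(ds, matrix_path, labels_path, delimiter = ",") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  mat <- ds$matrix
  body <- apply(mat, 2, function(col) format(col, digits = 17, trim = TRUE,
                                             scientific = TRUE))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(mat))
  df <- data.frame(feature_id = ds$feature_ids, body,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", ds$sample_ids)
  utils::write.table(df, matrix_path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(
    data.frame(sample_id = ds$sample_ids, label = dataset_labels(ds)),
    labels_path, sep = delimiter, row.names = FALSE, quote = FALSE)
  invisible(ds)
}
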