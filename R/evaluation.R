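#' Stratified k-fold assignment
#'
#' Splits the positive and the negative samples separately into `k` parts
#' whose sizes differ by at most one, so every fold preserves the class
#' balance.  The assignment is a deterministic function of
#' `(labels, k, seed)`.
#'
#' The special case `k == length(labels)` is leave-one-out: each sample is
#' its own fold and the seed is irrelevant.
#'
#' @param labels per-sample class labels (any vector with two values; only
#'   the grouping matters).
#' @param k number of folds, `>= 2`.
#' @param seed integer seed controlling the random split.
#' @return An object of class `FoldAssignment`: list with
#'   `fold_of_sample` (integer in `1..k`), `k`, `seed`.
#' @export
stratified_kfold <- function(labels, k, seed = 0L) {
  m <- length(labels)
  stopifnot(is_count(k), k >= 2)
  k <- as.integer(k)
  fold <- integer(m)
  if (k == m) {                       # leave-one-out, seed-invariant
    fold <- seq_len(m)
  } else {
    classes <- unique(labels)
    sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
    if (min(sizes) < k)
      rifs_stop("rifs_stratification_error", sprintf(
        "smallest class has %d samples < k = %d folds; use a smaller k",
        min(sizes), k))
    local_seed(seed, {
      for (cl in classes) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
  }
  structure(list(fold_of_sample = fold, k = k, seed = as.integer(seed)),
            class = "FoldAssignment")
}

#' Binary classification metrics from confusion counts
#'
#' Computes, from pooled confusion counts,
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Acc = (TP+TN)/(TP+FN+TN+FP)`, `Precision = TP/(TP+FP)` and
#' `Fscore = 2 * Precision * Sn / (Precision + Sn)`.
#' Degenerate denominators (`TP+FP = 0`, or `Precision + Sn = 0`) yield 0.
#'
#' @param counts named numeric vector or list with elements `TP`, `FN`,
#'   `FP`, `TN`.
#' @return Named numeric vector `c(Sn, Sp, Acc, Precision, Fscore)`.
#' @export
#' @examples
#' compute_metrics(c(TP = 3, FN = 1, FP = 2, TN = 4))
compute_metrics <- function(counts) {
  counts <- unlist(counts)
  stopifnot(all(c("TP", "FN", "FP", "TN") %in% names(counts)))
  TP <- counts[["TP"]]; FN <- counts[["FN"]]
  FP <- counts[["FP"]]; TN <- counts[["TN"]]
  stopifnot(all(c(TP, FN, FP, TN) >= 0), TP + FN >= 1, FP + TN >= 1)
  sn <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  acc <- (TP + TN) / (TP + FN + TN + FP)
  prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
  f <- if (prec + sn == 0) 0 else 2 * prec * sn / (prec + sn)
  c(Sn = sn, Sp = sp, Acc = acc, Precision = prec, Fscore = f)
}

# confusion counts (rows: classifiers, cols TP FN FP TN) for one fold
# assignment, generic R path through the plug-in registry.  Training
# failures fall back to majority-class predictions with a warning.
.cv_counts_r <- function(X, y, assignment, classifiers, scale) {
  fold <- assignment$fold_of_sample
  counts <- matrix(0L, length(classifiers), 4L,
                   dimnames = list(classifiers, c("TP", "FN", "FP", "TN")))
  for (f in seq_len(assignment$k)) {
    te <- fold == f
    if (!any(te)) next
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    ytr <- y[!te]
    yte <- y[te]
    if (scale) {
      mu <- colMeans(Xtr)
      sd <- apply(Xtr, 2, stats::sd)
      sd[sd == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sd, "/")
    }
    for (ci in seq_along(classifiers)) {
      entry <- get_classifier(classifiers[ci])
      pred <- tryCatch({
        model <- entry$train(Xtr, ytr)
        as.integer(entry$predict(model, Xte))
      }, error = function(e) {
        warning(sprintf(
          "classifier '%s' failed on fold %d (%s); using majority class",
          classifiers[ci], f, conditionMessage(e)), call. = FALSE)
        rep(if (sum(ytr == 1L) > sum(ytr == 0L)) 1L else 0L, sum(te))
      })
      counts[ci, 1L] <- counts[ci, 1L] + sum(yte == 1L & pred == 1L)
      counts[ci, 2L] <- counts[ci, 2L] + sum(yte == 1L & pred == 0L)
      counts[ci, 3L] <- counts[ci, 3L] + sum(yte == 0L & pred == 1L)
      counts[ci, 4L] <- counts[ci, 4L] + sum(yte == 0L & pred == 0L)
    }
  }
  counts
}

.cv_counts <- function(X, y, assignment, classifiers, scale, use_fast = TRUE) {
  if (use_fast && .all_builtin(classifiers)) {
    counts <- .cv_counts_cpp(X, as.integer(y),
                             as.integer(assignment$fold_of_sample),
                             assignment$k, classifiers, scale)
    dimnames(counts) <- list(classifiers, c("TP", "FN", "FP", "TN"))
    counts
  } else {
    .cv_counts_r(X, y, assignment, classifiers, scale)
  }
}

#' Cross-validated performance of a feature subset
#'
#' For each seed a stratified fold assignment is drawn and shared by all
#' classifiers; each classifier is trained on `k - 1` folds restricted to
#' `subset` and predicts the held-out fold.  Confusion counts are pooled
#' over the folds of a run (so run-level `Acc` is exactly
#' `(sum TP + sum TN) / m`), run-level metrics are averaged over seeds, and
#' `mAcc` is the maximum of the seed-averaged accuracies over the
#' classifier set.
#'
#' @param ds an `ExpressionDataset`.
#' @param subset integer vector of feature indices (non-empty, in range).
#' @param k folds per run (default 10).
#' @param seeds integer seeds, one run each (default `0:19`, the full
#'   report protocol; the search phase inside [rifs()] uses a single seed).
#' @param classifiers character vector of registered classifier names.
#' @param scale if `TRUE`, features are z-scaled with means/sds fitted on
#'   the training folds only (no leakage); default `FALSE` (features used
#'   as-is).
#' @param fold_assignments optional precomputed list of
#'   [stratified_kfold()] objects, one per seed (must match `seeds`).
#' @param use_fast internal: set `FALSE` to force the generic R path even
#'   for built-in classifiers.
#' @return An object of class `PerformanceReport`: list with
#'   `per_classifier` (data frame of seed-averaged `Sn`, `Sp`, `Acc`,
#'   `Precision`, `Fscore`), `mAcc`, `best_classifier`, `n_runs`,
#'   `n_folds`, and `counts` (array run x classifier x TP/FN/FP/TN).
#' @export
evaluate_subset <- function(ds, subset, k = 10L, seeds = 0:19,
                            classifiers = default_classifiers(),
                            scale = FALSE, fold_assignments = NULL,
                            use_fast = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  subset <- as.integer(subset)
  n <- nrow(ds$matrix)
  if (length(subset) == 0L || anyNA(subset) || any(subset < 1L | subset > n))
    rifs_stop("rifs_subset_error", "subset must be non-empty and within range")
  if (length(classifiers) == 0L)
    rifs_stop("rifs_classifier_error", "classifier set must be non-empty")

  if (is.null(fold_assignments)) {
    fold_assignments <- lapply(seeds, function(s)
      stratified_kfold(ds$y, k, s))
  }
  stopifnot(length(fold_assignments) == length(seeds))

  X <- t(ds$matrix[subset, , drop = FALSE])
  nruns <- length(seeds)
  counts <- array(0L, dim = c(nruns, length(classifiers), 4L),
                  dimnames = list(NULL, classifiers,
                                  c("TP", "FN", "FP", "TN")))
  metrics <- array(0, dim = c(nruns, length(classifiers), 5L),
                   dimnames = list(NULL, classifiers,
                                   c("Sn", "Sp", "Acc", "Precision",
                                     "Fscore")))
  for (r in seq_len(nruns)) {
    cnt <- .cv_counts(X, ds$y, fold_assignments[[r]], classifiers, scale,
                      use_fast)
    counts[r, , ] <- cnt
    for (ci in seq_along(classifiers))
      metrics[r, ci, ] <- compute_metrics(cnt[ci, ])
  }

  avg <- apply(metrics, c(2L, 3L), mean)
  if (length(classifiers) == 1L) {
    avg <- matrix(avg, nrow = 1L,
                  dimnames = list(classifiers,
                                  c("Sn", "Sp", "Acc", "Precision",
                                    "Fscore")))
  }
  best <- which.max(avg[, "Acc"])  # first classifier wins accuracy ties
  per_classifier <- data.frame(classifier = classifiers, avg,
                               row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_classifier = per_classifier,
                 mAcc = unname(avg[best, "Acc"]),
                 best_classifier = classifiers[best],
                 n_runs = nruns, n_folds = as.integer(k),
                 counts = counts),
            class = "PerformanceReport")
}

#' @export
print.PerformanceReport <- function(x, ...) {
  cat(sprintf("PerformanceReport: mAcc = %.4f (%s), %d x %d-fold CV\n",
              x$mAcc, x$best_classifier, x$n_runs, x$n_folds))
  print(x$per_classifier, digits = 4)
  invisible(x)
}

# Lean search-phase evaluator: returns a closure subset -> mAcc, reusing
# precomputed fold assignments and skipping report bookkeeping.  This is the
# hot path of the incremental search (thousands of calls per run).
.make_search_evaluator <- function(ds, k, seeds, classifiers, scale) {
  assignments <- lapply(seeds, function(s) stratified_kfold(ds$y, k, s))
  folds <- lapply(assignments, function(a) as.integer(a$fold_of_sample))
  y <- as.integer(ds$y)
  m <- length(y)
  mat <- ds$matrix
  nclf <- length(classifiers)
  fast <- .all_builtin(classifiers)
  function(subset) {
    X <- t(mat[subset, , drop = FALSE])
    acc <- numeric(nclf)
    for (r in seq_along(folds)) {
      cnt <- if (fast) {
        .cv_counts_cpp(X, y, folds[[r]], assignments[[r]]$k, classifiers,
                       scale)
      } else {
        .cv_counts_r(X, y, assignments[[r]], classifiers, scale)
      }
      acc <- acc + (cnt[, 1L] + cnt[, 4L]) / m
    }
    max(acc) / length(folds)
  }
}
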