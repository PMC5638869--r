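.FILTER_METHODS <- c(Trank = "ttest", FPR = "anova_fpr", Wrank = "wilcoxon")

#' Same-size filter baselines for a RIFS result
#'
#' The comparison design for filters: if the incremental search selected
#' `k` features, each filter contributes its top-`k` features, evaluated
#' under the identical protocol (same folds, seeds and classifier set as
#' the RIFS final report) so that only the feature subset differs between
#' rows.
#'
#' @param ds the `ExpressionDataset` the result was computed on.
#' @param rifs_result an [rifs()] result.
#' @param methods filter names among `"Trank"` (t-test), `"FPR"` (ANOVA-F)
#'   and `"Wrank"` (Wilcoxon rank-sum).
#' @return A data frame with one row per method plus a `RIFS` row:
#'   `method`, `n_features`, `mAcc`, `Fscore` (F-score of the classifier
#'   achieving `mAcc`).
#' @export
compare_filters <- function(ds, rifs_result,
                            methods = c("Trank", "FPR", "Wrank")) {
  stopifnot(inherits(rifs_result, "RIFSResult"))
  methods <- match.arg(methods, names(.FILTER_METHODS), several.ok = TRUE)
  k <- length(rifs_result$selected_features)
  stopifnot(k >= 1L)
  cfg <- rifs_result$config

  row_of <- function(name, report) {
    best <- report$per_classifier[
      report$per_classifier$classifier == report$best_classifier, ]
    data.frame(method = name, n_features = k, mAcc = report$mAcc,
               Fscore = best$Fscore, stringsAsFactors = FALSE)
  }

  rows <- list(row_of("RIFS", rifs_result$final_report))
  for (mth in methods) {
    ranked <- rank_features(ds, .FILTER_METHODS[[mth]])
    top_k <- ranked$order[seq_len(k)]
    report <- evaluate_subset(ds, top_k, k = cfg$folds,
                              seeds = cfg$report_seeds,
                              classifiers = cfg$classifiers,
                              scale = cfg$scale)
    rows[[length(rows) + 1L]] <- row_of(mth, report)
  }
  do.call(rbind, rows)
}

#' Lasso wrapper baseline (off-the-shelf adapter)
#'
#' Thin adapter around [glmnet::glmnet()] at a fixed penalty
#' (`lambda = 0.1`, mirroring the Lasso alpha used in published
#' comparisons): the features with non-zero coefficients are returned.
#' Wrappers are external fits, not part of the incremental search, and are
#' excluded from the core test surface.
#'
#' @param ds an `ExpressionDataset`.
#' @param lambda penalty (default 0.1).
#' @return Integer vector of selected feature indices (possibly empty).
#' @export
select_lasso <- function(ds, lambda = 0.1) {
  if (!requireNamespace("glmnet", quietly = TRUE))
    rifs_stop("rifs_dependency_error", "select_lasso needs the glmnet package")
  fit <- glmnet::glmnet(t(ds$matrix), factor(ds$y), family = "binomial",
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(fit$beta)
  which(beta != 0)
}
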