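#' Rank features by single-feature association with the class label
#'
#' Produces the ordering consumed by the incremental search: features sorted
#' ascending by two-sided p-value of a univariate two-group test, ties broken
#' by original feature index (stable, so results are identical across runs
#' and platforms).
#'
#' Methods:
#' \describe{
#'   \item{`ttest`}{Student's two-sample t-test with pooled variance
#'     (equal variances assumed), `df = P + N - 2`.  This preserves the
#'     two-group identity `F = t^2` used as a cross-method oracle.}
#'   \item{`wilcoxon`}{Wilcoxon rank-sum test (exact when both groups are
#'     small and tie-free, normal approximation with continuity correction
#'     otherwise).}
#'   \item{`anova_fpr`}{one-way two-group ANOVA F-test; at a fixed subset
#'     size this is the "false positive rate" filter, which reduces to
#'     p-value ordering.}
#' }
#'
#' Features that are constant across all samples carry no signal and are
#' assigned p-value 1 (ranked last) rather than erroring: constant probes
#' are routine post-filter artifacts and the ranking must stay total.  A
#' feature with zero pooled variance but unequal class means is perfectly
#' separating and gets p-value 0.
#'
#' @param ds an [expression_dataset()].
#' @param method one of `"ttest"`, `"wilcoxon"`, `"anova_fpr"`.
#' @return An object of class `RankedFeatures`: list with `order` (a
#'   permutation of feature indices, rank 1 first), `pvalues` (aligned to
#'   the *original* feature indices), `method`, and `feature_ids`.
#' @export
#' @examples
#' ds <- expression_dataset(matrix(rnorm(40), 4, 10),
#'                          rep(c("a", "b"), each = 5), positive_label = "a")
#' rank_features(ds)$order
rank_features <- function(ds, method = c("ttest", "wilcoxon", "anova_fpr")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  method <- match.arg(method)
  pos <- ds$y == 1L
  P <- ds$P
  N <- ds$N
  if (method %in% c("ttest", "anova_fpr") && (P < 2L || N < 2L))
    rifs_stop("rifs_insufficient_samples_error", sprintf(
      "%s ranking needs >= 2 samples per class (have P=%d, N=%d)",
      method, P, N))

  X <- ds$matrix
  p <- unname(switch(method,
    ttest = .pvalues_pooled_t(X, pos)$p,
    anova_fpr = .pvalues_anova_f(X, pos),
    wilcoxon = .pvalues_wilcoxon(X, pos)))

  ord <- order(p, seq_along(p))  # stable: index breaks p-value ties
  structure(list(order = as.integer(ord), pvalues = p, method = method,
                 feature_ids = ds$feature_ids),
            class = "RankedFeatures")
}

# pooled-variance two-sample t; returns t statistics and two-sided p-values
.pvalues_pooled_t <- function(X, pos) {
  P <- sum(pos)
  N <- sum(!pos)
  df <- P + N - 2L
  mp <- rowMeans(X[, pos, drop = FALSE])
  mn <- rowMeans(X[, !pos, drop = FALSE])
  ssp <- rowSums((X[, pos, drop = FALSE] - mp)^2)
  ssn <- rowSums((X[, !pos, drop = FALSE] - mn)^2)
  sp2 <- (ssp + ssn) / df
  se <- sqrt(sp2 * (1 / P + 1 / N))
  tt <- (mp - mn) / se
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se == 0
  if (any(zero)) {
    # no within-class variance: constant feature -> no signal (p = 1),
    # distinct class constants -> perfect separation (p = 0)
    p[zero] <- ifelse(mp[zero] == mn[zero], 1, 0)
    tt[zero] <- ifelse(mp[zero] == mn[zero], 0, Inf * sign(mp - mn)[zero])
  }
  list(t = tt, p = p)
}

.pvalues_anova_f <- function(X, pos) {
  res <- .pvalues_pooled_t(X, pos)
  P <- sum(pos)
  N <- sum(!pos)
  f <- res$t^2
  p <- stats::pf(f, 1, P + N - 2L, lower.tail = FALSE)
  p[!is.finite(f)] <- 0
  p[res$p == 1] <- 1  # constant features stay least significant
  p
}

.pvalues_wilcoxon <- function(X, pos) {
  apply(X, 1L, function(x) {
    if (all(x == x[1L])) return(1)
    pv <- suppressWarnings(
      stats::wilcox.test(x[pos], x[!pos], alternative = "two.sided")$p.value)
    if (!is.finite(pv)) 1 else min(pv, 1)
  })
}

#' @export
print.RankedFeatures <- function(x, ...) {
  k <- min(5L, length(x$order))
  top <- x$order[seq_len(k)]
  cat(sprintf("RankedFeatures (%s): %d features; top %d: %s\n", x$method,
              length(x$order), k,
              paste(sprintf("%s (p=%.3g)", x$feature_ids[top],
                            x$pvalues[top]), collapse = ", ")))
  invisible(x)
}

#' Export a full ranking as TSV
#'
#' Columns: `feature_id`, `rank`, `p_value`, `method`.
#'
#' @param ranked a `RankedFeatures` object.
#' @param path output path.
#' @return Invisibly, the written data frame.
#' @export
write_ranking <- function(ranked, path) {
  stopifnot(inherits(ranked, "RankedFeatures"))
  df <- data.frame(feature_id = ranked$feature_ids[ranked$order],
                   rank = seq_along(ranked$order),
                   p_value = ranked$pvalues[ranked$order],
                   method = ranked$method)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
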