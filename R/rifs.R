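#' RIFS configuration
#'
#' Defaults mirror the published protocol: 45% of the feature count as the
#' start budget, stopping depth 4, master seed 0, one round of 10-fold
#' cross-validation during the search and 20 random rounds for the final
#' report.
#'
#' @param pStartingPercentage fraction in `(0, 1]` of the total feature
#'   number used as the number of random start ranks (default 0.45).
#' @param pStoppingDepth tolerated number of consecutive accuracy
#'   decreases `D` (default 4).
#' @param master_seed integer seed for the start-rank draw (default 0).
#' @param max_subset_size safety cap on prefix length (default 100;
#'   published selections never exceeded 27 features).
#' @param folds folds per cross-validation run (default 10).
#' @param search_seeds seeds for the search-phase evaluator (default `0`:
#'   one round of k-fold CV).
#' @param report_seeds seeds for the final report (default `0:19`).
#' @param classifiers classifier names for `mAcc` (default all five
#'   built-ins).
#' @param scale z-scale features inside training folds (default `FALSE`).
#' @param restart_patience optional early exit: stop launching new starts
#'   after this many consecutive starts without improvement of the best
#'   accuracy (default `NULL`: the full start budget is always used).
#' @return A list of class `RIFSConfig`.
#' @export
rifs_config <- function(pStartingPercentage = 0.45, pStoppingDepth = 4L,
                        master_seed = 0L, max_subset_size = 100L,
                        folds = 10L, search_seeds = 0L, report_seeds = 0:19,
                        classifiers = default_classifiers(), scale = FALSE,
                        restart_patience = NULL) {
  stopifnot(is.numeric(pStartingPercentage), length(pStartingPercentage) == 1L,
            pStartingPercentage > 0, pStartingPercentage <= 1,
            is_count(pStoppingDepth), is_count(max_subset_size),
            is_count(folds), folds >= 2, length(search_seeds) >= 1L,
            length(report_seeds) >= 1L, length(classifiers) >= 1L)
  if (!is.null(restart_patience)) stopifnot(is_count(restart_patience))
  structure(list(pStartingPercentage = pStartingPercentage,
                 pStoppingDepth = as.integer(pStoppingDepth),
                 master_seed = as.integer(master_seed),
                 max_subset_size = as.integer(max_subset_size),
                 folds = as.integer(folds),
                 search_seeds = as.integer(search_seeds),
                 report_seeds = as.integer(report_seeds),
                 classifiers = classifiers,
                 scale = isTRUE(scale),
                 restart_patience = restart_patience),
            class = "RIFSConfig")
}

#' Draw the random start ranks
#'
#' Returns `ceiling(pct * n)` distinct ranks.  Rank 1 is always included,
#' so the search provably dominates classical IFS from the top rank; the
#' remaining ranks are the first entries of one seeded permutation of
#' `2..n`.  Truncating a single permutation makes start sets *nested*
#' across budgets under the same seed, which in turn makes the search
#' accuracy monotone in `pStartingPercentage`.
#'
#' @param n_features total feature count.
#' @param pStartingPercentage fraction in `(0, 1]`.
#' @param master_seed integer seed.
#' @return Integer vector of distinct ranks (rank 1 first).
#' @export
sample_start_ranks <- function(n_features, pStartingPercentage,
                               master_seed = 0L) {
  stopifnot(is_count(n_features), pStartingPercentage > 0,
            pStartingPercentage <= 1)
  n <- as.integer(n_features)
  b <- as.integer(ceiling(pStartingPercentage * n))
  if (n == 1L || b == 1L) return(1L)
  perm <- local_seed(master_seed, sample(2:n))
  c(1L, perm[seq_len(b - 1L)])
}

# trace comparator implementing the preference "higher accuracy, then fewer
# features, then smaller start rank"
.trace_better <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$best_accuracy != b$best_accuracy)
    return(a$best_accuracy > b$best_accuracy)
  if (a$best_prefix_len != b$best_prefix_len)
    return(a$best_prefix_len < b$best_prefix_len)
  a$start_rank < b$start_rank
}

#' Randomly re-started incremental feature selection
#'
#' Ranks all features by the t-test filter, runs [sifs()] from every
#' sampled start rank with the (cheap) search-phase evaluator, keeps the
#' trace with maximal best accuracy -- ties broken by fewer features, then
#' smaller start rank -- and re-evaluates the winning subset with the full
#' report protocol.
#'
#' @param ds an `ExpressionDataset`.
#' @param cfg a [rifs_config()].
#' @return An object of class `RIFSResult`: list with `selected_features`
#'   (original feature indices, in order of addition), `winning_start_rank`,
#'   `winning_trace`, `all_start_ranks`, `search_mAcc`, `final_report`
#'   (a `PerformanceReport`), `ranking`, `traces`, `n_evaluations`, `config`.
#' @export
#' @examples
#' \donttest{
#' gen <- generate_dataset(synthetic_spec(n_features = 60, m_pos = 15,
#'                                        m_neg = 15, seed = 1))
#' res <- rifs(gen$dataset, rifs_config(pStartingPercentage = 0.1,
#'                                      report_seeds = 0:4))
#' res$final_report$mAcc
#' }
rifs <- function(ds, cfg = rifs_config()) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(cfg, "RIFSConfig"))
  if (min(ds$P, ds$N) < cfg$folds)
    rifs_stop("rifs_stratification_error", sprintf(
      "smallest class (%d) is below the fold count (%d)",
      min(ds$P, ds$N), cfg$folds))

  ranked <- rank_features(ds, "ttest")
  n <- length(ranked$order)
  starts <- sample_start_ranks(n, cfg$pStartingPercentage, cfg$master_seed)

  eval_mAcc <- .make_search_evaluator(ds, cfg$folds, cfg$search_seeds,
                                      cfg$classifiers, cfg$scale)
  n_eval <- 0L
  counting_eval <- function(subset) {
    n_eval <<- n_eval + 1L
    eval_mAcc(subset)
  }

  traces <- vector("list", length(starts))
  best <- NULL
  since_improvement <- 0L
  used <- 0L
  for (i in seq_along(starts)) {
    tr <- sifs(ranked, starts[i], cfg$pStoppingDepth, counting_eval,
               cap = cfg$max_subset_size)
    traces[[i]] <- tr
    used <- i
    improved <- is.null(best) || tr$best_accuracy > best$best_accuracy
    if (.trace_better(tr, best)) best <- tr
    since_improvement <- if (improved) 0L else since_improvement + 1L
    if (!is.null(cfg$restart_patience) && i > 1L &&
        since_improvement >= cfg$restart_patience) break
  }
  traces <- traces[seq_len(used)]

  sel_ranks <- best$start_rank:(best$start_rank + best$best_prefix_len - 1L)
  selected <- ranked$order[sel_ranks]
  final_report <- evaluate_subset(ds, selected, k = cfg$folds,
                                  seeds = cfg$report_seeds,
                                  classifiers = cfg$classifiers,
                                  scale = cfg$scale)
  structure(list(selected_features = selected,
                 winning_start_rank = best$start_rank,
                 winning_trace = best,
                 all_start_ranks = starts[seq_len(used)],
                 search_mAcc = best$best_accuracy,
                 final_report = final_report,
                 ranking = ranked,
                 traces = traces,
                 n_evaluations = n_eval,
                 config = cfg),
            class = "RIFSResult")
}

#' @export
print.RIFSResult <- function(x, ...) {
  cat(sprintf(
    paste0("RIFSResult: %d feature(s) from start rank %d ",
           "(search mAcc %.4f, report mAcc %.4f)\n"),
    length(x$selected_features), x$winning_start_rank, x$search_mAcc,
    x$final_report$mAcc))
  cat("features:",
      paste(x$ranking$feature_ids[x$selected_features], collapse = ", "),
      "\n")
  invisible(x)
}

#' Sensitivity of the selected subset to the master seed
#'
#' Runs [rifs()] once per master seed and tabulates the winning start rank,
#' subset size and report `mAcc`, grouping rows that selected the identical
#' feature subset.
#'
#' @param ds an `ExpressionDataset`.
#' @param cfg a [rifs_config()]; its `master_seed` is overridden per row.
#' @param seeds integer vector of master seeds.
#' @return A data frame with columns `seed`, `winning_start_rank`,
#'   `n_features`, `mAcc`, `subset_group` (identical subsets share a group
#'   id) and `features` (comma-separated ids).
#' @export
seed_sweep <- function(ds, cfg = rifs_config(), seeds = 0:20) {
  stopifnot(length(seeds) >= 1L)
  rows <- lapply(seeds, function(s) {
    cfg_s <- cfg
    cfg_s$master_seed <- as.integer(s)
    res <- rifs(ds, cfg_s)
    list(seed = as.integer(s),
         winning_start_rank = res$winning_start_rank,
         n_features = length(res$selected_features),
         mAcc = res$final_report$mAcc,
         features = paste(
           res$ranking$feature_ids[res$selected_features], collapse = ","))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$subset_group <- as.integer(factor(df$features,
                                       levels = unique(df$features)))
  df[, c("seed", "winning_start_rank", "n_features", "mAcc",
         "subset_group", "features")]
}
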