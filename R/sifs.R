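#' Incremental feature selection from one start rank: sIFS(k, D)
#'
#' Starting at `start_rank` in the ranking order, the prefixes
#' `{f_k}`, `{f_k, f_(k+1)}`, ... are scored in turn.  A counter of
#' consecutive accuracy decreases is maintained: step `t` is a decrease iff
#' its accuracy is *strictly* below that of step `t - 1` (a plateau resets
#' the counter -- treating plateaus as decreases would stop on exactly the
#' flat stretches worth crossing).  The search stops when the counter
#' reaches `depth`, when the rank list is exhausted, or when the prefix
#' reaches `cap` features; the best prefix ever seen (first occurrence of
#' the maximum) is returned.
#'
#' @param ranked a `RankedFeatures` object or an integer permutation of
#'   feature indices (rank order).
#' @param start_rank first rank of the window, in `1..n`.
#' @param depth `D >= 1`, the tolerated number of consecutive decreases.
#' @param eval_fn `function(subset)` returning the accuracy (e.g. `mAcc`)
#'   of a non-empty integer vector of original feature indices.
#' @param cap maximum prefix length (safety bound, default 100).
#' @return An object of class `SifsTrace`: list with `start_rank`, `depth`,
#'   `step_accuracies` (one per prefix length), `best_prefix_len`,
#'   `best_accuracy`, `stopped_reason` (`"depth_exhausted"`,
#'   `"rank_exhausted"` or `"cap_reached"`).
#' @export
#' @examples
#' accs <- c(0.80, 0.90, 0.88, 0.87, 0.86, 0.85)
#' tr <- sifs(1:10, start_rank = 1, depth = 4,
#'            eval_fn = function(s) accs[length(s)])
#' tr$best_prefix_len  # 2
sifs <- function(ranked, start_rank, depth, eval_fn, cap = 100L) {
  ord <- if (inherits(ranked, "RankedFeatures")) ranked$order
         else as.integer(ranked)
  n <- length(ord)
  stopifnot(is_count(depth), is.function(eval_fn), is_count(cap))
  if (!is_count(start_rank) || start_rank > n)
    rifs_stop("rifs_start_rank_error", sprintf(
      "start_rank must be in 1..%d (got %s)", n, format(start_rank)))
  start_rank <- as.integer(start_rank)

  max_len <- min(as.integer(cap), n - start_rank + 1L)
  accs <- numeric(max_len)
  dec <- 0L
  len <- 0L
  stopped <- NULL
  while (len < max_len) {
    len <- len + 1L
    subset <- ord[start_rank:(start_rank + len - 1L)]
    a <- eval_fn(subset)
    if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
      rifs_stop("rifs_eval_error", sprintf(
        "eval_fn returned a non-finite accuracy at start %d, length %d",
        start_rank, len))
    accs[len] <- a
    if (len > 1L) dec <- if (a < accs[len - 1L]) dec + 1L else 0L
    if (dec >= depth) {
      stopped <- "depth_exhausted"
      break
    }
  }
  if (is.null(stopped))
    stopped <- if (max_len == n - start_rank + 1L) "rank_exhausted"
               else "cap_reached"
  accs <- accs[seq_len(len)]
  best <- which.max(accs)  # first occurrence: shortest best prefix
  structure(list(start_rank = start_rank, depth = as.integer(depth),
                 step_accuracies = accs,
                 best_prefix_len = as.integer(best),
                 best_accuracy = accs[best],
                 stopped_reason = stopped),
            class = "SifsTrace")
}

#' @export
print.SifsTrace <- function(x, ...) {
  cat(sprintf(
    "SifsTrace: start %d, depth %d; %d steps (%s); best %.4f at length %d\n",
    x$start_rank, x$depth, length(x$step_accuracies), x$stopped_reason,
    x$best_accuracy, x$best_prefix_len))
  invisible(x)
}
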