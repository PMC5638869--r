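#' Describe one planted synergy pair
#'
#' A synergy pair is two features that are individually near-null under a
#' univariate test yet jointly linearly separable -- the phenomenon that
#' motivates random re-starts.  The construction rotates a separated 2-D
#' configuration: a low-variance "signal" axis `u` (class-free noise, sd
#' `pair_separation / 10`) and a high-variance nuisance axis `v` are mixed
#' by `pair_angle`, and each member's realised class-mean difference is
#' then set *exactly* so its pooled t-statistic equals the value whose
#' p-value sits at the `target_rank_zone` quantile of the (uniform)
#' background p-value distribution.  Because both members get exactly the
#' same |t|, they occupy adjacent ranks.  The difference direction recovers
#' `u`, where the classes are separated by about `pair_separation` against
#' sd `pair_separation / 10` -- a ~10-sigma margin, linearly separable.
#'
#' @param target_rank_zone quantile in `(0, 1)` of the background p-value
#'   distribution where the pair's marginal p-values should land
#'   (default 0.1: weak but not last).
#' @param pair_angle rotation angle in degrees (default 45, maximal
#'   marginal camouflage).
#' @param pair_separation joint class separation along the recovered
#'   low-variance direction (default 4).
#' @return A list of class `synergy_pair_spec`.
#' @export
synergy_pair <- function(target_rank_zone = 0.1, pair_angle = 45,
                         pair_separation = 4) {
  stopifnot(target_rank_zone > 0, target_rank_zone < 1,
            pair_angle > 0, pair_angle < 90, pair_separation > 0)
  structure(list(target_rank_zone = target_rank_zone,
                 pair_angle = pair_angle,
                 pair_separation = pair_separation),
            class = "synergy_pair_spec")
}

#' Specification of a synthetic two-class expression dataset
#'
#' Emulates a normalised transcriptome matrix in the "large p, small n"
#' regime: background features are standard Gaussian in both classes,
#' `n_strong` features carry a marginal class-mean shift `delta_strong`,
#' and each [synergy_pair()] plants a marginally weak but jointly
#' discriminative feature pair.  Signal features occupy the first rows
#' (strong features first, then pair members in consecutive rows); see
#' `ground_truth` in [generate_dataset()].
#'
#' @param n_features total feature count (default 2000).
#' @param m_pos,m_neg positive / negative sample counts (default 30 each).
#' @param n_strong number of marginally strong features (default 3).
#' @param delta_strong class-mean shift of strong features, in units of
#'   `noise_sd` = 1 (default 3: unambiguous top ranks at these sample
#'   sizes).
#' @param synergy_pairs list of [synergy_pair()] specs (default: one pair).
#' @param noise_sd background standard deviation (default 1, as for
#'   z-scored expression).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return A list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_features = 2000L, m_pos = 30L, m_neg = 30L,
                           n_strong = 3L, delta_strong = 3,
                           synergy_pairs = list(synergy_pair()),
                           noise_sd = 1, seed = 0L) {
  stopifnot(is_count(n_features), is_count(m_pos), is_count(m_neg),
            is.numeric(n_strong), n_strong >= 0, n_strong == floor(n_strong),
            is.numeric(delta_strong), noise_sd > 0, is.list(synergy_pairs))
  for (p in synergy_pairs) stopifnot(inherits(p, "synergy_pair_spec"))
  if (n_strong + 2L * length(synergy_pairs) > n_features)
    rifs_stop("rifs_spec_error",
              "n_strong + 2 * number of pairs exceeds n_features")
  structure(list(n_features = as.integer(n_features),
                 m_pos = as.integer(m_pos), m_neg = as.integer(m_neg),
                 n_strong = as.integer(n_strong),
                 delta_strong = delta_strong,
                 synergy_pairs = synergy_pairs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{`dataset`}{an `ExpressionDataset` (labels `case`/`control`,
#'       positive class `case`).}
#'     \item{`ground_truth`}{list with `strong` (feature indices) and
#'       `pairs` (list of index pairs).}
#'     \item{`calibration`}{data frame per pair: target t statistic, axis
#'       sds, enforced mean shifts, realised joint margin.}
#'   }
#' @export
#' @examples
#' gen <- generate_dataset(synthetic_spec(n_features = 100, seed = 1))
#' gen$ground_truth$pairs
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$n_features
  P <- spec$m_pos
  N <- spec$m_neg
  m <- P + N
  pos <- c(rep(TRUE, P), rep(FALSE, N))
  npairs <- length(spec$synergy_pairs)
  if (npairs > 0L && (P < 2L || N < 2L))
    rifs_stop("rifs_calibration_error",
              "synergy calibration needs >= 2 samples per class")

  calib <- list()
  X <- local_seed(spec$seed, {
    X <- matrix(stats::rnorm(n * m, 0, spec$noise_sd), n, m)
    if (spec$n_strong > 0L)
      X[seq_len(spec$n_strong), pos] <-
        X[seq_len(spec$n_strong), pos, drop = FALSE] + spec$delta_strong

    df <- m - 2L
    se <- sqrt(1 / P + 1 / N)
    for (j in seq_len(npairs)) {
      ps <- spec$synergy_pairs[[j]]
      theta <- ps$pair_angle * pi / 180
      s <- ps$pair_separation
      t_target <- stats::qt(1 - ps$target_rank_zone / 2, df)
      sd_u <- s / 10
      sd_v <- s / ((sin(theta) + cos(theta)) * cos(theta) * t_target * se)
      if (!is.finite(sd_v) || sd_v <= 0)
        rifs_stop("rifs_calibration_error", sprintf(
          "target_rank_zone %.3g is unreachable (degenerate t target)",
          ps$target_rank_zone))

      u <- stats::rnorm(m, 0, sd_u)
      v <- stats::rnorm(m, 0, sd_v)
      x1 <- cos(theta) * v - sin(theta) * u
      x2 <- sin(theta) * v + cos(theta) * u

      # centre each member within class, then impose the exact class-mean
      # difference that pins the pooled t-statistic at +-t_target
      enforce <- function(x, delta_sign) {
        x[pos] <- x[pos] - mean(x[pos])
        x[!pos] <- x[!pos] - mean(x[!pos])
        s_pooled <- sqrt((sum(x[pos]^2) + sum(x[!pos]^2)) / df)
        delta <- t_target * se * s_pooled
        x[pos] <- x[pos] + delta_sign * delta / 2
        x[!pos] <- x[!pos] - delta_sign * delta / 2
        list(x = x, delta = delta)
      }
      e1 <- enforce(x1, -1)  # opposite signs: the difference carries the
      e2 <- enforce(x2, +1)  # joint separation, each margin stays weak
      margin <- sin(theta) * e1$delta + cos(theta) * e2$delta
      if (margin < 6 * sd_u)
        rifs_stop("rifs_calibration_error", sprintf(
          "target_rank_zone %.3g is unreachable: joint margin %.3g < 6 sd_u",
          ps$target_rank_zone, margin))

      r1 <- spec$n_strong + 2L * j - 1L
      X[r1, ] <- e1$x
      X[r1 + 1L, ] <- e2$x
      calib[[j]] <- data.frame(pair = j, t_target = t_target, sd_u = sd_u,
                               sd_v = sd_v, delta1 = e1$delta,
                               delta2 = e2$delta, margin = margin)
    }
    X
  })

  ids <- character(n)
  ids[] <- sprintf("bg%04d", seq_len(n))
  if (spec$n_strong > 0L)
    ids[seq_len(spec$n_strong)] <- sprintf("strong%d", seq_len(spec$n_strong))
  pairs <- vector("list", npairs)
  for (j in seq_len(npairs)) {
    r1 <- spec$n_strong + 2L * j - 1L
    ids[c(r1, r1 + 1L)] <- sprintf("pair%d%s", j, c("a", "b"))
    pairs[[j]] <- c(r1, r1 + 1L)
  }

  ds <- expression_dataset(
    X, ifelse(pos, "case", "control"), positive_label = "case",
    feature_ids = ids, sample_ids = sprintf("s%03d", seq_len(m)))
  list(dataset = ds,
       ground_truth = list(strong = seq_len(spec$n_strong), pairs = pairs),
       calibration = if (npairs) do.call(rbind, calib) else NULL)
}
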