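# Shared fixtures and independent reference implementations (oracles).
# Oracles are deliberately written from first principles, not by calling
# the package code they check.

# small two-class dataset with optional planted mean-shift features
toy_dataset <- function(n = 20, m_pos = 10, m_neg = 10, shift_idx = integer(),
                        shift = 2, seed = 42) {
  m <- m_pos + m_neg
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  X <- withr_seed({
    X <- matrix(rnorm(n * m), n, m)
    if (length(shift_idx))
      X[shift_idx, seq_len(m_pos)] <- X[shift_idx, seq_len(m_pos)] + shift
    X
  })
  expression_dataset(X, rep(c("case", "ctrl"), c(m_pos, m_neg)),
                     positive_label = "case")
}

# two well-separated Gaussian clouds (means +-5, sd 0.1): any sane
# classifier is perfect
separable_dataset <- function(n = 5, m_pos = 10, m_neg = 10, seed = 1) {
  m <- m_pos + m_neg
  set.seed(seed)
  X <- matrix(rnorm(n * m, sd = 0.1), n, m)
  X[, seq_len(m_pos)] <- X[, seq_len(m_pos)] + 5
  X[, m_pos + seq_len(m_neg)] <- X[, m_pos + seq_len(m_neg)] - 5
  expression_dataset(X, rep(c("case", "ctrl"), c(m_pos, m_neg)),
                     positive_label = "case")
}

# direct-formula pooled-variance two-sample t-test p-value (oracle)
oracle_t_pvalue <- function(x, pos) {
  xp <- x[pos]; xn <- x[!pos]
  P <- length(xp); N <- length(xn)
  sp <- sqrt(((P - 1) * var(xp) + (N - 1) * var(xn)) / (P + N - 2))
  t <- (mean(xp) - mean(xn)) / (sp * sqrt(1 / P + 1 / N))
  2 * pt(-abs(t), P + N - 2)
}

# direct-formula one-way two-group ANOVA F p-value (oracle)
oracle_f_pvalue <- function(x, pos) {
  xp <- x[pos]; xn <- x[!pos]
  P <- length(xp); N <- length(xn)
  gm <- mean(x)
  msb <- (P * (mean(xp) - gm)^2 + N * (mean(xn) - gm)^2) / 1
  msw <- (sum((xp - mean(xp))^2) + sum((xn - mean(xn))^2)) / (P + N - 2)
  pf(msb / msw, 1, P + N - 2, lower.tail = FALSE)
}

# reference simulator of the stopping rule: returns the number of
# evaluations consumed and the best prefix (first argmax) for a given
# accuracy sequence and tolerance D
oracle_stop <- function(accs, D) {
  dec <- 0L; used <- 0L
  for (i in seq_along(accs)) {
    used <- i
    if (i > 1L) dec <- if (accs[i] < accs[i - 1L]) dec + 1L else 0L
    if (dec >= D) break
  }
  seen <- accs[seq_len(used)]
  list(n_eval = used, best_len = which.max(seen), best_acc = max(seen))
}

# mocked evaluator: accuracy depends only on prefix length
mock_eval <- function(accs) {
  function(subset) accs[length(subset)]
}

write_toy_csv <- function(dir, ds, delimiter = ",") {
  mp <- file.path(dir, "matrix.csv")
  lp <- file.path(dir, "labels.csv")
  write_dataset(ds, mp, lp, delimiter = delimiter)
  list(matrix = mp, labels = lp)
}
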