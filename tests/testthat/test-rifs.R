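test_that("start-rank sampling: cardinality, forced rank 1, nesting", {
  s <- sample_start_ranks(100, 0.45, master_seed = 0)
  expect_length(s, 45L)
  expect_length(unique(s), 45L)
  expect_true(all(s %in% 1:100))
  expect_true(1L %in% s)

  # pct = 1 covers every rank
  expect_setequal(sample_start_ranks(30, 1, 5), 1:30)

  # nested across budgets under the same seed
  small <- sample_start_ranks(200, 0.10, master_seed = 7)
  big <- sample_start_ranks(200, 0.35, master_seed = 7)
  expect_true(all(small %in% big))
  expect_identical(big[seq_along(small)], small)

  # distinct seeds give distinct sets with ~45% pairwise overlap
  # (hypergeometric expectation at pct = 0.45)
  a <- sample_start_ranks(10000, 0.45, 1)
  b <- sample_start_ranks(10000, 0.45, 2)
  expect_false(setequal(a, b))
  overlap <- length(intersect(a, b)) / length(a)
  expect_gt(overlap, 0.40)
  expect_lt(overlap, 0.50)
})

test_that("start set forced to {1} with depth 1 reproduces classical IFS(1,1)", {
  ds <- toy_dataset(n = 40, m_pos = 10, m_neg = 10, shift_idx = 1:3,
                    shift = 1.5, seed = 31)
  cfg <- rifs_config(pStartingPercentage = 1e-9,  # ceil -> a single start
                     pStoppingDepth = 1, folds = 5, report_seeds = 0:4)
  res <- rifs(ds, cfg)
  expect_identical(res$all_start_ranks, 1L)
  expect_identical(res$winning_start_rank, 1L)

  ev <- rifs:::.make_search_evaluator(ds, cfg$folds, cfg$search_seeds,
                                      cfg$classifiers, cfg$scale)
  classical <- sifs(res$ranking, 1, 1, ev, cap = cfg$max_subset_size)
  expect_equal(res$winning_trace$step_accuracies,
               classical$step_accuracies)
  expect_identical(res$selected_features,
                   res$ranking$order[seq_len(classical$best_prefix_len)])
})

test_that("rifs equals an independent brute-force loop over the start set", {
  ds <- toy_dataset(n = 30, m_pos = 8, m_neg = 8, shift_idx = 1:2, seed = 17)
  cfg <- rifs_config(pStartingPercentage = 0.3, pStoppingDepth = 2,
                     folds = 4, report_seeds = 0:2)
  res <- rifs(ds, cfg)

  # oracle: fresh evaluator, fresh sifs per start, explicit tie-breaks
  ranked <- rank_features(ds, "ttest")
  ev <- rifs:::.make_search_evaluator(ds, cfg$folds, cfg$search_seeds,
                                      cfg$classifiers, cfg$scale)
  starts <- sample_start_ranks(30, 0.3, cfg$master_seed)
  best <- NULL
  for (k in starts) {
    tr <- sifs(ranked, k, cfg$pStoppingDepth, ev, cap = cfg$max_subset_size)
    if (is.null(best) ||
        tr$best_accuracy > best$best_accuracy ||
        (tr$best_accuracy == best$best_accuracy &&
         (tr$best_prefix_len < best$best_prefix_len ||
          (tr$best_prefix_len == best$best_prefix_len &&
           tr$start_rank < best$start_rank)))) best <- tr
  }
  expect_equal(res$search_mAcc, best$best_accuracy)
  expect_identical(res$winning_start_rank, best$start_rank)
  expect_identical(res$selected_features,
                   ranked$order[best$start_rank:(best$start_rank +
                                                 best$best_prefix_len - 1L)])
})

test_that("selected features are consecutive ranks and runs are bit-identical", {
  gen <- generate_dataset(synthetic_spec(n_features = 150, m_pos = 12,
                                         m_neg = 12, n_strong = 1,
                                         synergy_pairs = list(), seed = 5))
  cfg <- rifs_config(pStartingPercentage = 0.1, folds = 4,
                     report_seeds = 0:3)
  r1 <- rifs(gen$dataset, cfg)
  r2 <- rifs(gen$dataset, cfg)
  expect_identical(r1, r2)

  ranks <- match(r1$selected_features, r1$ranking$order)
  expect_identical(ranks,
                   seq(r1$winning_start_rank, by = 1L,
                       length.out = length(ranks)))
})

test_that("search accuracy is monotone in the start budget (nested sampling)", {
  ds <- toy_dataset(n = 60, m_pos = 8, m_neg = 8, shift_idx = 1:2, seed = 23)
  cfg <- function(pct) rifs_config(pStartingPercentage = pct,
                                   pStoppingDepth = 2, folds = 4,
                                   report_seeds = 0L, master_seed = 3)
  maccs <- sapply(c(0.05, 0.2, 0.5), function(p)
    rifs(ds, cfg(p))$search_mAcc)
  expect_true(!is.unsorted(maccs))
})

test_that("restart patience shortens the start list but keeps determinism", {
  ds <- toy_dataset(n = 50, m_pos = 8, m_neg = 8, shift_idx = 1, seed = 29)
  base <- rifs_config(pStartingPercentage = 0.5, pStoppingDepth = 2,
                      folds = 4, report_seeds = 0L)
  patient <- base
  patient$restart_patience <- 3L
  full <- rifs(ds, base)
  cut <- rifs(ds, patient)
  expect_lte(length(cut$all_start_ranks), length(full$all_start_ranks))
  expect_identical(cut$all_start_ranks,
                   full$all_start_ranks[seq_along(cut$all_start_ranks)])
  expect_identical(rifs(ds, patient), cut)
})

test_that("seed_sweep groups identical subsets and is seed-exhaustive at pct 1", {
  ds <- toy_dataset(n = 25, m_pos = 8, m_neg = 8, shift_idx = 1, seed = 41)
  cfg <- rifs_config(pStartingPercentage = 1, pStoppingDepth = 1,
                     folds = 4, report_seeds = 0:1)
  sw <- seed_sweep(ds, cfg, seeds = 0:2)
  expect_identical(nrow(sw), 3L)
  # pct = 1: the start set is seed-independent, so all rows coincide
  expect_identical(unique(sw$subset_group), 1L)
  expect_identical(sw$mAcc[1], sw$mAcc[3])

  # same seed twice: identical rows
  sw2 <- seed_sweep(ds, cfg, seeds = c(0L, 0L))
  expect_equal(sw2[1, -1], sw2[2, -1], ignore_attr = TRUE)
})
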