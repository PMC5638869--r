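test_that("stratified folds balance both classes to within one sample", {
  # P = N = 10, k = 10: every fold exactly 1 + 1
  y <- rep(c(1, 0), each = 10)
  fa <- stratified_kfold(y, 10, seed = 4)
  tab <- table(fa$fold_of_sample, y)
  expect_true(all(tab == 1))

  # P = 7, N = 5, k = 5: positive sizes a permutation of (2,2,1,1,1)
  y <- rep(c(1, 0), c(7, 5))
  fa <- stratified_kfold(y, 5, seed = 0)
  pos_sizes <- as.vector(table(fa$fold_of_sample[y == 1]))
  expect_identical(sort(pos_sizes), c(1L, 1L, 1L, 2L, 2L))
  expect_true(all(table(fa$fold_of_sample[y == 0]) == 1))

  # deterministic in (labels, k, seed)
  expect_identical(stratified_kfold(y, 5, seed = 123),
                   stratified_kfold(y, 5, seed = 123))
  expect_false(identical(stratified_kfold(y, 5, seed = 1)$fold_of_sample,
                         stratified_kfold(y, 5, seed = 2)$fold_of_sample))

  expect_error(stratified_kfold(rep(c(1, 0), c(3, 20)), 5),
               class = "rifs_stratification_error")
})

test_that("compute_metrics reproduces the defining formulas", {
  expect_equal(compute_metrics(c(TP = 5, FN = 0, FP = 0, TN = 5)),
               c(Sn = 1, Sp = 1, Acc = 1, Precision = 1, Fscore = 1))
  got <- compute_metrics(c(TP = 3, FN = 1, FP = 2, TN = 4))
  expect_equal(got, c(Sn = 0.75, Sp = 4 / 6, Acc = 0.7, Precision = 0.6,
                      Fscore = 2 * (0.6 * 0.75) / (0.6 + 0.75)))
  # degenerate: nothing predicted positive
  got0 <- compute_metrics(c(TP = 0, FN = 4, FP = 0, TN = 6))
  expect_equal(unname(got0[c("Sn", "Precision", "Fscore")]), c(0, 0, 0))
})

test_that("separable data is classified perfectly by every classifier", {
  ds <- separable_dataset()
  rep <- evaluate_subset(ds, 1:5, k = 5, seeds = 0:1)
  expect_equal(rep$mAcc, 1)
  expect_true(all(rep$per_classifier$Acc == 1))
})

test_that("mAcc semantics: singleton sets, monotonicity in the classifier set", {
  ds <- toy_dataset(n = 10, m_pos = 10, m_neg = 10, shift_idx = 1,
                    shift = 1.2, seed = 21)
  full <- evaluate_subset(ds, 1:3, k = 5, seeds = 0:2)
  accs <- setNames(full$per_classifier$Acc, full$per_classifier$classifier)
  expect_equal(full$mAcc, max(accs))
  for (clf in default_classifiers()) {
    single <- evaluate_subset(ds, 1:3, k = 5, seeds = 0:2, classifiers = clf)
    expect_equal(single$mAcc, unname(accs[clf]))
  }
  # adding classifiers never lowers mAcc
  grow <- Reduce(function(prev, clf) {
    set <- c(prev$set, clf)
    macc <- evaluate_subset(ds, 1:3, k = 5, seeds = 0:2,
                            classifiers = set)$mAcc
    expect_gte(macc, prev$mAcc)
    list(set = set, mAcc = macc)
  }, default_classifiers()[-1],
  init = list(set = default_classifiers()[1],
              mAcc = evaluate_subset(ds, 1:3, k = 5, seeds = 0:2,
                                     classifiers = default_classifiers()[1])$mAcc))
  expect_equal(grow$mAcc, full$mAcc)
})

test_that("run-level accuracy equals pooled counts over folds exactly", {
  ds <- toy_dataset(n = 12, m_pos = 12, m_neg = 8, shift_idx = 1, seed = 8)
  rep <- evaluate_subset(ds, c(1, 5, 7), k = 4, seeds = 0:3)
  m <- ncol(ds$matrix)
  for (r in seq_len(rep$n_runs)) {
    cnt <- rep$counts[r, , ]
    expect_true(all(cnt[, "TP"] + cnt[, "FN"] == ds$P))
    expect_true(all(cnt[, "FP"] + cnt[, "TN"] == ds$N))
  }
  # seed-averaged Acc per classifier equals mean of pooled-count accuracies
  acc_manual <- apply(rep$counts, 2, function(cc)
    mean((cc[, "TP"] + cc[, "TN"]) / m))
  expect_equal(rep$per_classifier$Acc, unname(acc_manual))
})

test_that("evaluation is reproducible and leave-one-out is seed-invariant", {
  ds <- toy_dataset(n = 8, m_pos = 6, m_neg = 6, shift_idx = 1, seed = 10)
  a <- evaluate_subset(ds, 1:4, k = 4, seeds = 0:4)
  b <- evaluate_subset(ds, 1:4, k = 4, seeds = 0:4)
  expect_identical(a, b)

  m <- ncol(ds$matrix)
  loo1 <- evaluate_subset(ds, 1:4, k = m, seeds = 17)
  loo2 <- evaluate_subset(ds, 1:4, k = m, seeds = 4242)
  expect_equal(loo1$per_classifier, loo2$per_classifier)
})

test_that("generic registry path agrees with the compiled fast path", {
  ds <- toy_dataset(n = 15, m_pos = 8, m_neg = 8, shift_idx = 1:2, seed = 13)
  fast <- evaluate_subset(ds, c(1, 2, 9), k = 4, seeds = 0:1)
  slow <- evaluate_subset(ds, c(1, 2, 9), k = 4, seeds = 0:1,
                          use_fast = FALSE)
  expect_equal(fast$per_classifier, slow$per_classifier)
  expect_identical(fast$counts, slow$counts)
})

test_that("null data stays near chance for every classifier", {
  # spec-scale null check: no signal, balanced m = 200, five seeds of data
  # x four CV runs; seed-averaged accuracies concentrate near 0.5
  accs <- sapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(10 * 200), 10, 200)
    ds <- expression_dataset(X, rep(c("a", "b"), 100), positive_label = "a")
    evaluate_subset(ds, 1:10, k = 10, seeds = 0:3)$per_classifier$Acc
  })
  expect_true(all(rowMeans(accs) > 0.40 & rowMeans(accs) < 0.60))
})

test_that("a failing plug-in classifier falls back to majority predictions", {
  register_classifier("broken",
                      train = function(X, y) stop("boom"),
                      predict = function(model, X) integer(nrow(X)))
  on.exit(rm("broken", envir = rifs:::.rifs_registry))
  ds <- toy_dataset(n = 5, m_pos = 8, m_neg = 4, seed = 2)
  w <- capture_warnings(
    rep <- evaluate_subset(ds, 1:2, k = 4, seeds = 0, classifiers = "broken"))
  expect_gte(length(w), 1L)
  expect_true(all(grepl("majority", w)))
  # majority class is positive (8 vs 4) on every training fold
  expect_equal(rep$per_classifier$Sn, 1)
  expect_equal(rep$per_classifier$Sp, 0)
})

test_that("custom classifiers participate in mAcc like built-ins", {
  # a nearest-centroid plug-in written against the train/predict contract
  register_classifier(
    "centroid",
    train = function(X, y) list(c1 = colMeans(X[y == 1, , drop = FALSE]),
                                c0 = colMeans(X[y == 0, , drop = FALSE])),
    predict = function(model, X) {
      d1 <- rowSums(sweep(X, 2, model$c1)^2)
      d0 <- rowSums(sweep(X, 2, model$c0)^2)
      as.integer(d1 < d0)
    })
  on.exit(rm("centroid", envir = rifs:::.rifs_registry))
  ds <- separable_dataset()
  rep <- evaluate_subset(ds, 1:5, k = 5, seeds = 0,
                         classifiers = c("LR", "centroid"))
  expect_equal(rep$mAcc, 1)
  expect_equal(nrow(rep$per_classifier), 2L)
})
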