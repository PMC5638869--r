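test_that("load_dataset ingests a toy CSV and honours orientation", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1.5, 2, 3, 4, 5, 6, 7, 8, 9.25, 10, 11, 12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ds0 <- expression_dataset(X, c("tumor", "tumor", "normal", "normal"),
                            positive_label = "tumor")
  paths <- write_toy_csv(dir, ds0)

  ds <- load_dataset(paths$matrix, paths$labels, positive_label = "tumor")
  expect_s3_class(ds, "ExpressionDataset")
  expect_identical(dim(ds), c(3L, 4L))
  expect_identical(ds$P, 2L)
  expect_identical(ds$N, 2L)
  expect_identical(ds$matrix, X)

  # transpose on disk + samples_as_rows gives the identical dataset
  tp <- file.path(dir, "t.csv")
  tdf <- data.frame(sample_id = colnames(X), t(X), check.names = FALSE)
  write.table(tdf, tp, sep = ",", row.names = FALSE, quote = FALSE)
  ds_t <- load_dataset(tp, paths$labels, positive_label = "tumor",
                       orientation = "samples_as_rows")
  expect_identical(ds_t$matrix, ds$matrix)
  expect_identical(ds_t$y, ds$y)
})

test_that("write then load round-trips values at full precision", {
  dir <- withr::local_tempdir()
  ds0 <- toy_dataset(n = 8, m_pos = 4, m_neg = 4, seed = 9)
  paths <- write_toy_csv(dir, ds0)
  ds1 <- load_dataset(paths$matrix, paths$labels, positive_label = "case")
  expect_identical(ds1$matrix, ds0$matrix)
  expect_identical(ds1$feature_ids, ds0$feature_ids)
  expect_identical(ds1$sample_ids, ds0$sample_ids)
})

test_that("label and alignment violations raise typed errors", {
  dir <- withr::local_tempdir()
  ds0 <- toy_dataset(n = 3, m_pos = 3, m_neg = 3)
  paths <- write_toy_csv(dir, ds0)

  # three distinct labels
  bad <- file.path(dir, "bad_labels.csv")
  write.table(data.frame(sample_id = ds0$sample_ids,
                         label = c("a", "a", "b", "b", "c", "c")),
              bad, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(paths$matrix, bad, positive_label = "a"),
               class = "rifs_label_error")

  # sample-id mismatch
  mis <- file.path(dir, "mis_labels.csv")
  write.table(data.frame(sample_id = paste0("zz", 1:6),
                         label = rep(c("a", "b"), 3)),
              mis, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(paths$matrix, mis, positive_label = "a"),
               class = "rifs_alignment_error")

  # positive label must name an observed value, never guessed
  expect_error(load_dataset(paths$matrix, paths$labels,
                            positive_label = "nope"),
               class = "rifs_label_error")
  expect_error(expression_dataset(ds0$matrix, dataset_labels(ds0)),
               class = "rifs_label_error")
})

test_that("drop_missing_features applies the exclusion rule and is idempotent", {
  X <- matrix(rnorm(20), 5, 4)
  X[2, 3] <- NA
  ds <- expression_dataset(X, c("a", "a", "b", "b"), positive_label = "a",
                           allow_missing = TRUE)
  expect_message(clean <- drop_missing_features(ds), "excluding 1 feature")
  expect_identical(nrow(clean$matrix), 4L)
  expect_identical(ncol(clean$matrix), 4L)      # samples unchanged
  expect_false(anyNA(clean$matrix))
  expect_identical(drop_missing_features(clean), clean)  # idempotent

  # no missing cells: identity
  ok <- toy_dataset(n = 4, m_pos = 2, m_neg = 2)
  expect_identical(drop_missing_features(ok), ok)

  # everything missing: empty-dataset error
  Xall <- matrix(NA_real_, 10, 4)
  Xall[, 1] <- c(1:9, NA)
  dsall <- expression_dataset(Xall, c("a", "a", "b", "b"),
                              positive_label = "a", allow_missing = TRUE)
  expect_error(drop_missing_features(dsall),
               class = "rifs_empty_dataset_error")
})

test_that("missing-value spellings are recognised at load time", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.csv")
  writeLines(c("feature_id,s1,s2,s3,s4",
               "g1,1,2,3,4",
               "g2,1,,3,4",
               "g3,1,2,NaN,4",
               "g4,1,2,3,na"), mp)
  lp <- file.path(dir, "l.csv")
  write.table(data.frame(sample_id = paste0("s", 1:4),
                         label = c("a", "a", "b", "b")),
              lp, sep = ",", row.names = FALSE, quote = FALSE)
  expect_message(ds <- load_dataset(mp, lp, positive_label = "a"),
                 "excluding 3")
  expect_identical(ds$feature_ids, "g1")
})
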