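# Cosine-distance NNA, metrics, jackknife and the IFS loop.

test_that("cosine distance matches hand computations", {
  expect_equal(nna_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nna_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(nna_distance(c(1, 1), 5 * c(1, -1)), 1)
  expect_equal(nna_distance(c(1, 1), c(-1, -1)), 2)
  expect_equal(nna_distance(c(2, 0), c(7, 0)), 0)  # scale invariance
})

test_that("cosine distance rejects zero norms and dimension mismatches", {
  expect_error(nna_distance(c(0, 0), c(1, 2)), "zero-norm")
  expect_error(nna_distance(1:2, 1:3), "equal dimension")
})

test_that("cosine distance equals 1 - cos(angle) on random 2-D vectors", {
  for (seed in 1:20) {
    uv <- withr::with_seed(seed, matrix(rnorm(4), 2))
    ang <- abs(atan2(uv[2, 1], uv[1, 1]) - atan2(uv[2, 2], uv[1, 2]))
    expect_equal(nna_distance(uv[, 1], uv[, 2]), 1 - cos(ang), tolerance = 1e-12)
    expect_equal(nna_distance(uv[, 1], uv[, 2]), nna_distance(uv[, 2], uv[, 1]))
  }
})

test_that("NNA prediction returns the nearest training label", {
  fm <- random_fm(n = 10, p = 4, seed = 3)
  # a query equal to a training sample predicts that sample's class
  p <- nna_predict(fm$values[4, ], fm)
  expect_equal(p$label, as.character(fm$labels[4]))
  expect_equal(p$nn_index, 4L)
  expect_equal(p$distance, 0, tolerance = 1e-12)
  # a single-sample training set always returns that label
  one <- feature_matrix(fm$values[1, , drop = FALSE], fm$descriptors,
                        fm$labels[1])
  expect_equal(nna_predict(rnorm(4) + 3, one)$label, as.character(fm$labels[1]))
  expect_error(nna_predict(rnorm(3), fm), "dimension mismatch")
})

test_that("NNA prediction matches the exhaustive minimum-distance scan", {
  for (seed in 1:10) {
    fm <- random_fm(n = 10, p = 5, seed = seed)
    q <- withr::with_seed(seed + 500, rnorm(5, mean = 3))
    expect_equal(nna_predict(q, fm)$label,
                 oracle_nn_scan(q, fm$values, fm$labels))
  }
})

test_that("evaluation metrics follow the confusion-count formulas", {
  perfect <- compute_metrics(list(TP = 10, FP = 0, TN = 20, FN = 0))
  expect_equal(unlist(perfect[, c("Sn", "Sp", "AC", "MCC")]),
               c(Sn = 1, Sp = 1, AC = 1, MCC = 1))
  anti <- compute_metrics(list(TP = 0, FP = 20, TN = 0, FN = 10))
  expect_equal(anti$MCC, -1)
  mixed <- compute_metrics(list(TP = 8, FP = 4, TN = 16, FN = 2))
  expect_equal(mixed$Sn, 0.8)
  expect_equal(mixed$Sp, 0.8)
  expect_equal(mixed$AC, 24 / 30)
  expect_equal(mixed$MCC, (8 * 16 - 4 * 2) / sqrt(12 * 10 * 20 * 18))
  # degenerate margin: no predicted positives -> MCC defined as 0
  expect_message(deg <- compute_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)),
                 "MCC set to 0")
  expect_equal(deg$MCC, 0)
})

test_that("|MCC| = 1 only for diagonal or anti-diagonal confusion matrices", {
  for (seed in 1:20) {
    cts <- withr::with_seed(seed, as.list(stats::setNames(sample(0:6, 4, TRUE),
                                                          c("TP", "FP", "TN", "FN"))))
    if (sum(unlist(cts)) == 0) next
    m <- suppressMessages(compute_metrics(cts))
    diag_like <- cts$FP == 0 && cts$FN == 0 && cts$TP > 0 && cts$TN > 0
    anti_like <- cts$TP == 0 && cts$TN == 0 && cts$FP > 0 && cts$FN > 0
    expect_equal(abs(m$MCC) == 1, diag_like || anti_like, info = paste(cts))
  }
})

test_that("jackknife handles duplicate and separated classes as expected", {
  desc <- tibble::tibble(column = 1:2, position = 1L, kind = "pssm",
                         sub_id = c("A", "C"), name = c("f1", "f2"))
  # exact duplicates per class force each sample's nearest neighbour right
  X <- rbind(c(1, 2), c(1, 2), c(5, 1), c(5, 1))
  fm <- feature_matrix(X, desc, factor(c("positive", "positive", "negative",
                                         "negative"),
                                       levels = c("positive", "negative")))
  expect_equal(jackknife_nna(fm)$AC, 1)
  # angularly separated clusters: perfect metrics
  X2 <- rbind(c(1, 0.1), c(2, 0.3), c(0.1, 1), c(0.2, 3))
  fm2 <- feature_matrix(X2, desc, fm$labels)
  m <- jackknife_nna(fm2)
  expect_equal(m$AC, 1)
  expect_equal(m$MCC, 1)
})

test_that("jackknife equals an independently coded leave-one-out loop", {
  for (seed in 1:5) {
    fm <- random_fm(n = 20, p = 6, seed = seed + 40)
    got <- jackknife_nna(fm)
    want <- suppressMessages(compute_metrics(oracle_loocv(fm$values, fm$labels)))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("jackknife is permutation-equivariant", {
  fm <- random_fm(n = 25, p = 5, seed = 77)
  perm <- withr::with_seed(8, sample(25))
  fm2 <- feature_matrix(fm$values[perm, ], fm$descriptors, fm$labels[perm])
  expect_equal(jackknife_nna(fm), jackknife_nna(fm2))
})

test_that("IFS evaluates nested prefixes and picks the accuracy peak", {
  g <- generate_synthetic(synthetic_spec(seed = 12))
  w <- build_dataset(g$records, "P", 2, seed = 12)
  fm <- encode_windows(w, g$aaindex)
  ranked <- rank_mrmr(fm, 15)
  ifs <- run_ifs(fm, ranked)
  expect_equal(nrow(ifs$per_k), 15L)
  expect_equal(ifs$per_k$k, 1:15)
  expect_equal(ifs$optimal_metrics$AC, max(ifs$per_k$AC))
  # smallest k attaining the max
  expect_equal(ifs$optimal_k, min(ifs$per_k$k[ifs$per_k$AC == max(ifs$per_k$AC)]))
  expect_gt(ifs$optimal_metrics$AC, 0.9)  # planted signal is recoverable
  # max_k = 1 degenerate case
  one <- run_ifs(fm, ranked, max_k = 1)
  expect_equal(nrow(one$per_k), 1L)
  expect_equal(one$optimal_k, 1L)
})

test_that("IFS at the full feature list equals a single jackknife", {
  fm <- random_fm(n = 15, p = 6, seed = 9)
  ifs <- run_ifs(fm, seq_len(6))
  expect_equal(ifs$per_k[6, -1], jackknife_nna(fm))
})

test_that("tidy, glance and autoplot expose the IFS fit", {
  fm <- random_fm(n = 12, p = 4, seed = 2)
  ifs <- run_ifs(fm, 1:4)
  td <- tidy(ifs)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("k", "TP", "FP", "TN", "FN", "Sn", "Sp", "AC", "MCC"))
  gl <- glance(ifs)
  expect_equal(gl$optimal_k, ifs$optimal_k)
  expect_s3_class(autoplot(ifs), "ggplot")
})

test_that("IFS curves round-trip through TSV", {
  fm <- random_fm(n = 12, p = 4, seed = 3)
  ifs <- run_ifs(fm, 1:4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ifs_curve(ifs, path)
  back <- read_ifs_curve(path)
  expect_equal(back$AC, ifs$per_k$AC)
  expect_equal(back$k, ifs$per_k$k)
})
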