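# Discretization, mutual information and the MaxRel / mRMR rankings.

test_that("three-state discretization uses mean +/- k*sd thresholds", {
  x <- c(-10, 0, 10)
  # mean 0, sample sd 10: k = 1 puts the thresholds exactly at -10/+10 and
  # threshold values take the outer states
  D <- discretize_features(matrix(x), k_sigma = 1)
  expect_equal(D[, 1], c(1L, 2L, 3L))
  # widening the band pulls everything into the middle state
  Dw <- discretize_features(matrix(x), k_sigma = 1.5)
  expect_equal(Dw[, 1], c(2L, 2L, 2L))
})

test_that("constant columns map to the middle state", {
  D <- discretize_features(matrix(5, 10, 2))
  expect_true(all(D == 2L))
})

test_that("discretization is invariant under shifting a feature", {
  x <- withr::with_seed(1, rnorm(50))
  expect_equal(discretize_features(matrix(x)),
               discretize_features(matrix(x + 100)))
})

test_that("mutual information matches hand cases", {
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)  # 1 bit
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)  # independent
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("mutual information equals the brute-force plug-in sum", {
  for (seed in 1:25) {
    xy <- withr::with_seed(seed, list(x = sample(1:3, 40, TRUE),
                                      y = sample(1:2, 40, TRUE)))
    expect_equal(mutual_information(xy$x, xy$y), oracle_mi(xy$x, xy$y),
                 tolerance = 1e-12)
  }
})

test_that("MI(x,x) is the entropy of x and MI is symmetric and non-negative", {
  for (seed in 1:10) {
    xy <- withr::with_seed(seed, list(x = sample(1:3, 60, TRUE),
                                      y = sample(1:3, 60, TRUE)))
    px <- table(xy$x) / 60
    expect_equal(mutual_information(xy$x, xy$x), -sum(px * log2(px)))
    expect_equal(mutual_information(xy$x, xy$y),
                 mutual_information(xy$y, xy$x), tolerance = 1e-12)
    expect_gte(mutual_information(xy$x, xy$y), 0)
  }
})

planted_fm <- function(seed = 1, n = 60, p = 8) {
  withr::with_seed(seed, {
    labels <- factor(rep(c("positive", "negative"), length.out = n),
                     levels = c("positive", "negative"))
    X <- matrix(rnorm(n * p), n, p)
    X[, 3] <- ifelse(labels == "positive", 5, -5) + rnorm(n, sd = 0.1)
    desc <- tibble::tibble(column = seq_len(p), position = 1L, kind = "pssm",
                           sub_id = LETTERS[seq_len(p)],
                           name = paste0("f", seq_len(p)))
    feature_matrix(X, desc, labels)
  })
}

test_that("MaxRel ranks a perfectly separating feature first", {
  fm <- planted_fm()
  r <- rank_maxrel(fm, 8)
  expect_equal(r$column[1], 3L)
  expect_true(all(diff(r$score) <= 1e-12))  # descending scores
})

test_that("MaxRel ranking is invariant under row shuffling", {
  fm <- planted_fm(seed = 2)
  perm <- withr::with_seed(7, sample(nrow(fm$values)))
  fm2 <- feature_matrix(fm$values[perm, ], fm$descriptors, fm$labels[perm])
  expect_equal(rank_maxrel(fm, 8)$column, rank_maxrel(fm2, 8)$column)
})

test_that("mRMR demotes a duplicated informative feature below an independent one", {
  fm <- withr::with_seed(3, {
    n <- 200
    labels <- factor(rep(c("positive", "negative"), length.out = n),
                     levels = c("positive", "negative"))
    strong <- ifelse(labels == "positive", 4, -4) + rnorm(n, sd = 0.5)
    weaker <- ifelse(labels == "positive", 1.2, -1.2) + rnorm(n)
    X <- cbind(strong, strong + rnorm(n, sd = 0.05), weaker)
    desc <- tibble::tibble(column = 1:3, position = 1L, kind = "pssm",
                           sub_id = c("A", "C", "D"),
                           name = c("dup1", "dup2", "indep"))
    feature_matrix(X, desc, labels)
  })
  r <- rank_mrmr(fm, 3)
  expect_true(r$column[1] %in% c(1L, 2L))  # one duplicate tops the list
  expect_equal(r$column[2], 3L)            # independent beats the other copy
  expect_true(r$column[3] %in% c(1L, 2L))
  # MaxRel, with no redundancy penalty, keeps the duplicates adjacent
  expect_equal(sort(rank_maxrel(fm, 2)$column), c(1L, 2L))
})

test_that("mRMR and MaxRel always agree on the first selected feature", {
  for (seed in 1:8) {
    fm <- random_fm(n = 40, p = 7, seed = seed)
    expect_equal(rank_mrmr(fm, 1)$column, rank_maxrel(fm, 1)$column)
  }
})

test_that("greedy mRMR matches the brute-force greedy trace on small problems", {
  for (seed in 1:6) {
    fm <- random_fm(n = 50, p = 8, seed = seed + 100)
    D <- discretize_features(fm)
    for (scheme in c("difference", "quotient")) {
      got <- rank_mrmr(fm, 8, scheme = scheme)$column
      want <- oracle_mrmr_greedy(D, fm$labels, 8, scheme = scheme)
      expect_equal(got, want, info = paste("seed", seed, scheme))
    }
  }
})

test_that("top_n above the feature count truncates with a warning", {
  fm <- random_fm(n = 30, p = 5, seed = 1)
  expect_warning(r <- rank_mrmr(fm, 10), "truncating")
  expect_equal(nrow(r), 5L)
})

test_that("ranked lists round-trip through TSV", {
  fm <- planted_fm(seed = 4)
  r <- rank_mrmr(fm, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked(r, path)
  back <- read_ranked(path)
  expect_equal(back$column, r$column)
  expect_equal(back$score, r$score, tolerance = 1e-10)
  expect_equal(attr(back, "criterion"), attr(r, "criterion"))
})
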