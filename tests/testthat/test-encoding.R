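# Feature-space construction: descriptor enumeration, dimension law,
# value placement and the column <-> descriptor bijection.

test_that("the feature space dimension is 12(A+21)+21 for any A", {
  for (A in c(1, 3, 17, 506)) {
    d <- feature_descriptors(sprintf("IDX%03d", seq_len(A)))
    expect_equal(nrow(d), 12 * (A + 21) + 21)
  }
  # the benchmark constants: 506 usable indices -> 6,345 dimensions,
  # 527 per flanking position, 21 at the centre
  d506 <- feature_descriptors(sprintf("IDX%03d", 1:506))
  expect_equal(nrow(d506), 6345L)
  expect_equal(sum(d506$position == 1), 527L)
  expect_equal(sum(d506$position == 7), 21L)
  expect_false(any(d506$kind == "aaindex" & d506$position == 7))
})

test_that("descriptor order is position-major with aaindex->pssm->disorder", {
  d <- feature_descriptors(c("B2", "A1"))
  expect_equal(d$position, sort(d$position))
  expect_equal(d$kind[1:2], c("aaindex", "aaindex"))
  expect_equal(d$sub_id[1:2], c("A1", "B2"))  # accessions sorted
  expect_equal(d$kind[3], "pssm")
  expect_equal(d$name[1], "p01|aaindex|A1")
  expect_equal(d$name[nrow(d)], "p13|disorder|-")
})

test_that("describe_feature and locate_feature are mutually inverse", {
  d <- feature_descriptors(sprintf("TST%03d", 1:3))
  for (col in seq_len(nrow(d))) {
    row <- describe_feature(d, col)
    expect_equal(locate_feature(d, row$position, row$kind, row$sub_id), col)
  }
  expect_error(describe_feature(d, nrow(d) + 1), "out of range")
})

test_that("encoding places AAindex, PSSM and disorder values correctly", {
  tab <- mini_aaindex(3)
  rec <- toy_record("CDEFGHPIKLMNQ", positive_sites = 7)
  w <- extract_windows(rec, "P")
  fm <- encode_windows(w, tab)
  expect_equal(ncol(fm$values), 12 * 24 + 21)  # A = 3 -> 309
  d <- fm$descriptors
  # aaindex feature at position 1 = index value of the residue there (C)
  col <- locate_feature(d, 1, "aaindex", "TST001")
  expect_equal(unname(fm$values[1, col]), unname(tab$entries$TST001["C"]))
  # centre disorder column equals the centre disorder score
  col <- locate_feature(d, 7, "disorder", NA)
  expect_equal(unname(fm$values[1, col]), 0.25)
  # pssm columns carry the aligned PSSM rows (all 1 in the toy record)
  col <- locate_feature(d, 13, "pssm", "V")
  expect_equal(unname(fm$values[1, col]), 1)
})

test_that("padding placeholder encodes as index mean / zero PSSM / 0.5 disorder", {
  tab <- mini_aaindex(3)
  rec <- toy_record("AAPAAAAAAAAAA")  # left-padded window
  w <- extract_windows(rec, "P", "pad")
  fm <- encode_windows(w, tab)
  d <- fm$descriptors
  col <- locate_feature(d, 1, "aaindex", "TST002")
  expect_equal(unname(fm$values[1, col]), mean(tab$entries$TST002))
  col <- locate_feature(d, 1, "pssm", "A")
  expect_equal(unname(fm$values[1, col]), 0)
  col <- locate_feature(d, 1, "disorder", NA)
  expect_equal(unname(fm$values[1, col]), 0.5)
})

test_that("identical windows encode to identical vectors", {
  tab <- mini_aaindex(3)
  rec <- toy_record("AAAAAAPAAAAAAQQAAAAAAPAAAAAA")
  w <- extract_windows(rec, "P")
  fm <- encode_windows(w, tab)
  expect_equal(nrow(fm$values), 2L)
  expect_equal(fm$values[1, ], fm$values[2, ])
})

test_that("zero windows give an empty matrix with the full descriptor list", {
  tab <- mini_aaindex(3)
  fm <- encode_windows(empty_windows_for_test(), tab)
  expect_equal(nrow(fm$values), 0L)
  expect_equal(ncol(fm$values), 309L)
  expect_equal(nrow(fm$descriptors), 309L)
})

test_that("permuting window order permutes matrix rows identically", {
  g <- generate_synthetic(synthetic_spec(n_proteins = 4, seq_length = 60,
                                         n_positive_sites = 5, seed = 4))
  w <- build_dataset(g$records, "P", 2, seed = 4)
  perm <- withr::with_seed(9, sample(nrow(w)))
  fm1 <- encode_windows(w, g$aaindex)
  fm2 <- encode_windows(w[perm, ], g$aaindex)
  expect_equal(fm2$values, fm1$values[perm, ])
  expect_equal(fm2$labels, fm1$labels[perm])
})

test_that("feature matrices round-trip through TSV", {
  g <- generate_synthetic(synthetic_spec(n_proteins = 2, seq_length = 40,
                                         n_positive_sites = 3, seed = 5))
  w <- build_dataset(g$records, "P", 1, seed = 5)
  fm <- encode_windows(w, g$aaindex)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(unname(back$values), unname(fm$values))
  expect_equal(back$labels, fm$labels)
  expect_equal(back$descriptors$name, fm$descriptors$name)
  expect_equal(back$descriptors$sub_id, fm$descriptors$sub_id)
})
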