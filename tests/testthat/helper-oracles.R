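# Independent oracles and small fixture builders. Every oracle here is a
# deliberately slow, direct transcription of the definition it checks, with
# no code shared with the implementation under test.

# Plug-in mutual information (bits) by explicit summation over table cells.
oracle_mi_table <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        out <- out + pij * log2(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  out
}

oracle_mi <- function(x, y) oracle_mi_table(table(x, y))

# Step-by-step greedy mRMR, enumerating every candidate score each step.
oracle_mrmr_greedy <- function(D, y, top_n, scheme = "difference") {
  p <- ncol(D)
  rel <- vapply(seq_len(p), function(j) oracle_mi(D[, j], y), numeric(1))
  selected <- integer(0)
  for (step in seq_len(top_n)) {
    best <- NA_integer_; best_score <- -Inf
    for (j in setdiff(seq_len(p), selected)) {
      if (length(selected) == 0) {
        score <- rel[j]
      } else {
        red <- mean(vapply(selected, function(s) oracle_mi(D[, j], D[, s]),
                           numeric(1)))
        score <- if (scheme == "difference") rel[j] - red
                 else rel[j] / max(red, .Machine$double.eps)
      }
      if (score > best_score + 1e-12) { best <- j; best_score <- score }
    }
    selected <- c(selected, best)
  }
  selected
}

oracle_cosine_dist <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  1 - sum(u * v) / (nu * nv)
}

# Exhaustive nearest-neighbour scan; ties to the lowest training index.
oracle_nn_scan <- function(query, train_x, train_labels) {
  d <- apply(train_x, 1, function(r) oracle_cosine_dist(query, r))
  as.character(train_labels[which.min(d)])
}

# Slow leave-one-out loop over explicit train/test splits.
oracle_loocv <- function(X, labels) {
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    pred[i] <- oracle_nn_scan(X[i, ], X[-i, , drop = FALSE], labels[-i])
  }
  list(TP = sum(labels == "positive" & pred == "positive"),
       FP = sum(labels == "negative" & pred == "positive"),
       TN = sum(labels == "negative" & pred == "negative"),
       FN = sum(labels == "positive" & pred == "negative"))
}

# Random continuous feature matrix with both classes.
random_fm <- function(n = 20, p = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p, mean = 3), n, p)
    desc <- tibble::tibble(column = seq_len(p), position = 1L, kind = "pssm",
                           sub_id = LETTERS[seq_len(p)],
                           name = paste0("f", seq_len(p)))
    labels <- factor(sample(rep(c("positive", "negative"), length.out = n)),
                     levels = c("positive", "negative"))
    feature_matrix(X, desc, labels)
  })
}

# Miniature in-memory AAindex table (3 indices, deterministic values).
mini_aaindex <- function(n_idx = 3) {
  acc <- sprintf("TST%03d", seq_len(n_idx))
  entries <- stats::setNames(lapply(seq_len(n_idx), function(i) {
    stats::setNames(round(sin(seq_len(20) * i) * 2, 3),
                    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  }), acc)
  aaindex_table(entries)
}

empty_windows_for_test <- function() {
  tibble::tibble(protein_id = character(), center = integer(),
                 peptide = character(), label = character(),
                 pssm = list(), disorder = list())
}

# One-record protein tibble with constant tracks, for window tests.
toy_record <- function(sequence, positive_sites = integer()) {
  L <- nchar(sequence)
  protein_records(
    tibble::tibble(protein_id = "prot1", sequence = sequence),
    pssms = list(prot1 = pssm_profile(sequence, matrix(1L, L, 20))),
    disorders = list(prot1 = rep(0.25, L)),
    sites = if (length(positive_sites) > 0) {
      tibble::tibble(protein_id = "prot1", pos = as.integer(positive_sites),
                     residue = substring(sequence, positive_sites, positive_sites))
    } else NULL)
}
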