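# Window -> feature-vector encoding.
#
# Each of the 12 flanking positions contributes one value per AAindex index
# (A of them), 20 PSSM conservation scores and 1 disorder score (A + 21
# features); the centre residue is the same letter in every window, so it
# contributes only its 20 PSSM scores and 1 disorder score. Total dimension
# 12 * (A + 21) + 21; with the 506 usable AAindex indices that is 6,345.
#
# Canonical feature order is position-major (1..13); within a position,
# kinds run aaindex -> pssm -> disorder and sub-identifiers (index
# accessions, amino-acid column letters) sort lexicographically. The order
# carries through every ranked list and output header.

#' Enumerate the canonical feature descriptors
#'
#' @param accessions Character vector of usable AAindex accessions (length A).
#' @param window_length Odd window size, default 13.
#' @return A tibble with one row per feature column: `column` (1-based),
#'   `position` (1..window_length, centre = (window_length+1)/2), `kind`
#'   (`aaindex`/`pssm`/`disorder`), `sub_id` (accession, amino-acid letter,
#'   or `NA` for disorder) and `name` (`"p07|pssm|L"` style).
#' @export
feature_descriptors <- function(accessions, window_length = 13L) {
  window_length <- assert_scalar_count(window_length, "window_length")
  if (window_length %% 2L == 0L) stop_hx("`window_length` must be odd")
  accessions <- sort(as.character(accessions))
  center <- (window_length + 1L) %/% 2L
  per_pos <- purrr::map(seq_len(window_length), function(p) {
    kinds <- c(if (p != center) rep("aaindex", length(accessions)),
               rep("pssm", 20L), "disorder")
    subs <- c(if (p != center) accessions, AA_LETTERS, NA_character_)
    tibble::tibble(position = p, kind = kinds, sub_id = subs)
  })
  d <- dplyr::bind_rows(per_pos)
  d$column <- seq_len(nrow(d))
  d$name <- sprintf("p%02d|%s|%s", d$position, d$kind,
                    ifelse(is.na(d$sub_id), "-", d$sub_id))
  d[, c("column", "position", "kind", "sub_id", "name")]
}

#' Map a column number to its feature descriptor (and back)
#'
#' `describe_feature()` and `locate_feature()` are mutually inverse over the
#' whole descriptor set.
#'
#' @param descriptors A [feature_descriptors()] tibble.
#' @param column Column number(s).
#' @return `describe_feature()`: the descriptor row(s); `locate_feature()`:
#'   integer column number(s).
#' @export
describe_feature <- function(descriptors, column) {
  if (any(column < 1L | column > nrow(descriptors))) {
    stop_hx("feature column out of range 1..", nrow(descriptors))
  }
  descriptors[column, ]
}

#' @rdname describe_feature
#' @param position,kind,sub_id Descriptor fields (`sub_id = NA` for disorder).
#' @export
locate_feature <- function(descriptors, position, kind, sub_id = NA) {
  hit <- descriptors$position == position & descriptors$kind == kind &
    (is.na(sub_id) & is.na(descriptors$sub_id) |
       !is.na(descriptors$sub_id) & descriptors$sub_id %in% sub_id)
  if (sum(hit) != 1L) stop_hx("descriptor does not identify exactly one column")
  descriptors$column[hit]
}

#' Encode labelled windows as a named feature matrix
#'
#' Applies the AAindex/PSSM/disorder coding to every window. The placeholder
#' residue `X` (terminus padding) takes each index's mean over the 20
#' residues; its PSSM row is zeros and its disorder score 0.5. No feature
#' scaling is applied (`standardize = TRUE` is available; the cosine
#' nearest-neighbour distance is scale-sensitive across features, and the
#' unscaled encoding is the method's stated form).
#'
#' @param windows A window tibble from [extract_windows()] /
#'   [build_dataset()].
#' @param table An `aaindex_table`.
#' @param window_length Odd window size, default 13.
#' @param standardize Centre/scale each feature column (default `FALSE`).
#' @return A `feature_matrix`: list with `values` (samples x features
#'   numeric matrix, named columns), `descriptors`, `labels` (factor
#'   positive/negative), `sample_id`, `aaindex` (the table used).
#' @export
encode_windows <- function(windows, table, window_length = 13L,
                           standardize = FALSE) {
  desc <- feature_descriptors(names(table$entries), window_length)
  n <- nrow(windows)
  X <- matrix(NA_real_, n, nrow(desc), dimnames = list(NULL, desc$name))
  if (n > 0L) {
    if (any(nchar(windows$peptide) != window_length)) {
      stop_hx("all peptides must have exactly ", window_length, " residues")
    }
    res <- do.call(rbind, strsplit(windows$peptide, "", fixed = TRUE))
    # AAindex lookup incl. placeholder row: 21 x A
    acc <- sort(names(table$entries))
    aa_tab <- vapply(acc, function(a) {
      v <- table$entries[[a]]
      c(v[AA_LETTERS], X = mean(v))
    }, numeric(21L))
    rownames(aa_tab) <- c(AA_LETTERS, PAD_RESIDUE)
    unknown <- setdiff(unique(as.vector(res)), rownames(aa_tab))
    if (length(unknown) > 0L) {
      # non-standard letters (B, Z, U, ...) are treated like the placeholder
      res[res %in% unknown] <- PAD_RESIDUE
    }
    pssm_arr <- windows$pssm
    dis_arr <- windows$disorder
    center <- (window_length + 1L) %/% 2L
    for (p in seq_len(window_length)) {
      cols <- desc$column[desc$position == p]
      pssm_rows <- t(vapply(pssm_arr, function(m) m[p, ], numeric(20L)))
      colnames(pssm_rows) <- PSSM_ALPHABET
      pssm_rows <- pssm_rows[, AA_LETTERS, drop = FALSE]
      dis <- vapply(dis_arr, function(d) d[p], numeric(1L))
      block <- if (p == center) cbind(pssm_rows, dis)
               else cbind(aa_tab[res[, p], , drop = FALSE], pssm_rows, dis)
      X[, cols] <- block
    }
    bad <- which(!is.finite(X), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop_hx(sprintf("non-finite value for sample %d, feature '%s'",
                      bad[1, 1], desc$name[bad[1, 2]]))
    }
    if (standardize) {
      X <- scale(X)
      X[, attr(X, "scaled:scale") == 0] <- 0
      attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    }
  }
  labels <- factor(windows$label, levels = c("positive", "negative"))
  sample_id <- if (n > 0L) sprintf("%s:%d", windows$protein_id, windows$center)
               else character()
  feature_matrix(X, desc, labels, sample_id, table)
}

#' Construct a feature matrix object
#'
#' @param values Samples x features numeric matrix.
#' @param descriptors Matching [feature_descriptors()] tibble.
#' @param labels Factor with levels `positive`, `negative`.
#' @param sample_id Character sample identifiers.
#' @param aaindex Optional `aaindex_table` used for encoding.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, descriptors, labels, sample_id = NULL,
                           aaindex = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(descriptors)) {
    stop_hx("values/descriptors dimension mismatch")
  }
  if (nrow(values) != length(labels)) stop_hx("values/labels length mismatch")
  structure(list(values = values, descriptors = descriptors,
                 labels = labels,
                 sample_id = sample_id %||% as.character(seq_len(nrow(values))),
                 aaindex = aaindex),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "positive"), sum(x$labels == "negative")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Serialize / load a feature matrix as TSV
#'
#' Columns: `sample_id`, `label`, then one column per feature named by its
#' descriptor string.
#'
#' @param fm A `feature_matrix`.
#' @param path TSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- tibble::as_tibble(fm$values)
  df <- dplyr::bind_cols(tibble::tibble(sample_id = fm$sample_id,
                                        label = as.character(fm$labels)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param descriptors Descriptor tibble matching the stored columns
#'   (re-derived from the feature names if omitted).
#' @export
read_feature_matrix <- function(path, descriptors = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), label = readr::col_character(),
    .default = readr::col_double()))
  vals <- as.matrix(df[, -(1:2)])
  if (is.null(descriptors)) {
    parts <- strsplit(colnames(vals), "|", fixed = TRUE)
    descriptors <- tibble::tibble(
      column = seq_along(parts),
      position = as.integer(substring(vapply(parts, `[`, "", 1L), 2L)),
      kind = vapply(parts, `[`, "", 2L),
      sub_id = dplyr::na_if(vapply(parts, `[`, "", 3L), "-"),
      name = colnames(vals))
  }
  feature_matrix(vals, descriptors,
                 factor(df$label, levels = c("positive", "negative")),
                 df$sample_id)
}
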