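# Feature-distribution analyses of a selected feature set against the full
# descriptor universe: by feature kind, window position, AAindex property
# cluster and PSSM amino-acid column. "Distributive" counts are the
# expectation under proportional draw from the universe
# (background proportion x set size); "resultant" counts are observed.

as_descriptor_set <- function(features) {
  if (inherits(features, "ranked_features") || is.data.frame(features)) features
  else stop_hx("`features` must be a descriptor/ranked tibble")
}

#' Distribution of feature kinds in a selected set
#'
#' @param features Descriptor rows of the selected set (e.g. a
#'   `ranked_features` list or a prefix of one).
#' @param background Full descriptor universe from [feature_descriptors()].
#' @return Tibble: `kind`, `background_n`, `distributive` (expected count
#'   under proportional draw, unrounded), `resultant` (observed count),
#'   `resultant_prop`.
#' @export
kind_distribution <- function(features, background) {
  features <- as_descriptor_set(features)
  kinds <- c("aaindex", "pssm", "disorder")
  bg <- table(factor(background$kind, levels = kinds))
  obs <- table(factor(features$kind, levels = kinds))
  tibble::tibble(kind = kinds,
                 background_n = as.integer(bg),
                 distributive = as.numeric(bg) / sum(bg) * nrow(features),
                 resultant = as.integer(obs),
                 resultant_prop = as.integer(obs) / max(nrow(features), 1L))
}

#' Distribution of window positions in a selected set
#'
#' Counts every feature at each of the window positions (the centre
#' position carries only pssm/disorder features, flagged in `center`).
#'
#' @inheritParams kind_distribution
#' @param window_length Window size of the universe (default 13).
#' @return Tibble: `position`, `center`, `background_n`, `distributive`,
#'   `resultant`, `resultant_prop`.
#' @export
position_distribution <- function(features, background, window_length = 13L) {
  features <- as_descriptor_set(features)
  pos <- seq_len(window_length)
  bg <- table(factor(background$position, levels = pos))
  obs <- table(factor(features$position, levels = pos))
  tibble::tibble(position = pos,
                 center = pos == (window_length + 1L) %/% 2L,
                 background_n = as.integer(bg),
                 distributive = as.numeric(bg) / sum(bg) * nrow(features),
                 resultant = as.integer(obs),
                 resultant_prop = as.integer(obs) / max(nrow(features), 1L))
}

#' Distribution of AAindex property clusters in a selected set
#'
#' Partitions the aaindex-kind features of the set by the property cluster
#' of their accession; accessions without a cluster assignment count under
#' `"unassigned"`.
#'
#' @inheritParams kind_distribution
#' @param table The `aaindex_table` carrying cluster labels.
#' @return Tibble: `cluster`, `resultant`, `resultant_prop` (of the aaindex
#'   subset).
#' @export
cluster_distribution <- function(features, table) {
  features <- as_descriptor_set(features)
  aa <- features[features$kind == "aaindex", ]
  lv <- c(AAINDEX_CLUSTERS, "unassigned")
  cl <- factor(unname(table$cluster[aa$sub_id]), levels = lv)
  cl[is.na(cl)] <- "unassigned"
  obs <- base::table(cl)  # the `table` argument shadows base::table here
  tibble::tibble(cluster = lv, resultant = as.integer(obs),
                 resultant_prop = as.integer(obs) / max(nrow(aa), 1L))
}

#' Distribution of PSSM amino-acid columns in a selected set
#'
#' Partitions the pssm-kind features of the set by the amino-acid column
#' they score (the residue the position may mutate to).
#'
#' @inheritParams kind_distribution
#' @return Tibble: `letter`, `resultant`, `resultant_prop` (of the pssm
#'   subset).
#' @export
pssm_column_distribution <- function(features) {
  features <- as_descriptor_set(features)
  ps <- features[features$kind == "pssm", ]
  obs <- table(factor(ps$sub_id, levels = AA_LETTERS))
  tibble::tibble(letter = AA_LETTERS, resultant = as.integer(obs),
                 resultant_prop = as.integer(obs) / max(nrow(ps), 1L))
}

#' Bar chart for a feature-distribution table
#'
#' Draws observed (resultant) counts, with expected (distributive) counts
#' overlaid where the table carries them.
#'
#' @param dist A tibble from one of the `*_distribution()` functions.
#' @return A ggplot object.
#' @export
plot_distribution <- function(dist) {
  cat_col <- setdiff(names(dist), c("center", "background_n", "distributive",
                                    "resultant", "resultant_prop"))[1]
  df <- dist
  df[[cat_col]] <- factor(df[[cat_col]], levels = unique(df[[cat_col]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[cat_col]], y = .data$resultant)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(y = "features in set") +
    ggplot2::theme_minimal()
  if ("distributive" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$distributive),
                                 colour = "firebrick", shape = 18, size = 3)
  }
  p
}
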