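# Protein records and labelled 13-residue peptide windows.
#
# The classification unit is a window of `window_length` residues (default
# 13) centred on a candidate proline or lysine: the candidate plus 6
# flanking residues each side. Windows at annotated hydroxylation sites are
# positives; the remaining candidate windows form the negative pool, from
# which negatives are drawn at a fixed ratio (default 2:1).

#' Assemble protein records
#'
#' Joins sequences with their PSSM profiles, disorder tracks and annotated
#' hydroxylation sites into one record table, validating that per-residue
#' tracks match sequence lengths and that every annotated site indexes the
#' annotated residue letter.
#'
#' @param sequences Tibble with `protein_id`, `sequence`.
#' @param pssms Named list of `pssm_profile` objects (names = protein ids);
#'   may omit proteins (their windows then cannot be encoded).
#' @param disorders Named list of numeric disorder vectors.
#' @param sites Site tibble as returned by [read_sites()]; may be `NULL`
#'   (no positives, e.g. for prediction-only inputs).
#' @return A tibble with columns `protein_id`, `sequence` and list-columns
#'   `pssm` (L x 20 matrix), `disorder` (length-L numeric),
#'   `positive_sites` (integer positions, 1-based).
#' @export
protein_records <- function(sequences, pssms = list(), disorders = list(),
                            sites = NULL) {
  if (!is.null(sites)) {
    read_check <- sites  # already validated if it came through read_sites()
    seq_of <- stats::setNames(sequences$sequence, sequences$protein_id)
    at <- substr(seq_of[read_check$protein_id], read_check$pos, read_check$pos)
    if (any(is.na(at)) || any(at != read_check$residue)) {
      stop_hx("site table inconsistent with sequences (unknown id or residue mismatch)")
    }
  }
  recs <- sequences
  recs$pssm <- purrr::map(recs$protein_id, function(id) {
    p <- pssms[[id]]
    if (is.null(p)) return(NULL)
    m <- if (inherits(p, "pssm_profile")) p$scores else as.matrix(p)
    if (nrow(m) != nchar(recs$sequence[recs$protein_id == id])) {
      stop_hx("PSSM length mismatch for protein ", id)
    }
    m
  })
  recs$disorder <- purrr::map(recs$protein_id, function(id) {
    d <- disorders[[id]]
    if (!is.null(d) && length(d) != nchar(recs$sequence[recs$protein_id == id])) {
      stop_hx("disorder length mismatch for protein ", id)
    }
    d
  })
  recs$positive_sites <- purrr::map(recs$protein_id, function(id) {
    if (is.null(sites)) integer() else sort(sites$pos[sites$protein_id == id])
  })
  tibble::as_tibble(recs)
}

#' Extract candidate peptide windows from one protein record
#'
#' Emits one window per occurrence of the target residue. Windows that run
#' past a terminus are, under the default `"pad"` policy, filled with the
#' placeholder residue `X` (AAindex value = per-index mean over the 20
#' residues, PSSM row = zeros, disorder = 0.5, a class-neutral imputation);
#' under `"exclude"` they are dropped. Padding preserves every annotated
#' site, which matters on small datasets.
#'
#' @param record One row of a [protein_records()] tibble (a list or
#'   one-row tibble with `protein_id`, `sequence`, `pssm`, `disorder`,
#'   `positive_sites`).
#' @param target_residue `"P"` (hydroxyproline task) or `"K"`
#'   (hydroxylysine task).
#' @param terminus_policy `"pad"` (default) or `"exclude"`.
#' @param window_length Odd window size, default 13.
#' @return A tibble of windows: `protein_id`, `center` (1-based position of
#'   the candidate), `peptide` (window string, `X`-padded), `label`
#'   (`"positive"`/`"negative"`), and list-columns `pssm`
#'   (window_length x 20 matrix) and `disorder` (numeric, window_length).
#' @export
extract_windows <- function(record, target_residue = c("P", "K"),
                            terminus_policy = c("pad", "exclude"),
                            window_length = 13L) {
  target_residue <- match.arg(target_residue)
  terminus_policy <- match.arg(terminus_policy)
  window_length <- assert_scalar_count(window_length, "window_length")
  if (window_length %% 2L == 0L) stop_hx("`window_length` must be odd")
  flank <- (window_length - 1L) %/% 2L
  if (is.data.frame(record)) {
    record <- list(protein_id = record$protein_id[[1]],
                   sequence = record$sequence[[1]],
                   pssm = record$pssm[[1]],
                   disorder = record$disorder[[1]],
                   positive_sites = record$positive_sites[[1]])
  }
  seq_chars <- split_chars(record$sequence)
  L <- length(seq_chars)
  centers <- which(seq_chars == target_residue)
  if (terminus_policy == "exclude") {
    centers <- centers[centers > flank & centers <= L - flank]
  }
  pos_sites <- record$positive_sites %||% integer()
  pssm <- record$pssm
  disorder <- record$disorder
  if (length(centers) == 0L) return(empty_windows())

  rows <- purrr::map(centers, function(c0) {
    idx <- (c0 - flank):(c0 + flank)
    inside <- idx >= 1L & idx <= L
    res <- rep(PAD_RESIDUE, window_length)
    res[inside] <- seq_chars[idx[inside]]
    pm <- matrix(0, window_length, 20L, dimnames = list(NULL, PSSM_ALPHABET))
    if (!is.null(pssm)) pm[inside, ] <- pssm[idx[inside], , drop = FALSE]
    dis <- rep(PAD_DISORDER, window_length)
    if (!is.null(disorder)) dis[inside] <- disorder[idx[inside]]
    tibble::tibble(
      protein_id = record$protein_id,
      center = c0,
      peptide = paste(res, collapse = ""),
      label = if (c0 %in% pos_sites) "positive" else "negative",
      pssm = list(pm),
      disorder = list(dis))
  })
  dplyr::bind_rows(rows)
}

empty_windows <- function() {
  tibble::tibble(protein_id = character(), center = integer(),
                 peptide = character(), label = character(),
                 pssm = list(), disorder = list())
}

#' Sample negative windows at a fixed ratio to positives
#'
#' Draws `round(ratio * n_positive)` windows uniformly without replacement
#' from the negative-candidate pool. The draw is global across proteins and
#' deterministic given `seed`.
#'
#' @param candidates Tibble of negative-candidate windows.
#' @param n_positive Number of positive windows the sample is matched to.
#' @param ratio Negatives per positive (default 2, the benchmark design).
#' @param seed Integer seed; required so the sample is reproducible.
#' @return A tibble of sampled negative windows (input row order preserved).
#' @export
sample_negatives <- function(candidates, n_positive, ratio = 2, seed) {
  if (!is.numeric(ratio) || ratio <= 0) stop_hx("`ratio` must be > 0")
  n_positive <- assert_scalar_count(n_positive, "n_positive")
  seed <- assert_scalar_count(abs(seed) + 1L, "seed") - 1L
  n_draw <- as.integer(round(ratio * n_positive))
  if (nrow(candidates) < n_draw) {
    stop_hx(sprintf("need %d negative candidates but only %d available (shortfall %d)",
                    n_draw, nrow(candidates), n_draw - nrow(candidates)))
  }
  keep <- withr::with_seed(seed, sort(sample.int(nrow(candidates), n_draw)))
  candidates[keep, ]
}

#' Build the labelled benchmark window set
#'
#' Extracts all candidate windows from every record, keeps all positives and
#' samples negatives at `ratio` per positive.
#'
#' @param records A [protein_records()] tibble.
#' @inheritParams extract_windows
#' @inheritParams sample_negatives
#' @return A window tibble (positives first, then sampled negatives).
#' @export
build_dataset <- function(records, target_residue = c("P", "K"), ratio = 2,
                          seed, terminus_policy = c("pad", "exclude"),
                          window_length = 13L) {
  target_residue <- match.arg(target_residue)
  terminus_policy <- match.arg(terminus_policy)
  all_win <- dplyr::bind_rows(purrr::map(seq_len(nrow(records)), function(i) {
    extract_windows(records[i, ], target_residue, terminus_policy, window_length)
  }))
  pos <- dplyr::filter(all_win, .data$label == "positive")
  neg_pool <- dplyr::filter(all_win, .data$label == "negative")
  if (nrow(pos) == 0L) stop_hx("no positive windows: check site annotations")
  neg <- sample_negatives(neg_pool, nrow(pos), ratio, seed)
  dplyr::bind_rows(pos, neg)
}

#' Write / read the peptide table
#'
#' Serializes windows in the shape of a supplementary peptide list
#' (`peptide`, `protein_id`, `center`, `label`); PSSM and disorder
#' list-columns are not carried (they are re-attached by re-extracting
#' against the records).
#'
#' @param windows A window tibble.
#' @param path TSV path.
#' @export
write_peptides <- function(windows, path) {
  readr::write_tsv(windows[, c("peptide", "protein_id", "center", "label")], path)
  invisible(path)
}

#' @rdname write_peptides
#' @export
read_peptides <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    peptide = readr::col_character(), protein_id = readr::col_character(),
    center = readr::col_integer(), label = readr::col_character()))
}
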