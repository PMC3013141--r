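# FASTA, per-residue disorder tracks and annotated-site tables.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A tibble with columns `protein_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  tibble::tibble(protein_id = sub("\\s.*$", "", names(aas)),
                 sequence = unname(as.character(aas)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Tibble with columns `protein_id`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  aas <- Biostrings::AAStringSet(sequences$sequence)
  names(aas) <- sequences$protein_id
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Read a per-residue disorder track
#'
#' Two-column TSV (`pos`, `score`), one row per residue, scores in \[0, 1\]
#' (the range of per-residue disorder predictors such as VSL2).
#'
#' @param path TSV path.
#' @param length_expected Optional sequence length to validate against.
#' @return Numeric vector of scores, one per residue.
#' @export
read_disorder <- function(path, length_expected = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    pos = readr::col_integer(), score = readr::col_double()))
  if (any(df$pos != seq_len(nrow(df)))) {
    stop_hx("disorder track ", path, " positions must run 1..L without gaps")
  }
  if (any(df$score < 0 | df$score > 1 | !is.finite(df$score))) {
    stop_hx("disorder scores in ", path, " must lie in [0, 1]")
  }
  if (!is.null(length_expected) && nrow(df) != length_expected) {
    stop_hx(sprintf("disorder track %s has %d rows, expected %d",
                    path, nrow(df), length_expected))
  }
  df$score
}

#' Write a per-residue disorder track
#'
#' @param scores Numeric vector in \[0, 1\].
#' @param path Output path.
#' @export
write_disorder <- function(scores, path) {
  readr::write_tsv(tibble::tibble(pos = seq_along(scores), score = scores), path)
  invisible(path)
}

#' Read an annotated modified-residue site table
#'
#' Three-column TSV (`protein_id`, `pos`, `residue`) listing experimentally
#' annotated hydroxylation sites (1-based positions). When `sequences` is
#' supplied each site is validated: the position must lie within the
#' sequence and the residue letter must match the sequence at that position.
#'
#' @param path TSV path.
#' @param sequences Optional tibble (`protein_id`, `sequence`) to validate
#'   against.
#' @return A tibble with columns `protein_id`, `pos`, `residue`.
#' @export
read_sites <- function(path, sequences = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(), pos = readr::col_integer(),
    residue = readr::col_character()))
  if (!all(df$residue %in% c("P", "K"))) {
    stop_hx("site residues must be P or K; offenders: ",
            paste(unique(df$residue[!df$residue %in% c("P", "K")]), collapse = ", "))
  }
  if (!is.null(sequences)) {
    seq_of <- stats::setNames(sequences$sequence, sequences$protein_id)
    missing_ids <- setdiff(df$protein_id, names(seq_of))
    if (length(missing_ids) > 0L) {
      stop_hx("site table references unknown protein(s): ",
              paste(missing_ids, collapse = ", "))
    }
    len <- nchar(seq_of[df$protein_id])
    oob <- df$pos < 1L | df$pos > len
    if (any(oob)) {
      stop_hx("site position(s) beyond sequence length: ",
              paste(sprintf("%s:%d", df$protein_id[oob], df$pos[oob]), collapse = ", "))
    }
    at <- substr(seq_of[df$protein_id], df$pos, df$pos)
    mism <- at != df$residue
    if (any(mism)) {
      stop_hx("annotated residue disagrees with sequence at: ",
              paste(sprintf("%s:%d (%s vs %s)", df$protein_id[mism], df$pos[mism],
                            df$residue[mism], at[mism]), collapse = ", "))
    }
  }
  df
}

#' Write a modified-residue site table
#'
#' @param sites Tibble with columns `protein_id`, `pos`, `residue`.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  readr::write_tsv(sites[, c("protein_id", "pos", "residue")], path)
  invisible(path)
}
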