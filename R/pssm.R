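# PSI-BLAST ASCII PSSM reader/writer.
#
# The ASCII matrix dump has two header lines, a column-header line, then one
# row per residue:
#   <pos> <residue> <20 log-odds integers> <20 weighted-percentage integers>
#   [information-per-position] [relative-weight]
# followed by K/Lambda footer lines. Both 20-column blocks are parsed; the
# log-odds block is the default conservation encoding (the conventional
# choice in PTM-site predictors), the percentage block is available via
# `block = "percent"`.

#' Read a PSI-BLAST ASCII PSSM
#'
#' @param path Path to the ASCII matrix file (the PSI-BLAST profile dump).
#' @param block Which 20-column block to expose as `scores`: `"logodds"`
#'   (default) or `"percent"`.
#' @return A `pssm_profile`: list with `sequence` (string reconstructed from
#'   the residue column), `scores` (L x 20 numeric matrix, columns in
#'   PSI-BLAST amino-acid order, from the selected block), and `block`.
#' @export
read_pssm <- function(path, block = c("logodds", "percent")) {
  block <- match.arg(block)
  lines <- readLines(path)
  is_row <- grepl("^[[:space:]]*[0-9]+[[:space:]]+[A-Za-z][[:space:]]", lines)
  if (!any(is_row)) stop_hx("no PSSM rows found in ", path)
  rows <- which(is_row)
  letters_out <- character(length(rows))
  logodds <- matrix(NA_real_, length(rows), 20L)
  percent <- matrix(NA_real_, length(rows), 20L)
  for (j in seq_along(rows)) {
    ln <- rows[j]
    toks <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    letters_out[j] <- toks[2]
    nums <- suppressWarnings(as.numeric(toks[-(1:2)]))
    # real dumps append information content and relative weight (2 floats)
    if (anyNA(nums) || !(length(nums) %in% c(40L, 42L))) {
      stop_hx(sprintf("malformed PSSM row at line %d of %s: expected 40 numeric columns, found %d",
                      ln, path, sum(!is.na(nums))))
    }
    logodds[j, ] <- nums[1:20]
    percent[j, ] <- nums[21:40]
  }
  scores <- if (block == "logodds") logodds else percent
  colnames(scores) <- PSSM_ALPHABET
  pssm_profile(paste(letters_out, collapse = ""), scores, block = block)
}

#' Construct a PSSM profile
#'
#' @param sequence Amino-acid string of length L.
#' @param scores L x 20 numeric matrix in PSI-BLAST column order.
#' @param block Label recording which block `scores` came from.
#' @return A `pssm_profile` object.
#' @export
pssm_profile <- function(sequence, scores, block = "logodds") {
  scores <- as.matrix(scores)
  if (nrow(scores) != nchar(sequence)) {
    stop_hx(sprintf("PSSM has %d rows but sequence has %d residues",
                    nrow(scores), nchar(sequence)))
  }
  if (ncol(scores) != 20L) stop_hx("PSSM rows must have exactly 20 values")
  colnames(scores) <- PSSM_ALPHABET
  structure(list(sequence = sequence, scores = scores, block = block),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %d residues, %s block\n", nrow(x$scores), x$block))
  invisible(x)
}

#' Write a PSSM profile as a PSI-BLAST-style ASCII matrix
#'
#' Emits the standard two-block layout. The profile's own scores fill the
#' block it was read from; the other block is written as zeros (it is not
#' recoverable from a single block).
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @export
write_pssm <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", rep(PSSM_ALPHABET, 2)), collapse = ""))),
    con)
  res <- split_chars(profile$sequence)
  zero <- rep(0L, 20L)
  for (i in seq_len(nrow(profile$scores))) {
    sc <- profile$scores[i, ]
    lo <- if (profile$block == "logodds") sc else zero
    pc <- if (profile$block == "percent") sc else zero
    writeLines(sprintf("%5d %s %s %s  0.00 0.00", i, res[i],
                       paste(sprintf("%3d", as.integer(round(lo))), collapse = " "),
                       paste(sprintf("%3d", as.integer(round(pc))), collapse = " ")),
               con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}
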