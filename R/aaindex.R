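# AAindex1 flat-file reader/writer and the accession -> property-cluster map.
#
# An AAindex1 record looks like
#   H ANDN920101
#   D alpha-CH chemical shifts (Andersen et al., 1992)
#   ...
#   I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
#      4.35    4.38    4.75    4.76    4.65    4.37    4.29    3.97    4.63    3.95
#      4.17    4.36    4.52    4.66    4.44    4.50    4.35    4.70    4.60    3.95
#   //
# The two data lines after "I" carry values for A R N D C Q E G H I and
# L K M F P S T W Y V respectively; missing values are printed as "NA".

#' Read an AAindex1 flat file
#'
#' Parses the AAindex1 record grammar (`H` accession line, `I` value header,
#' two 10-value data lines, `//` terminator) into a table of amino-acid
#' property indices. Indices containing missing (`NA`) values are dropped by
#' default, since downstream feature encoding requires a finite value for
#' every residue; the number of exclusions is reported via a message.
#'
#' @param path Path to an AAindex1-format file.
#' @param drop_na Drop indices with any missing value (default `TRUE`);
#'   with `drop_na = FALSE` an NA-containing record is an error instead,
#'   since every retained index must be fully usable for encoding.
#' @param cluster_map Optional tibble with columns `accession`, `cluster`
#'   assigning each index to one of the five property clusters
#'   (alpha-and-turn-propensities, beta-propensity, composition,
#'   hydrophobicity, physicochemical). Accessions absent from the map are
#'   labelled `"unassigned"`.
#' @return An object of class `aaindex_table`: a list with `entries` (a
#'   named list of length-20 numeric vectors, names = one-letter amino-acid
#'   codes), `cluster` (named character vector), and `count`.
#' @export
read_aaindex <- function(path, drop_na = TRUE, cluster_map = NULL) {
  lines <- readLines(path)
  starts <- grep("^H ", lines)
  if (length(starts) == 0L) stop_hx("no AAindex records (H lines) found in ", path)
  ends <- grep("^//", lines)
  if (length(ends) < length(starts)) stop_hx("unterminated AAindex record in ", path)

  entries <- list()
  dropped <- character()
  for (i in seq_along(starts)) {
    rec <- lines[starts[i]:ends[ends >= starts[i]][1]]
    acc <- trimws(sub("^H ", "", rec[1]))
    ihdr <- grep("^I ", rec)
    if (length(ihdr) != 1L) {
      stop_hx(sprintf("AAindex record '%s': missing or duplicated I line", acc))
    }
    vals_raw <- unlist(strsplit(trimws(rec[ihdr + 1:2]), "[[:space:]]+"))
    if (length(vals_raw) != 20L) {
      stop_hx(sprintf("AAindex record '%s': expected 20 values, found %d",
                      acc, length(vals_raw)))
    }
    vals <- suppressWarnings(as.numeric(vals_raw))
    bad <- vals_raw != "NA" & is.na(vals)
    if (any(bad)) {
      stop_hx(sprintf("AAindex record '%s': unparseable value '%s'",
                      acc, vals_raw[bad][1]))
    }
    names(vals) <- AAINDEX_ALPHABET
    if (anyNA(vals)) {
      if (!drop_na) {
        stop_hx(sprintf("AAindex record '%s' contains NA values; encoding needs 20 finite values (see drop_na)",
                        acc))
      }
      dropped <- c(dropped, acc)
    } else {
      entries[[acc]] <- vals
    }
  }
  if (length(dropped) > 0L) {
    message(sprintf("read_aaindex: dropped %d of %d indices containing NA values",
                    length(dropped), length(dropped) + length(entries)))
  }
  aaindex_table(entries, cluster_map)
}

#' Construct an AAindex table from in-memory entries
#'
#' @param entries Named list of length-20 numeric vectors (names = accessions;
#'   each vector named by one-letter amino-acid code).
#' @inheritParams read_aaindex
#' @return An `aaindex_table` object.
#' @export
aaindex_table <- function(entries, cluster_map = NULL) {
  for (acc in names(entries)) {
    v <- entries[[acc]]
    if (length(v) != 20L || !all(is.finite(v))) {
      stop_hx(sprintf("AAindex entry '%s' must have exactly 20 finite values", acc))
    }
    entries[[acc]] <- v[AAINDEX_ALPHABET]
  }
  cluster <- rep("unassigned", length(entries))
  names(cluster) <- names(entries)
  if (!is.null(cluster_map)) {
    bad <- setdiff(unique(cluster_map$cluster), AAINDEX_CLUSTERS)
    if (length(bad) > 0L) {
      stop_hx("unknown AAindex cluster label(s): ", paste(bad, collapse = ", "))
    }
    hit <- match(names(entries), cluster_map$accession)
    cluster[!is.na(hit)] <- cluster_map$cluster[hit[!is.na(hit)]]
  }
  structure(list(entries = entries, cluster = cluster,
                 count = length(entries)),
            class = "aaindex_table")
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat(sprintf("<aaindex_table> %d indices (%d cluster-assigned)\n",
              x$count, sum(x$cluster != "unassigned")))
  invisible(x)
}

#' Write an AAindex table as an AAindex1 flat file
#'
#' Inverse of [read_aaindex()]: the emitted file parses back to an identical
#' table (up to numeric formatting, controlled by `digits`).
#'
#' @param table An `aaindex_table`.
#' @param path Output path.
#' @param digits Decimal places used for values.
#' @export
write_aaindex <- function(table, path, digits = 3) {
  fmt <- function(v) paste(formatC(v, format = "f", digits = digits, width = 8),
                           collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in names(table$entries)) {
    v <- table$entries[[acc]]
    writeLines(c(
      paste0("H ", acc),
      paste0("D synthetic index ", acc),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      fmt(v[1:10]), fmt(v[11:20]), "//"), con)
  }
  invisible(path)
}

#' Read an accession-to-cluster mapping file
#'
#' Two-column TSV (`accession`, `cluster`) assigning AAindex accessions to
#' the five property clusters used in feature analysis.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `accession`, `cluster`.
#' @export
read_cluster_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(), cluster = readr::col_character()))
  bad <- setdiff(unique(df$cluster), AAINDEX_CLUSTERS)
  if (length(bad) > 0L) {
    stop_hx("unknown cluster label(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  df
}
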