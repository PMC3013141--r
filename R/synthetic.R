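# Synthetic benchmark generator with planted informative features.
#
# Emulates every external input the pipeline consumes — sequences with
# annotated sites, PSSM profiles, disorder tracks and a miniature AAindex
# table — with a known ground truth: a chosen set of pssm/disorder feature
# descriptors whose values are mean-shifted in positive-class windows by
# `effect_size` within-class standard deviations. The signal is planted on
# pssm and disorder descriptors only, because all AAindex features at a
# window position are jointly determined by the residue letter, so an exact
# chosen subset of them cannot be shifted independently.
#
# Candidate sites are spaced one full window apart so windows never overlap
# and each planted shift affects exactly one window.

#' Specification for a synthetic benchmark
#'
#' Defaults define a ~200-sample study (67 positives + 134 sampled
#' negatives at the 2:1 design ratio) with 10 strongly informative planted
#' features (3-SD class shift) — large enough for stable ranking and
#' jackknife estimates, small enough to run in seconds.
#'
#' @param n_proteins Number of proteins.
#' @param seq_length Residues per protein (>= window length).
#' @param n_positive_sites Total annotated (positive) sites across proteins.
#' @param target_residue `"P"` or `"K"`.
#' @param n_informative_features Number of planted informative descriptors.
#' @param effect_size Class mean shift on planted features, in within-class
#'   SD units.
#' @param n_aaindex Indices in the miniature AAindex table.
#' @param window_length Window size (default 13).
#' @param seed Integer seed; every random choice derives from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins = 20L, seq_length = 150L,
                           n_positive_sites = 67L,
                           target_residue = c("P", "K"),
                           n_informative_features = 10L, effect_size = 3,
                           n_aaindex = 3L, window_length = 13L, seed = 1L) {
  target_residue <- match.arg(target_residue)
  spec <- list(n_proteins = assert_scalar_count(n_proteins, "n_proteins"),
               seq_length = assert_scalar_count(seq_length, "seq_length"),
               n_positive_sites = assert_scalar_count(n_positive_sites, "n_positive_sites"),
               target_residue = target_residue,
               n_informative_features = assert_scalar_count(n_informative_features,
                                                            "n_informative_features"),
               effect_size = effect_size,
               n_aaindex = assert_scalar_count(n_aaindex, "n_aaindex"),
               window_length = assert_scalar_count(window_length, "window_length"),
               seed = assert_scalar_count(seed + 1L, "seed") - 1L)
  if (spec$seq_length < spec$window_length) {
    stop_hx("`seq_length` must be at least the window length")
  }
  if (!is.numeric(spec$effect_size) || spec$effect_size < 0) {
    stop_hx("`effect_size` must be >= 0")
  }
  structure(spec, class = "synthetic_spec")
}

# Within-class noise scales of the generated tracks.
SYN_PSSM_SD <- 3
SYN_DISORDER_SD <- 0.08

#' Generate a synthetic benchmark with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `records` ([protein_records()] tibble), `aaindex`
#'   (miniature `aaindex_table` with cluster labels), `cluster_map`,
#'   `sites` (site tibble), `truth` (descriptor rows of the planted
#'   informative features), `descriptors` (full universe), `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    wl <- spec$window_length
    flank <- (wl - 1L) %/% 2L
    # one candidate site per non-overlapping window slot
    slot_centers <- seq(flank + 1L, spec$seq_length - flank, by = wl)
    n_slots <- spec$n_proteins * length(slot_centers)
    if (n_slots < spec$n_positive_sites) {
      stop_hx(sprintf("only %d candidate sites available for %d positives; increase n_proteins or seq_length",
                      n_slots, spec$n_positive_sites))
    }

    acc <- sprintf("SYN%03d", seq_len(spec$n_aaindex))
    entries <- stats::setNames(lapply(acc, function(a) {
      stats::setNames(round(stats::rnorm(20L), 3), AAINDEX_ALPHABET)
    }), acc)
    cluster_map <- tibble::tibble(
      accession = acc,
      cluster = AAINDEX_CLUSTERS[(seq_along(acc) - 1L) %% 5L + 1L])
    aaindex <- aaindex_table(entries, cluster_map)

    descriptors <- feature_descriptors(acc, wl)
    eligible <- descriptors[descriptors$kind %in% c("pssm", "disorder"), ]
    if (nrow(eligible) < spec$n_informative_features) {
      stop_hx("not enough pssm/disorder descriptors to plant the requested signal")
    }
    truth <- eligible[sort(sample.int(nrow(eligible),
                                      spec$n_informative_features)), ]

    other <- setdiff(AA_LETTERS, c(spec$target_residue, PAD_RESIDUE))
    ids <- sprintf("SYNP%03d", seq_len(spec$n_proteins))
    global_site <- sort(sample.int(n_slots, spec$n_positive_sites))

    seqs <- character(spec$n_proteins)
    pssms <- list(); disorders <- list(); site_rows <- list()
    slot <- 0L
    for (i in seq_len(spec$n_proteins)) {
      chars <- sample(other, spec$seq_length, replace = TRUE)
      chars[slot_centers] <- spec$target_residue
      pm <- matrix(round(stats::rnorm(spec$seq_length * 20L, 0, SYN_PSSM_SD)),
                   spec$seq_length, 20L, dimnames = list(NULL, PSSM_ALPHABET))
      dis <- pmin(1, pmax(0, stats::rnorm(spec$seq_length, 0.5, SYN_DISORDER_SD)))
      pos_here <- integer()
      for (c0 in slot_centers) {
        slot <- slot + 1L
        if (!(slot %in% global_site)) next
        pos_here <- c(pos_here, c0)
        # shift the underlying tracks so this window carries the planted signal
        for (r in seq_len(nrow(truth))) {
          at <- c0 + truth$position[r] - (flank + 1L)
          if (truth$kind[r] == "pssm") {
            pm[at, truth$sub_id[r]] <- pm[at, truth$sub_id[r]] +
              round(spec$effect_size * SYN_PSSM_SD)
          } else {
            dis[at] <- min(1, dis[at] + spec$effect_size * SYN_DISORDER_SD)
          }
        }
      }
      seqs[i] <- paste(chars, collapse = "")
      pssms[[ids[i]]] <- pssm_profile(seqs[i], pm)
      disorders[[ids[i]]] <- dis
      if (length(pos_here) > 0L) {
        site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
          protein_id = ids[i], pos = pos_here, residue = spec$target_residue)
      }
    }
    sites <- dplyr::bind_rows(site_rows)
    records <- protein_records(tibble::tibble(protein_id = ids, sequence = seqs),
                               pssms, disorders, sites)
    list(records = records, aaindex = aaindex, cluster_map = cluster_map,
         sites = sites, truth = truth, descriptors = descriptors, spec = spec)
  })
}

#' Write a synthetic benchmark to disk as pipeline input files
#'
#' Emits `sequences.fasta`, `sites.tsv`, `aaindex.txt`, `clusters.tsv`,
#' `truth.tsv` and per-protein `<id>.pssm` / `<id>.disorder.tsv` — valid
#' inputs to every reader in the package. Output is byte-identical for the
#' same spec.
#'
#' @param gen Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixtures <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_fasta(gen$records[, c("protein_id", "sequence")], fp("sequences.fasta"))
  write_sites(gen$sites, fp("sites.tsv"))
  write_aaindex(gen$aaindex, fp("aaindex.txt"))
  readr::write_tsv(gen$cluster_map, fp("clusters.tsv"))
  readr::write_tsv(gen$truth[, c("column", "position", "kind", "sub_id", "name")],
                   fp("truth.tsv"))
  for (i in seq_len(nrow(gen$records))) {
    id <- gen$records$protein_id[i]
    write_pssm(pssm_profile(gen$records$sequence[i], gen$records$pssm[[i]]),
               fp(paste0(id, ".pssm")))
    write_disorder(gen$records$disorder[[i]], fp(paste0(id, ".disorder.tsv")))
  }
  invisible(dir)
}

#' Read pipeline input files from a fixture directory
#'
#' Counterpart of [write_synthetic_fixtures()]; also the generic loader for
#' user-supplied data laid out the same way.
#'
#' @param dir Directory containing `sequences.fasta`, `sites.tsv`,
#'   `aaindex.txt`, optional `clusters.tsv`, and per-protein `<id>.pssm`
#'   and `<id>.disorder.tsv` files.
#' @return A list with `records`, `aaindex`, `sites`.
#' @export
read_input_dir <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  seqs <- read_fasta(fp("sequences.fasta"))
  sites <- if (file.exists(fp("sites.tsv"))) read_sites(fp("sites.tsv"), seqs) else NULL
  cmap <- if (file.exists(fp("clusters.tsv"))) read_cluster_map(fp("clusters.tsv")) else NULL
  aaindex <- read_aaindex(fp("aaindex.txt"), cluster_map = cmap)
  pssms <- list(); disorders <- list()
  for (id in seqs$protein_id) {
    pf <- fp(paste0(id, ".pssm"))
    df <- fp(paste0(id, ".disorder.tsv"))
    if (file.exists(pf)) pssms[[id]] <- read_pssm(pf)
    if (file.exists(df)) {
      disorders[[id]] <- read_disorder(df, nchar(seqs$sequence[seqs$protein_id == id]))
    }
  }
  list(records = protein_records(seqs, pssms, disorders, sites),
       aaindex = aaindex, sites = sites)
}
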