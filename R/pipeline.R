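# File-to-file pipeline stages. Each stage consumes the previous stage's
# outputs, writes plain-text artifacts plus a JSON manifest recording
# inputs, parameters, seed and package version, and is byte-reproducible:
# identical manifests imply identical outputs. The Rscript front-end in
# inst/cli/hydroxsite.R dispatches one subcommand to each stage function.

write_manifest <- function(dir, stage, inputs, params) {
  manifest <- list(stage = stage, inputs = inputs, params = params,
                   package = "hydroxsite",
                   version = as.character(utils::packageVersion("hydroxsite")))
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop_hx(sprintf("missing artifact '%s'; run the '%s' stage first",
                    path, produced_by))
  }
  path
}

#' Pipeline stage: generate synthetic fixtures
#'
#' @param dir Output directory.
#' @param spec A [synthetic_spec()].
#' @return The generated benchmark, invisibly.
#' @export
stage_fixtures <- function(dir, spec = synthetic_spec()) {
  gen <- generate_synthetic(spec)
  write_synthetic_fixtures(gen, dir)
  write_manifest(dir, "fixtures", inputs = list(), params = unclass(spec))
  invisible(gen)
}

#' Pipeline stage: build the labelled peptide dataset
#'
#' Reads an input directory ([read_input_dir()] layout), extracts candidate
#' windows, samples negatives at `ratio` per positive and writes
#' `peptides.tsv`.
#'
#' @param input_dir Directory with sequences, sites, PSSMs, disorder tracks.
#' @param out_dir Output directory.
#' @inheritParams build_dataset
#' @return The window tibble, invisibly.
#' @export
stage_dataset <- function(input_dir, out_dir, target_residue = "P", ratio = 2,
                          seed = 1L, terminus_policy = "pad",
                          window_length = 13L) {
  require_artifact(file.path(input_dir, "sequences.fasta"), "fixtures")
  inp <- read_input_dir(input_dir)
  windows <- build_dataset(inp$records, target_residue, ratio, seed,
                           terminus_policy, window_length)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_peptides(windows, file.path(out_dir, "peptides.tsv"))
  write_manifest(out_dir, "dataset", inputs = list(input_dir = input_dir),
                 params = list(target_residue = target_residue, ratio = ratio,
                               seed = seed, terminus_policy = terminus_policy,
                               window_length = window_length))
  invisible(windows)
}

# Re-attach PSSM/disorder tracks to a peptide table by re-extracting the
# listed (protein, center) windows against the records.
windows_from_peptides <- function(peptides, records, target_residue,
                                  terminus_policy = "pad", window_length = 13L) {
  all_win <- dplyr::bind_rows(purrr::map(seq_len(nrow(records)), function(i) {
    extract_windows(records[i, ], target_residue, terminus_policy, window_length)
  }))
  key <- paste(peptides$protein_id, peptides$center)
  hit <- match(key, paste(all_win$protein_id, all_win$center))
  if (anyNA(hit)) {
    stop_hx("peptide table lists windows absent from the records: ",
            paste(utils::head(key[is.na(hit)], 3L), collapse = ", "))
  }
  out <- all_win[hit, ]
  out$label <- peptides$label
  out
}

#' Pipeline stage: encode the dataset as a feature matrix
#'
#' Reads `peptides.tsv` (from [stage_dataset()]) plus the input directory,
#' encodes every window and writes `feature_matrix.tsv`.
#'
#' @inheritParams stage_dataset
#' @param work_dir Directory holding `peptides.tsv`; outputs go there too.
#' @return The `feature_matrix`, invisibly.
#' @export
stage_encode <- function(input_dir, work_dir, target_residue = "P",
                         terminus_policy = "pad", window_length = 13L) {
  peptides <- read_peptides(require_artifact(file.path(work_dir, "peptides.tsv"),
                                             "build-dataset"))
  inp <- read_input_dir(input_dir)
  windows <- windows_from_peptides(peptides, inp$records, target_residue,
                                   terminus_policy, window_length)
  fm <- encode_windows(windows, inp$aaindex, window_length)
  write_feature_matrix(fm, file.path(work_dir, "feature_matrix.tsv"))
  write_manifest(work_dir, "encode", inputs = list(input_dir = input_dir),
                 params = list(target_residue = target_residue,
                               terminus_policy = terminus_policy,
                               window_length = window_length))
  invisible(fm)
}

#' Pipeline stage: rank features (MaxRel and mRMR)
#'
#' Reads `feature_matrix.tsv` and writes `maxrel.tsv` and `mrmr.tsv`.
#'
#' @param work_dir Directory holding `feature_matrix.tsv`.
#' @inheritParams rank_mrmr
#' @return List of the two `ranked_features` tibbles, invisibly.
#' @export
stage_rank <- function(work_dir, top_n = 500L, scheme = "difference",
                       k_sigma = 1) {
  fm <- read_feature_matrix(require_artifact(file.path(work_dir, "feature_matrix.tsv"),
                                             "encode"))
  maxrel <- rank_maxrel(fm, top_n, k_sigma)
  mrmr <- rank_mrmr(fm, top_n, scheme, k_sigma)
  write_ranked(maxrel, file.path(work_dir, "maxrel.tsv"))
  write_ranked(mrmr, file.path(work_dir, "mrmr.tsv"))
  write_manifest(work_dir, "rank",
                 inputs = list(feature_matrix = "feature_matrix.tsv"),
                 params = list(top_n = top_n, scheme = scheme,
                               k_sigma = k_sigma))
  invisible(list(maxrel = maxrel, mrmr = mrmr))
}

#' Pipeline stage: incremental feature selection
#'
#' Reads `feature_matrix.tsv` and `mrmr.tsv`, runs the IFS loop, writes the
#' curve (`ifs_curve.tsv`) and the serialized optimal model
#' (`model.json`, with the training matrix already in `feature_matrix.tsv`).
#'
#' @inheritParams stage_rank
#' @inheritParams run_ifs
#' @return The `ifs_result`, invisibly.
#' @export
stage_ifs <- function(work_dir, max_k = NULL, objective = "AC") {
  fm <- read_feature_matrix(require_artifact(file.path(work_dir, "feature_matrix.tsv"),
                                             "encode"))
  ranked <- read_ranked(require_artifact(file.path(work_dir, "mrmr.tsv"), "rank"))
  ifs <- run_ifs(fm, ranked, max_k, objective)
  write_ifs_curve(ifs, file.path(work_dir, "ifs_curve.tsv"))
  jsonlite::write_json(
    list(optimal_k = ifs$optimal_k,
         objective = ifs$objective,
         feature_columns = ifs$feature_columns,
         feature_names = fm$descriptors$name[ifs$feature_columns],
         metrics = as.list(ifs$optimal_metrics)),
    file.path(work_dir, "model.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_manifest(work_dir, "ifs",
                 inputs = list(feature_matrix = "feature_matrix.tsv",
                               ranked = "mrmr.tsv"),
                 params = list(max_k = max_k, objective = objective))
  invisible(ifs)
}

#' Pipeline stage: predict hydroxylation sites on new proteins
#'
#' Applies the serialized IFS-optimal model (training matrix + selected
#' feature prefix) to every candidate window of a new input directory and
#' writes `predictions.tsv` with per-site labels and nearest-neighbour
#' distances.
#'
#' @param model_dir Directory holding `model.json` and `feature_matrix.tsv`
#'   (a completed [stage_ifs()] work directory).
#' @param input_dir New input directory (sites file optional and unused).
#' @param out_path Output TSV path.
#' @inheritParams stage_dataset
#' @return The prediction tibble, invisibly.
#' @export
stage_predict <- function(model_dir, input_dir, out_path, target_residue = "P",
                          terminus_policy = "pad", window_length = 13L) {
  model <- jsonlite::read_json(require_artifact(file.path(model_dir, "model.json"),
                                                "ifs"), simplifyVector = TRUE)
  train <- read_feature_matrix(require_artifact(file.path(model_dir, "feature_matrix.tsv"),
                                                "encode"))
  inp <- read_input_dir(input_dir)
  windows <- dplyr::bind_rows(purrr::map(seq_len(nrow(inp$records)), function(i) {
    extract_windows(inp$records[i, ], target_residue, terminus_policy,
                    window_length)
  }))
  if (nrow(windows) == 0L) stop_hx("no candidate ", target_residue, " sites in input")
  fm <- encode_windows(windows, inp$aaindex, window_length)
  if (!identical(fm$descriptors$name, train$descriptors$name)) {
    stop_hx("query feature space differs from the model's training space")
  }
  pred <- nna_predict(fm$values, train, model$feature_columns)
  out <- tibble::tibble(protein_id = windows$protein_id,
                        pos = windows$center,
                        residue = target_residue,
                        predicted = pred$label,
                        nn_distance = pred$distance,
                        nn_id = pred$nn_id)
  readr::write_tsv(out, out_path)
  write_manifest(dirname(out_path), "predict",
                 inputs = list(model_dir = model_dir, input_dir = input_dir),
                 params = list(target_residue = target_residue,
                               terminus_policy = terminus_policy,
                               window_length = window_length))
  invisible(out)
}

#' Pipeline stage: feature-distribution analyses
#'
#' Computes the kind/position/cluster/PSSM-column distributions for feature
#' set A (the MaxRel list) and feature set B (the IFS-optimal prefix) and
#' writes one TSV per table.
#'
#' @inheritParams stage_rank
#' @param input_dir Input directory (for the AAindex cluster labels).
#' @return Named list of distribution tibbles, invisibly.
#' @export
stage_analyze <- function(work_dir, input_dir) {
  fm <- read_feature_matrix(require_artifact(file.path(work_dir, "feature_matrix.tsv"),
                                             "encode"))
  maxrel <- read_ranked(require_artifact(file.path(work_dir, "maxrel.tsv"), "rank"))
  model <- jsonlite::read_json(require_artifact(file.path(work_dir, "model.json"),
                                                "ifs"), simplifyVector = TRUE)
  inp <- read_input_dir(input_dir)
  universe <- fm$descriptors
  set_b <- universe[model$feature_columns, ]
  sets <- list(A = maxrel, B = set_b)
  out <- list()
  for (nm in names(sets)) {
    s <- sets[[nm]]
    out[[paste0("kind_", nm)]] <- kind_distribution(s, universe)
    out[[paste0("position_", nm)]] <- position_distribution(s, universe)
    out[[paste0("cluster_", nm)]] <- cluster_distribution(s, inp$aaindex)
    out[[paste0("pssm_column_", nm)]] <- pssm_column_distribution(s)
  }
  for (nm in names(out)) {
    readr::write_tsv(out[[nm]], file.path(work_dir, paste0("dist_", nm, ".tsv")))
  }
  write_manifest(work_dir, "analyze", inputs = list(input_dir = input_dir),
                 params = list())
  invisible(out)
}
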