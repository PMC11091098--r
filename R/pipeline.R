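#' Write a score table as a MaveDB-style CSV
#'
#' Header row, UTF-8, '.' decimal; columns `variant` (compact form, e.g.
#' `C152W`), `score`, `sd`, `n_rep`.
#'
#' @param scores tibble with at least `variant`, `score`, `sd`, `n_rep`.
#' @param path output file.
#' @export
write_score_csv <- function(scores, path) {
  stopifnot(all(c("variant", "score", "sd", "n_rep") %in% names(scores)))
  readr::write_csv(scores[, c("variant", "score", "sd", "n_rep")], path)
  invisible(path)
}

#' Read a MaveDB-style score CSV
#' @param path file written by [write_score_csv()].
#' @return Tibble with parsed variant fields attached.
#' @export
read_score_csv <- function(path) {
  scores <- readr::read_csv(path, show_col_types = FALSE)
  parsed <- parse_variant(scores$variant)
  dplyr::bind_cols(scores,
                   parsed[, c("position", "wt_aa", "alt_aa", "var_class")])
}

#' Write/read tab-separated tables
#' @param x data frame.
#' @param path file path.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' Load a simulation configuration from YAML or JSON
#'
#' File fields override the [sim_config()] defaults; unknown fields are an
#' error.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, raw)
}

#' Run the full synthetic pipeline
#'
#' Chains every stage with a single master seed: library simulation,
#' FACS-bin and time-course count simulation, predictor tracks, tile design
#' and tile sorting, abundance/toxicity/TSI scoring, structural metrics on a
#' synthetic globule, and summary analytics. All artifacts are written under
#' `outdir` together with a manifest (parameters, seed, package version).
#' Rerunning with the same config reproduces the stochastic outputs
#' byte-identically.
#'
#' @param config a [sim_config()].
#' @param outdir output directory, created if missing.
#' @param min_reads per-replicate read threshold for scoring (default 20).
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the in-memory results (`scores_abundance`,
#'   `scores_toxicity`, `tsi`, `metrics`, `summary`, `manifest`, paths).
#' @export
run_pipeline <- function(config, outdir, min_reads = 20, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  say("stage 1/6: simulating barcoded library")
  lib <- simulate_library(config)
  write_tsv_table(lib$map, file.path(outdir, "barcode_map.tsv"))
  write_tsv_table(lib$truth, file.path(outdir, "latent_truth.tsv"))

  say("stage 2/6: simulating FACS-bin and time-course counts")
  facs <- simulate_facs_counts(lib$truth, lib$map, config)
  tc <- simulate_timecourse(lib$truth, lib$map, config)
  write_tsv_table(facs, file.path(outdir, "facs_counts.tsv"))
  write_tsv_table(tc, file.path(outdir, "timecourse_counts.tsv"))

  say("stage 3/6: abundance scores (PSI normalization)")
  ab <- abundance_scores(facs, min_reads = min_reads)
  write_score_csv(ab$scores, file.path(outdir, "abundance_scores.csv"))

  say("stage 4/6: toxicity scores (depletion slopes)")
  tox <- toxicity_scores(tc, min_reads = min_reads,
                         toxic_anchor = config$toxic_anchor)
  write_score_csv(tox$scores, file.path(outdir, "toxicity_scores.csv"))

  say("stage 5/6: tile design and TSI scoring")
  tiles <- design_tiles(config$protein_seq)
  tile_sim <- simulate_tile_counts(tiles, config)
  tsi <- renormalize_tsi(tsi_table(tile_sim$counts))
  write_tsv_table(tiles, file.path(outdir, "tile_design.tsv"))
  write_tsv_table(tsi$scores, file.path(outdir, "tsi_scores.tsv"))

  say("stage 6/6: residue metrics and summary analytics")
  L <- nchar(config$protein_seq)
  globule <- make_synthetic_globule(L, seed = config$seed)
  wcn <- compute_wcn(globule)
  med_ab <- per_position_median(ab$scores)
  med_tox <- per_position_median(tox$scores)
  metrics <- tibble::tibble(position = seq_len(L)) |>
    dplyr::left_join(dplyr::rename(med_ab, median_abundance = "median_score"),
                     by = "position") |>
    dplyr::left_join(dplyr::rename(med_tox, median_toxicity = "median_score"),
                     by = "position") |>
    dplyr::select(-dplyr::any_of(c("n_variants.x", "n_variants.y",
                                   "n_variants")))
  metrics$wcn <- wcn
  write_tsv_table(metrics, file.path(outdir, "residue_metrics.tsv"))

  pred <- simulate_predictor_tracks(lib$truth, config)
  joined <- ab$scores |>
    dplyr::inner_join(pred, by = "variant")
  ve <- variance_explained(ab$scores)
  summary <- list(
    n_variants_universe = nrow(enumerate_variant_universe(config$protein_seq)),
    n_variants_scored_abundance = nrow(ab$scores),
    n_variants_scored_toxicity = nrow(tox$scores),
    abundance_vs_ddg_spearman = correlate(joined$score, joined$ddg,
                                          seed = config$seed)$estimate,
    abundance_vs_conservation_spearman =
      correlate(joined$score, joined$conservation,
                seed = config$seed)$estimate,
    variance_explained_r = ve$r,
    variance_explained_r_squared = ve$r_squared,
    abundance_replicate_pearson =
      replicate_stats(ab$replicate_scores)$mean_r,
    toxicity_replicate_pearson =
      replicate_stats(tox$replicate_scores)$mean_r)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "vampseqr",
    version = as.character(utils::packageVersion("vampseqr")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "protein_seq")],
    protein_length = L,
    outputs = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(scores_abundance = ab, scores_toxicity = tox, tsi = tsi,
                 metrics = metrics, summary = summary, manifest = manifest,
                 outdir = outdir))
}
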