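#' Run the full demo analysis pipeline and write its outputs
#'
#' Simulates the three synthetic inputs (repertoire timeline,
#' integration-site reads, cell table) under one master seed, runs every
#' analysis arm — repertoire diversity/overlap metrics and rank tracks,
#' absolute-count clone kinetics, integration-site clone calling, and
#' the clonotype-fate analysis — and writes all outputs as
#' tab-separated tables plus a JSON manifest recording the seed,
#' parameter values and input checksums. Identical configuration and
#' seed give identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param n_isa_sites Integration sites planted in the ISA simulation.
#' @param isa_genome_length Toy genome length (bp).
#' @param n_cells_per_timepoint Cells per timepoint in the cell table.
#' @param n_reps Downsampling replicates for the entropy metrics.
#' @param fold_threshold Kinetic classification fold threshold.
#' @param weight_kg,sex,dose,car_counts Patient metadata for the
#'   absolute-count conversion.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         n_isa_sites = 25, isa_genome_length = 5e4,
                         n_cells_per_timepoint = 2000, n_reps = 200,
                         fold_threshold = 2,
                         weight_kg = 70, sex = "male", dose = 5e8,
                         car_counts = c(early = 80, late = 15)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(seed = seed, n_isa_sites = n_isa_sites,
                 isa_genome_length = isa_genome_length,
                 n_cells_per_timepoint = n_cells_per_timepoint,
                 n_reps = n_reps, fold_threshold = fold_threshold,
                 weight_kg = weight_kg, sex = sex, dose = dose,
                 car_counts = as.list(car_counts))

  rep_sim <- sim_demo_repertoire(seed = seed)
  readr::write_tsv(rep_sim$samples, file.path(out_dir, "repertoire_samples.tsv"))
  readr::write_tsv(rep_sim$truth, file.path(out_dir, "repertoire_truth.tsv"))

  metrics <- repertoire_metrics(rep_sim$samples, n_reps = n_reps,
                                seed = derive_seed(seed, 21L))
  readr::write_tsv(metrics, file.path(out_dir, "repertoire_metrics.tsv"))
  readr::write_tsv(morisita_matrix(rep_sim$samples),
                   file.path(out_dir, "morisita_matrix.tsv"))
  readr::write_tsv(track_clonotype_ranks(rep_sim$samples),
                   file.path(out_dir, "rank_tracks.tsv"))

  kin <- clone_kinetics(rep_sim$samples, weight_kg = weight_kg, sex = sex,
                        dose = dose, car_counts = car_counts,
                        fold_threshold = fold_threshold)
  readr::write_tsv(dplyr::left_join(kin$tracks, kin$patterns,
                                    by = "clonotype_id"),
                   file.path(out_dir, "clone_tracks.tsv"))

  isa_sim <- sim_isa_reads(genome_length = isa_genome_length,
                           n_sites = n_isa_sites,
                           seed = derive_seed(seed, 22L))
  isa <- call_integration_sites(isa_sim$reads, isa_sim$genome,
                                isa_sim$ltr_seq, isa_sim$vector_seq,
                                linker_seq = isa_sim$linker_seq)
  readr::write_tsv(isa$sites, file.path(out_dir, "isa_sites.tsv"))
  readr::write_tsv(isa$frequencies, file.path(out_dir, "isa_frequencies.tsv"))

  cells <- sim_cell_table(rep_sim, n_cells_per_timepoint = n_cells_per_timepoint,
                          seed = derive_seed(seed, 23L))
  cells_kept <- qc_filter(cells)
  fate <- clonotype_fate_test(cells_kept)
  readr::write_tsv(tidy(fate), file.path(out_dir, "fate_labels.tsv"))
  readr::write_tsv(persistence_proportions(fate, cells_kept),
                   file.path(out_dir, "fate_persistence.tsv"))
  ip_cells <- cells_kept[cells_kept$timepoint == "IP", ]
  attribution <- if (fate$n_irf + fate$n_drf > 0) {
    cluster_attribution(fate, ip_cells)
  } else {
    tibble::tibble(label = character(), cluster = integer(),
                   n_cells = integer(), fraction = numeric())
  }
  readr::write_tsv(attribution,
                   file.path(out_dir, "fate_cluster_attribution.tsv"))
  readr::write_tsv(detected_cluster_composition(ip_cells, cells_kept),
                   file.path(out_dir, "detected_cluster_composition.tsv"))

  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "clonekin",
    version = as.character(utils::packageVersion("clonekin")),
    seed = seed,
    params = params,
    outputs = lapply(setNames(outputs, outputs), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
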