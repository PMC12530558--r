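#' Run the full synthetic analysis pipeline
#'
#' Orchestrates generate -> slice -> repair -> morphometry -> spines ->
#' electrotonics on a seeded synthetic cohort and returns (optionally
#' writes) a single summary with the headline statistics: terminal
#' diameter, terminal length fraction, spine plateau density, terminal
#' spine fraction and terminal electrotonic lengths. Deterministic for a
#' fixed configuration.
#'
#' @param config list with elements `species` ("mouse"/"human"),
#'   `n_cells`, `seed`, and optionally `soma_depth_um` (default 40),
#'   `slab_thickness_um` (300), `n_candidates` (20), `out_file` (JSON
#'   path). Alternatively the path of a JSON file holding that list.
#' @return List of class `spn_pipeline_summary` (invisibly written to
#'   `out_file` when given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  need <- c("species", "n_cells", "seed")
  if (!all(need %in% names(config)))
    stop("configuration error: need fields ", paste(need, collapse = ", "))
  species <- match.arg(config$species, c("mouse", "human"))
  n <- config$n_cells
  seed <- config$seed
  soma_depth <- config$soma_depth_um %||% 40
  slab <- config$slab_thickness_um %||% 300
  n_cand <- config$n_candidates %||% 20
  preset <- species_preset(species)

  cohort <- generate_cohort(preset, n, seed = seed)
  recs <- lapply(cohort, `[[`, "recon")
  neuron_tab <- cohort_neuron_features(recs)
  branch_tab <- cohort_branch_features(recs)

  # slice and repair the first cell as the repair demonstration
  sliced <- slice_cut(recs[[1]], slab_thickness = slab,
                      soma_depth = soma_depth)
  pool <- build_donor_pool(recs, preset$cut_z_threshold_um,
                           preset$diam_bounds_um)
  repaired <- repair_reconstruction(sliced$recon, pool, neuron_tab,
                                    n_candidates = n_cand, seed = seed)

  # spine statistics over the cohort
  sp_frac <- vapply(recs, function(rc)
    expected_spine_counts(rc, preset$spine_model)$terminal_fraction,
    numeric(1))
  areas <- unlist(lapply(cohort, function(cl) cl$spines$area_um2))

  el <- do.call(rbind, lapply(recs, electrotonic_summary,
                              passive = preset$passive))

  term_diam <- {
    d <- unlist(lapply(recs, function(rc) {
      segs <- partition_segments(rc)
      segs$end_diam_um[segs$is_terminal]
    }))
    mean(d)
  }
  summary <- structure(list(
    species = species, n_cells = n, seed = seed,
    terminal_diameter_um = term_diam,
    terminal_length_fraction =
      sum(branch_tab$total_length_um * branch_tab$terminal_length_fraction) /
      sum(branch_tab$total_length_um),
    spine_plateau_per_um = preset$spine_model$a,
    terminal_spine_fraction = mean(sp_frac),
    mean_spine_area_um2 = mean(areas),
    median_n_primaries = stats::median(neuron_tab$n_primaries),
    mean_terminal_L = mean(el$L),
    repair_score = repaired$score,
    repair_total_length_um = neuron_morphometry(repaired$recon)$total_length_um,
    unsliced_total_length_um = neuron_morphometry(recs[[1]])$total_length_um
  ), class = "spn_pipeline_summary")
  if (!is.null(config$out_file)) {
    dir.create(dirname(config$out_file), showWarnings = FALSE,
               recursive = TRUE)
    jsonlite::write_json(unclass(summary), config$out_file,
                         auto_unbox = TRUE, digits = NA)
  }
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spn_pipeline_summary <- function(x, ...) {
  cat("<spn_pipeline_summary> ", x$species, ", n = ", x$n_cells, "\n",
      sep = "")
  cat(sprintf("  terminal diameter %.2f um, terminal length fraction %.3f\n",
              x$terminal_diameter_um, x$terminal_length_fraction))
  cat(sprintf("  terminal spine fraction %.3f, mean spine area %.2f um^2\n",
              x$terminal_spine_fraction, x$mean_spine_area_um2))
  cat(sprintf("  repaired/unsliced total length: %.0f / %.0f um\n",
              x$repair_total_length_um, x$unsliced_total_length_um))
  invisible(x)
}
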