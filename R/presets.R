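#' Species parameter presets for synthetic SPN cohorts
#'
#' Bundles the generative and biophysical parameters of a species:
#' branching statistics (number of primary dendrites; branch breadth
#' frequencies), per-class segment-length distributions, diameters (the
#' subtree-law slope with a constant terminal-diameter floor), the sigmoid
#' spine-density model with spine-geometry statistics, soma radius, the
#' slice-cut detection threshold and repair diameter bounds, and passive
#' membrane constants for cable models.
#'
#' Numbers with an empirical anchor: primaries 3-8 (mouse, median 5) and
#' 3-9 (human, median 6); breadth frequencies from the per-breadth branch
#' counts of the two reconstruction datasets; terminal diameters 0.6 um
#' (mouse) and 1.0 um (human); terminal-length fractions 84% / 92% (the
#' terminal-length means are solved from the breadth counts so the
#' expected fraction hits these targets, see the vignette); spine plateau
#' densities 1.6 / 0.7 spines/um; mean spine areas 3.118 / 4.263 um^2;
#' soma mean diameters 12.9 / 17.4 um; repair diameter bounds
#' [0.376, 0.876] / [0.59, 1.26] um; cut-detection thresholds 20 / 10 um.
#' `R_m` values are calibration constants chosen so the measured terminal
#' membrane time constant is larger in human than mouse and terminal
#' electrotonic lengths are similar across species; they are not measured
#' quantities. Sigmoid half-rise `b = 35` um and scale `c = 8` um place
#' near-zero density over the first 25 um and the plateau by ~50 um.
#'
#' @param species `"mouse"` or `"human"`.
#' @return A list of class `species_preset`.
#' @export
species_preset <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  breadth_counts <- if (species == "mouse") {
    c(`1` = 8, `2` = 4, `3` = 6, `4` = 9, `5` = 6, `6` = 4, `7` = 4,
      `8` = 4, `13` = 1)
  } else {
    c(`1` = 4, `2` = 4, `3` = 9, `4` = 6, `5` = 2, `6` = 5, `7` = 1,
      `8` = 2, `15` = 1, `21` = 1)
  }
  n_primary <- if (species == "mouse") {
    list(values = 3:8, prob = c(0.10, 0.20, 0.30, 0.20, 0.12, 0.08))
  } else {
    list(values = 3:9, prob = c(0.06, 0.14, 0.20, 0.30, 0.15, 0.10, 0.05))
  }
  # terminal-length means solved from the breadth counts so the expected
  # cohort terminal-length fraction equals the species target (see vignette)
  p <- list(
    species = species,
    n_primary = n_primary,
    breadth = list(values = as.integer(names(breadth_counts)),
                   prob = unname(breadth_counts) / sum(breadth_counts)),
    len_primary_um = 25, len_primary_cv = 0.30,
    len_intermediate_um = if (species == "mouse") 20 else 25,
    len_intermediate_cv = 0.40,
    len_terminal_um = if (species == "mouse") 85.55 else 225.4,
    len_terminal_cv = 0.40,
    target_terminal_length_fraction = if (species == "mouse") 0.84 else 0.92,
    terminal_diam_um = if (species == "mouse") 0.6 else 1.0,
    subtree_k = 0.002,           # um diameter per um subtree length
    spine_model = spine_density_model(
      a = if (species == "mouse") 1.6 else 0.7, b = 35, c = 8),
    spine_area_um2 = if (species == "mouse") 3.118 else 4.263,
    spine_area_cv = 0.6,
    F_spines_mean = if (species == "mouse") 2.23 else 1.71,
    soma_radius_um = if (species == "mouse") 12.9 / 2 else 17.4 / 2,
    cut_z_threshold_um = if (species == "mouse") 20 else 10,
    diam_bounds_um = if (species == "mouse") c(0.376, 0.876) else c(0.59, 1.26),
    # passive membrane; R_m is a calibration constant (see above)
    passive = passive_params(
      R_m = if (species == "mouse") 6800 else 20000),
    syn_conductance_factor = if (species == "mouse") 1.0 else 1.37,
    # embedding: persistence of the direction random walk (aesthetic only)
    walk_sigma = 0.12, branch_sigma = 0.55, step_um = 5
  )
  class(p) <- "species_preset"
  p
}

#' @export
print.species_preset <- function(x, ...) {
  cat("<species_preset> ", x$species, "\n", sep = "")
  cat(sprintf("  terminal diameter %.1f um, terminal length mean %.1f um\n",
              x$terminal_diam_um, x$len_terminal_um))
  cat(sprintf("  spine plateau %.1f /um, mean spine area %.3f um^2\n",
              x$spine_model$a, x$spine_area_um2))
  cat(sprintf("  soma radius %.2f um, R_m %.0f Ohm cm^2\n",
              x$soma_radius_um, x$passive$R_m))
  invisible(x)
}
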