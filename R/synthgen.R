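# Synthetic SPN morphology and spine generator. Cohorts drawn from a
# species preset reproduce the preset's branching statistics, terminal
# diameters, terminal-length fraction, spine densities and spine areas,
# giving every pipeline stage a ground truth to validate against.

# lognormal parameterised by mean and coefficient of variation
rlnorm_mean <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

rand_dir <- function() unit_vec(stats::rnorm(3))

perturb_dir <- function(dir, sigma) unit_vec(dir + stats::rnorm(3, 0, sigma))

#' Sample a synthetic SPN morphology
#'
#' Grows a reconstruction by recursive branching: the number of primary
#' dendrites and each branch's breadth (terminal count) are drawn from the
#' preset's empirical distributions; a random binary topology realises
#' each breadth; segment lengths are lognormal per class (primary /
#' intermediate / terminal); node diameters follow the subtree-length law
#' `d = k * L` with a constant floor at the preset terminal diameter (so
#' terminal segments have uniform diameter); 3D embedding uses a
#' persistent random walk starting from uniformly random primary
#' directions, giving a roughly spherically symmetric field. The soma is a
#' single sphere at the origin.
#'
#' @param preset a [species_preset].
#' @param seed integer seed; fixed seed gives a bit-identical morphology.
#' @param n_primaries optionally override the sampled number of primary
#'   dendrites.
#' @return An [spn_recon] (standardised by construction: sphere soma at
#'   the origin).
#' @export
sample_morphology <- function(preset, seed = NULL, n_primaries = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_primaries))
    n_primaries <- sample(preset$n_primary$values, 1,
                          prob = preset$n_primary$prob)
  if (n_primaries < 1) stop("need at least one primary dendrite")
  rows <- new.env(parent = emptyenv())
  rows$tab <- vector("list", 4096)
  rows$n <- 0L
  push <- function(x, y, z, r, parent) {
    rows$n <- rows$n + 1L
    rows$tab[[rows$n]] <- c(x, y, z, r, parent)
    rows$n  # id
  }
  soma_id <- push(0, 0, 0, preset$soma_radius_um, -1L)
  seg_len <- function(class) {
    switch(class,
           primary = rlnorm_mean(1, preset$len_primary_um,
                                 preset$len_primary_cv),
           intermediate = rlnorm_mean(1, preset$len_intermediate_um,
                                      preset$len_intermediate_cv),
           terminal = rlnorm_mean(1, preset$len_terminal_um,
                                  preset$len_terminal_cv))
  }
  # grow one segment; returns nothing, appends rows (radii placeholder 1)
  grow <- function(pos, dir, parent_id, breadth, order) {
    if (breadth < 1) stop("unrealisable breadth: ", breadth)
    class <- if (breadth == 1L) "terminal"
      else if (order == 1L) "primary" else "intermediate"
    L <- seg_len(class)
    ds <- preset$step_um
    remaining <- L
    while (remaining > 1e-9) {
      h <- min(ds, remaining)
      pos <- pos + h * dir
      parent_id <- push(pos[1], pos[2], pos[3], 1, parent_id)
      dir <- perturb_dir(dir, preset$walk_sigma * sqrt(h / ds))
      remaining <- remaining - h
    }
    if (breadth > 1L) {
      b1 <- sample.int(breadth - 1L, 1)
      for (b in c(b1, breadth - b1))
        grow(pos, perturb_dir(dir, preset$branch_sigma), parent_id, b,
             order + 1L)
    }
    invisible(NULL)
  }
  for (i in seq_len(n_primaries)) {
    dir <- rand_dir()
    base <- preset$soma_radius_um * dir
    first_id <- push(base[1], base[2], base[3], 1, soma_id)
    grow(base, dir, first_id, sample(preset$breadth$values, 1,
                                     prob = preset$breadth$prob), 1L)
  }
  m <- do.call(rbind, rows$tab[seq_len(rows$n)])
  nodes <- data.frame(id = seq_len(rows$n),
                      type = c(1L, rep.int(3L, rows$n - 1L)),
                      x = m[, 1], y = m[, 2], z = m[, 3], r = m[, 4],
                      parent = as.integer(m[, 5]))
  rec <- spn_recon(nodes, provenance = c(
    sprintf("synthetic %s SPN", preset$species),
    if (!is.null(seed)) sprintf("seed=%d", seed)))
  assign_diameters(rec, preset)
}

# node diameters from the subtree-length law with a terminal floor
assign_diameters <- function(rec, preset) {
  nd <- rec$nodes
  pr <- parent_index(rec)
  # distal dendritic length through each node: sum of child edge lengths
  # plus child subtree lengths, computed children-first
  n <- nrow(nd)
  kids <- children_index(rec)
  sub <- numeric(n)
  # process in reverse depth-first order (parents precede children)
  for (i in rev(seq_len(n))) {
    ck <- kids[[i]]
    if (length(ck))
      sub[i] <- sum(sub[ck] + edge_length(nd, rep.int(i, length(ck)), ck))
  }
  dend <- nd$type != 1L
  d <- pmax(preset$subtree_k * sub, preset$terminal_diam_um)
  nd$r[dend] <- d[dend] / 2
  structure(list(nodes = nd, provenance = rec$provenance),
            class = "spn_recon")
}

#' Cut a reconstruction with a virtual slice surface
#'
#' Emulates the loss of the dendritic arbour nearest the upper face of a
#' tissue slice: the soma is placed `soma_depth` below the face, all
#' geometry above the face is removed, and paths crossing the face are
#' truncated at it by linear interpolation. The ids of the truncated
#' terminals (the ground-truth cut set) are recorded.
#'
#' @param recon a standardised [spn_recon] (soma at origin).
#' @param slab_thickness slice thickness, um (must exceed `soma_depth`).
#' @param soma_depth depth of the soma below the upper face, um
#'   (typically 30-50).
#' @return List with `recon` (the sliced [spn_recon]), `cut_ids`
#'   (node ids, in the sliced reconstruction, of the truncated terminals),
#'   `z_cut` (the cut plane) and `ground_truth` (the unsliced input and
#'   its per-branch morphometry).
#' @export
slice_cut <- function(recon, slab_thickness = 300, soma_depth = 40) {
  if (!(slab_thickness > soma_depth && soma_depth > 0))
    stop("need slab_thickness > soma_depth > 0")
  nd <- recon$nodes
  z_cut <- soma_depth
  if (nd$z[nd$type == 1L][1] > z_cut)
    stop("soma lies above the cut plane")
  pr <- parent_index(recon)
  above <- nd$z > z_cut
  # drop nodes above the plane and all their descendants (truncate at the
  # first crossing)
  drop <- above
  repeat {
    more <- !drop & !is.na(pr) & drop[ifelse(is.na(pr), 1L, pr)]
    more[is.na(pr)] <- FALSE
    if (!any(more)) break
    drop <- drop | more
  }
  cut_edge <- which(drop & !is.na(pr) & !drop[ifelse(is.na(pr), 1L, pr)] &
                      nd$type != 1L &
                      nd$type[ifelse(is.na(pr), 1L, pr)] != 1L)
  keep <- nd[!drop, , drop = FALSE]
  cut_ids <- integer(0)
  if (length(cut_edge)) {
    newrows <- lapply(cut_edge, function(i) {
      j <- pr[i]
      t <- (z_cut - nd$z[j]) / (nd$z[i] - nd$z[j])
      data.frame(id = 0L, type = nd$type[i],
                 x = nd$x[j] + t * (nd$x[i] - nd$x[j]),
                 y = nd$y[j] + t * (nd$y[i] - nd$y[j]),
                 z = z_cut,
                 r = nd$r[j] + t * (nd$r[i] - nd$r[j]),
                 parent = nd$id[j])
    })
    newrows <- do.call(rbind, newrows)
    newrows$id <- max(nd$id) + seq_len(nrow(newrows))
    cut_ids <- newrows$id
    keep <- rbind(keep, newrows)
  }
  rec <- renumber_recon(structure(
    list(nodes = keep,
         provenance = c(recon$provenance,
                        sprintf("slice_cut: z=%.1f um", z_cut))),
    class = "spn_recon"))
  # renumbering changed ids; recover them by position (cut nodes are the
  # terminals exactly on the plane)
  cut_ids <- rec$nodes$id[abs(rec$nodes$z - z_cut) < 1e-9 &
                            !(rec$nodes$id %in% rec$nodes$parent)]
  segs <- partition_segments(recon)
  gt_branches <- lapply(split(segs, segs$branch_id), branch_morphometry)
  list(recon = rec, cut_ids = cut_ids, z_cut = z_cut,
       ground_truth = list(unsliced = recon, branches = gt_branches))
}

#' Sample a spine inventory for a reconstruction
#'
#' Places spines by an inhomogeneous Poisson process with rate `S(x)`
#' along every dendritic segment (thinning of a homogeneous process at the
#' plateau rate), and samples per-spine geometry: total surface area
#' (lognormal at the preset mean and CV), head area (a Beta-distributed
#' fraction of the total), neck length and neck diameter.
#'
#' @param recon a standardised [spn_recon].
#' @param preset a [species_preset].
#' @param seed optional integer seed.
#' @return Data frame with columns `dendrite_id` (branch index),
#'   `distance_um`, `area_um2`, `head_area_um2`, `neck_length_um`,
#'   `neck_diameter_um`.
#' @export
sample_spines <- function(recon, preset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- preset$spine_model
  segs <- partition_segments(recon)
  out <- list()
  for (i in seq_len(NROW(segs))) {
    L <- segs$length_um[i]
    if (L <= 0) next
    n_hom <- stats::rpois(1, model$a * L)
    if (n_hom == 0) next
    x <- segs$base_dist_um[i] + stats::runif(n_hom, 0, L)
    keep <- stats::runif(n_hom) < spine_density(x, model) / model$a
    x <- x[keep]
    if (!length(x)) next
    out[[length(out) + 1L]] <-
      data.frame(dendrite_id = segs$branch_id[i], distance_um = x)
  }
  if (!length(out))
    return(data.frame(dendrite_id = integer(), distance_um = numeric(),
                      area_um2 = numeric(), head_area_um2 = numeric(),
                      neck_length_um = numeric(), neck_diameter_um = numeric()))
  sp <- do.call(rbind, out)
  n <- nrow(sp)
  sp$area_um2 <- rlnorm_mean(n, preset$spine_area_um2, preset$spine_area_cv)
  sp$head_area_um2 <- sp$area_um2 * stats::rbeta(n, 6, 4)  # head ~60% of area
  sp$neck_length_um <- rlnorm_mean(n, 1.0, 0.4)
  sp$neck_diameter_um <- rlnorm_mean(n, 0.2, 0.3)
  sp[order(sp$dendrite_id, sp$distance_um), , drop = FALSE]
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n` independent cells (morphology plus spine inventory) from one
#' master seed; per-cell seeds are derived from the master stream, so
#' regeneration with the same master seed is bit-identical. Optionally
#' writes SWC files, spine CSVs and a JSON manifest.
#'
#' @param preset a [species_preset].
#' @param n number of cells.
#' @param seed master integer seed.
#' @param out_dir optional output directory; created if missing.
#' @param spines also sample spine inventories (default `TRUE`).
#' @return List of class `spn_cohort`: per-cell lists with `recon`,
#'   `spines`, `seed`; attribute `manifest` (data frame).
#' @export
generate_cohort <- function(preset, n, seed = 1, out_dir = NULL,
                            spines = TRUE) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- sample_morphology(preset, seed = cell_seeds[i])
    sp <- if (spines) sample_spines(rec, preset, seed = cell_seeds[n + i])
      else NULL
    cells[[i]] <- list(recon = rec, spines = sp, seed = cell_seeds[i])
  }
  manifest <- data.frame(cell = seq_len(n), seed = cell_seeds[seq_len(n)],
                         species = preset$species)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      swc <- file.path(out_dir, sprintf("%s_%03d.swc", preset$species, i))
      write_swc(cells[[i]]$recon, swc)
      if (spines)
        utils::write.csv(cells[[i]]$spines,
                         file.path(out_dir,
                                   sprintf("%s_%03d_spines.csv",
                                           preset$species, i)),
                         row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  structure(cells, class = "spn_cohort", manifest = manifest)
}

#' Sample a single straight dendrite with spines
#'
#' Convenience generator for spine-density studies: one unbranched
#' dendritic path of given length, sampled at 1 um resolution, with a
#' Poisson spine inventory. Used to reproduce density-versus-distance
#' fits without growing full arbours.
#'
#' @param preset a [species_preset].
#' @param length_um dendrite length (default 400).
#' @param seed optional integer seed.
#' @return List with `recon` (an [spn_recon]) and `spines` (data frame).
#' @export
sample_dendrite <- function(preset, length_um = 400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- seq(0, length_um, by = 1)
  n <- length(xs)
  nodes <- data.frame(id = seq_len(n + 1),
                      type = c(1L, rep.int(3L, n)),
                      x = c(0, xs), y = 0, z = 0,
                      r = c(preset$soma_radius_um,
                            rep.int(preset$terminal_diam_um / 2, n)),
                      parent = c(-1L, seq_len(n)))
  rec <- spn_recon(nodes, provenance = sprintf("synthetic %s dendrite",
                                               preset$species))
  list(recon = rec, spines = sample_spines(rec, preset))
}

#' Bin a spine inventory for density fitting
#'
#' Counts spines in half-open distance bins `[lo, hi)` anchored at the
#' soma and accumulates the dendritic length sampled in each bin, the
#' input needed by [fit_spine_density].
#'
#' @param spines data frame with `distance_um` (e.g. [sample_spines]).
#' @param recon the reconstruction the spines live on.
#' @param bin_width bin width, um (default 10).
#' @return Data frame `x_um` (bin centre), `count`, `length_um`.
#' @export
bin_spine_counts <- function(spines, recon, bin_width = 10) {
  segs <- partition_segments(recon)
  max_dist <- max(segs$base_dist_um + segs$length_um)
  breaks <- seq(0, bin_width * ceiling(max_dist / bin_width), by = bin_width)
  nb <- length(breaks) - 1L
  len <- numeric(nb)
  for (i in seq_len(NROW(segs))) {
    lo <- segs$base_dist_um[i]
    hi <- lo + segs$length_um[i]
    len <- len + pmax(0, pmin(hi, breaks[-1]) - pmax(lo, breaks[-length(breaks)]))
  }
  cnt <- tabulate(findInterval(spines$distance_um, breaks,
                               rightmost.closed = FALSE), nbins = nb)
  data.frame(x_um = breaks[-length(breaks)] + bin_width / 2,
             count = cnt, length_um = len)
}
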