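# Detection and repair of slice-cut dendrites: cut terminals near the
# upper slice face are extended by grafting order-matched intact branch
# material, and candidate repairs are scored against mirror-predicted
# morphometry.

#' Detect slice-cut terminals
#'
#' Flags dendritic terminal nodes lying within `z_threshold` of the
#' maximal z coordinate of the reconstruction, the signature of dendrites
#' truncated at the upper face of the slice.
#'
#' @param recon a standardised [spn_recon].
#' @param z_threshold detection band below the top of the reconstruction,
#'   um (20 for mouse, 10 for human material).
#' @return List of class `cut_report`: `cut_node_ids`, `z_threshold`,
#'   `z_max`.
#' @export
detect_cut_points <- function(recon, z_threshold) {
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stop("z_threshold must be positive")
  nd <- recon$nodes
  kids <- children_index(recon)
  term <- which(lengths(kids) == 0L & nd$type != 1L)
  z_max <- max(nd$z)
  flagged <- term[nd$z[term] >= z_max - z_threshold]
  structure(list(cut_node_ids = nd$id[flagged], z_threshold = z_threshold,
                 z_max = z_max), class = "cut_report")
}

#' @export
print.cut_report <- function(x, ...) {
  cat("<cut_report> ", length(x$cut_node_ids), " cut terminal(s), z_max ",
      sprintf("%.1f", x$z_max), " um, threshold ", x$z_threshold, " um\n",
      sep = "")
  invisible(x)
}

#' Build a pool of intact donor branches
#'
#' Collects, over a cohort of reconstructions, every dendritic branch that
#' contains no flagged cut point. The pool is indexed by the centrifugal
#' orders available inside each branch and carries the species terminal
#' diameter bounds used to discard implausible grafts.
#'
#' @param recons list of standardised [spn_recon]s.
#' @param z_threshold cut-detection band passed to [detect_cut_points].
#' @param diameter_bounds numeric length-2: admissible terminal diameter
#'   range after graft scaling, um.
#' @return List of class `donor_pool`: `branches` (each with `recon`,
#'   `segments`, `orders`), `diameter_bounds`, `z_threshold`.
#' @export
build_donor_pool <- function(recons, z_threshold,
                             diameter_bounds = c(0.376, 0.876)) {
  if (inherits(recons, "spn_recon")) recons <- list(recons)
  if (inherits(recons, "spn_cohort")) recons <- lapply(recons, `[[`, "recon")
  branches <- list()
  for (rc in recons) {
    rep_ <- detect_cut_points(rc, z_threshold)
    segs <- partition_segments(rc)
    cut_rows <- match(rep_$cut_node_ids, rc$nodes$id)
    ends <- vapply(segs$path, function(p) p[length(p)], integer(1))
    cut_branches <- unique(segs$branch_id[ends %in% cut_rows])
    for (b in setdiff(unique(segs$branch_id), cut_branches)) {
      bs <- segs[segs$branch_id == b, , drop = FALSE]
      branches[[length(branches) + 1L]] <-
        list(recon = rc, segments = bs, orders = sort(unique(bs$order)))
    }
  }
  if (!length(branches))
    stop("empty donor pool: every branch in the cohort contains a cut point; ",
         "supply additional intact reconstructions")
  structure(list(branches = branches, diameter_bounds = diameter_bounds,
                 z_threshold = z_threshold), class = "donor_pool")
}

#' @export
print.donor_pool <- function(x, ...) {
  cat("<donor_pool> ", length(x$branches), " intact branches, ",
      "terminal diameter bounds [", x$diameter_bounds[1], ", ",
      x$diameter_bounds[2], "] um\n", sep = "")
  invisible(x)
}

# keep geometry with z <= plane; paths truncated at the first crossing
clip_recon_above <- function(recon, z_plane = 0) {
  nd <- recon$nodes
  pr <- parent_index(recon)
  drop <- nd$z > z_plane & nd$type != 1L
  repeat {
    more <- !drop & !is.na(pr) & drop[ifelse(is.na(pr), 1L, pr)]
    more[is.na(pr)] <- FALSE
    if (!any(more)) break
    drop <- drop | more
  }
  # interpolate only on dendritic cable: an edge leaving the soma sphere
  # carries no length, so a primary lost at its base leaves no stub
  cut_edge <- which(drop & !is.na(pr) & !drop[ifelse(is.na(pr), 1L, pr)] &
                      nd$type[ifelse(is.na(pr), 1L, pr)] != 1L)
  keep <- nd[!drop, , drop = FALSE]
  if (length(cut_edge)) {
    newrows <- do.call(rbind, lapply(cut_edge, function(i) {
      j <- pr[i]
      t <- (z_plane - nd$z[j]) / (nd$z[i] - nd$z[j])
      data.frame(id = 0L, type = nd$type[i],
                 x = nd$x[j] + t * (nd$x[i] - nd$x[j]),
                 y = nd$y[j] + t * (nd$y[i] - nd$y[j]),
                 z = z_plane,
                 r = nd$r[j] + t * (nd$r[i] - nd$r[j]),
                 parent = nd$id[j])
    }))
    newrows$id <- max(nd$id) + seq_len(nrow(newrows))
    keep <- rbind(keep, newrows)
  }
  renumber_recon(structure(list(nodes = keep, provenance = recon$provenance),
                           class = "spn_recon"))
}

#' Predict whole-cell morphometry from the intact half
#'
#' The dendritic field of an SPN is spherically symmetric on average, so
#' the morphometry of a sliced cell can be predicted from its intact
#' lower half: the geometry with `z <= 0` (paths truncated at the soma
#' plane) is united with its z-mirror image and measured.
#'
#' @param recon a standardised [spn_recon] (soma at origin).
#' @return A [neuron_morphometry] of the mirrored half-reconstruction.
#' @export
predict_morphometry <- function(recon) {
  half <- clip_recon_above(recon, 0)
  if (sum(half$nodes$type != 1L) == 0L)
    stop("no dendrite below z = 0: cannot build a half-reconstruction")
  nd <- half$nodes
  mirror <- nd[nd$type != 1L, , drop = FALSE]
  idmax <- max(nd$id)
  soma_id <- nd$id[nd$type == 1L][1]
  map <- stats::setNames(mirror$id + idmax, mirror$id)
  mirror$id <- mirror$id + idmax
  mirror$parent <- ifelse(mirror$parent == soma_id, soma_id,
                          mirror$parent + idmax)
  mirror$z <- -mirror$z
  union <- structure(list(nodes = rbind(nd, mirror),
                          provenance = c(recon$provenance, "z-mirror union")),
                     class = "spn_recon")
  neuron_morphometry(renumber_recon(union))
}

# rotation matrix taking unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- unit_vec(u); v <- unit_vec(v)
  cth <- sum(u * v)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- unit_vec(a - sum(a * u) * u)
    return(2 * outer(w, w) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

# tangent direction of the last `window` um leading into a terminal node
terminal_tangent <- function(recon, term_row, window = 3) {
  nd <- recon$nodes
  pr <- parent_index(recon)
  path <- term_row
  cur <- term_row
  len <- 0
  while (!is.na(pr[cur]) && nd$type[pr[cur]] != 1L && len < window) {
    len <- len + edge_length(nd, cur, pr[cur])
    cur <- pr[cur]
    path <- c(cur, path)
  }
  p0 <- c(nd$x[path[1]], nd$y[path[1]], nd$z[path[1]])
  p1 <- c(nd$x[term_row], nd$y[term_row], nd$z[term_row])
  if (sum((p1 - p0)^2) < 1e-12) return(c(0, 0, 1))
  unit_vec(p1 - p0)
}

#' Graft donor material onto a cut terminal
#'
#' Copies the part of a donor branch distal to an attachment node of the
#' same centrifugal order as the cut terminal, rigidly moves it so the
#' attachment point continues the cut terminal along its end tangent, and
#' scales all grafted diameters by
#' `(arc-weighted mean diameter of the cut segment) / (donor diameter at
#' the attachment node)` to make the junction diameter-continuous. The
#' graft is rejected when a scaled grafted terminal diameter falls
#' outside `bounds`.
#'
#' @param recon an [spn_recon] with at least one cut terminal.
#' @param cut_node_id id of the cut terminal node.
#' @param donor one branch entry of a [build_donor_pool] pool.
#' @param bounds admissible terminal diameter range after scaling, um.
#' @return The repaired [spn_recon], or `NULL` when the donor has no
#'   material of the required order or the scaled graft violates the
#'   bounds (caller retries another donor).
#' @export
graft <- function(recon, cut_node_id, donor, bounds) {
  nd <- recon$nodes
  cut_row <- match(cut_node_id, nd$id)
  if (is.na(cut_row)) stop("cut node id ", cut_node_id, " not present")
  segs <- partition_segments(recon)
  ends <- vapply(segs$path, function(p) p[length(p)], integer(1))
  iseg <- which(ends == cut_row)
  if (length(iseg) != 1L) stop("cut node is not a terminal")
  ord <- segs$order[iseg]
  target_diam <- segs$mean_diam_um[iseg]
  dsegs <- donor$segments
  cand_segs <- which(dsegs$order == ord)
  if (!length(cand_segs)) return(NULL)
  dnd <- donor$recon$nodes
  soma_rows <- which(dnd$type == 1L)
  # candidate attachment nodes: interior/end nodes of same-order donor
  # segments (a segment's structural base belongs to its parent)
  cand_nodes <- unlist(lapply(dsegs$path[cand_segs], function(p)
    if (p[1] %in% soma_rows || length(p) == 1L) p else p[-1]))
  attach <- cand_nodes[sample.int(length(cand_nodes), 1)]
  # donor subtree distal to the attachment node
  pr_d <- match(dnd$parent, dnd$id)
  in_sub <- rep(FALSE, nrow(dnd))
  in_sub[attach] <- TRUE
  repeat {
    more <- !in_sub & !is.na(pr_d) & in_sub[ifelse(is.na(pr_d), 1L, pr_d)]
    more[is.na(pr_d)] <- FALSE
    if (!any(more)) break
    in_sub <- in_sub | more
  }
  sub <- which(in_sub)
  if (length(sub) < 2L) return(NULL)  # bare node: nothing to graft
  scale <- target_diam / (2 * dnd$r[attach])
  # reject if a grafted terminal diameter leaves the species bounds
  has_kid <- dnd$id[sub] %in% dnd$parent[sub]
  term_diam <- 2 * dnd$r[sub][!has_kid] * scale
  if (any(term_diam < bounds[1] | term_diam > bounds[2])) return(NULL)
  # tangent at attachment: direction into its first child
  kids_attach <- sub[dnd$parent[sub] == dnd$id[attach]]
  base_dir <- unit_vec(c(dnd$x[kids_attach[1]] - dnd$x[attach],
                         dnd$y[kids_attach[1]] - dnd$y[attach],
                         dnd$z[kids_attach[1]] - dnd$z[attach]))
  tgt_dir <- terminal_tangent(recon, cut_row)
  R <- rotation_between(base_dir, tgt_dir)
  sub_no_attach <- setdiff(sub, attach)
  rel <- cbind(dnd$x[sub_no_attach] - dnd$x[attach],
               dnd$y[sub_no_attach] - dnd$y[attach],
               dnd$z[sub_no_attach] - dnd$z[attach]) %*% t(R)
  newid <- max(nd$id) + seq_along(sub_no_attach)
  idmap <- stats::setNames(newid, dnd$id[sub_no_attach])
  idmap[as.character(dnd$id[attach])] <- cut_node_id
  newrows <- data.frame(
    id = newid, type = 3L,
    x = nd$x[cut_row] + rel[, 1],
    y = nd$y[cut_row] + rel[, 2],
    z = nd$z[cut_row] + rel[, 3],
    r = dnd$r[sub_no_attach] * scale,
    parent = as.integer(idmap[as.character(dnd$parent[sub_no_attach])]))
  out <- structure(list(nodes = rbind(nd, newrows),
                        provenance = recon$provenance),
                   class = "spn_recon")
  attr(out, "graft_scale") <- scale
  out
}

#' Repair a sliced reconstruction
#'
#' Generates `n_candidates` full repairs with random donor choices (every
#' cut terminal extended by [graft]), scores each candidate's
#' morphometry against the mirror prediction of the input
#' ([predict_morphometry]) as an aggregate of feature `|Z|` values with
#' SDs taken from the intact reference cohort, and returns the
#' best-scoring candidate, post-processed by [resample] (3 um, 1.01).
#'
#' @param recon a standardised [spn_recon].
#' @param pool a [build_donor_pool] pool.
#' @param reference data frame of [neuron_morphometry] features over the
#'   intact cohort (rows = cells), the source of the Z-score SDs.
#' @param n_candidates number of seeded random repairs (default 100).
#' @param seed integer seed for donor selection.
#' @param max_donor_tries donors attempted per cut point before a
#'   candidate is abandoned (default 25).
#' @param cut_report optional precomputed [detect_cut_points] report;
#'   detection on intact cells always flags the topmost terminals, so a
#'   curated (possibly empty) report can be passed instead.
#' @return List of class `spn_repair`: `recon` (repaired, resampled),
#'   `graft_log` (data frame: candidate, cut id, donor index, scale),
#'   `score`, `prediction`, `n_rejected`.
#' @export
repair_reconstruction <- function(recon, pool, reference,
                                  n_candidates = 100, seed = 1,
                                  max_donor_tries = 25, cut_report = NULL) {
  rep_ <- if (is.null(cut_report)) detect_cut_points(recon, pool$z_threshold)
    else cut_report
  if (!length(rep_$cut_node_ids))
    return(structure(list(recon = recon,
                          graft_log = data.frame(), score = 0,
                          prediction = NULL, n_rejected = 0L),
                     class = "spn_repair"))
  score_feats <- c("total_length_um", "n_terminals", "max_order",
                   "n_bifurcations", "max_breadth", "mean_terminal_length_um")
  pred <- predict_morphometry(recon)
  mu <- unlist(pred[score_feats])
  sd_ <- vapply(score_feats, function(f) stats::sd(reference[[f]]), numeric(1))
  sd_[!is.finite(sd_) | sd_ == 0] <- NA_real_
  set.seed(seed)
  best <- NULL
  best_score <- Inf
  best_log <- NULL
  n_rejected <- 0L
  for (cand in seq_len(n_candidates)) {
    cur <- recon
    log_rows <- list()
    ok <- TRUE
    for (cut_id in rep_$cut_node_ids) {
      done <- FALSE
      for (try in seq_len(max_donor_tries)) {
        di <- sample.int(length(pool$branches), 1)
        res <- graft(cur, cut_id, pool$branches[[di]],
                     pool$diameter_bounds)
        if (!is.null(res)) {
          log_rows[[length(log_rows) + 1L]] <-
            data.frame(candidate = cand, cut_id = cut_id, donor = di,
                       scale = attr(res, "graft_scale"))
          cur <- res
          done <- TRUE
          break
        }
      }
      if (!done) { ok <- FALSE; break }
    }
    if (!ok) { n_rejected <- n_rejected + 1L; next }
    nm <- neuron_morphometry(cur)
    z <- (unlist(nm[score_feats]) - mu) / sd_
    score <- sum(abs(z), na.rm = TRUE)
    if (score < best_score) {
      best_score <- score
      best <- cur
      best_log <- do.call(rbind, log_rows)
    }
  }
  if (is.null(best))
    stop("all ", n_candidates, " repair candidates rejected ",
         "(diameter bounds or missing donor orders); ",
         n_rejected, " rejections")
  structure(list(recon = resample(best, 3, 1.01), graft_log = best_log,
                 score = best_score, prediction = pred,
                 n_rejected = n_rejected),
            class = "spn_repair")
}

#' @export
print.spn_repair <- function(x, ...) {
  cat("<spn_repair> ", NROW(x$graft_log), " graft(s), score ",
      sprintf("%.2f", x$score), ", ", x$n_rejected,
      " candidate(s) rejected\n", sep = "")
  invisible(x)
}

#' Validate a repaired cohort against complete branches
#'
#' Compares the mean per-branch morphometric features of repaired
#' reconstructions with the distribution of the same features over
#' complete (uncut) branches, as per-feature Z-scores.
#'
#' @param repaired list of repaired [spn_recon]s (or `spn_repair`
#'   objects).
#' @param complete_branch_features data frame of [branch_morphometry]
#'   features over complete branches (one row per branch).
#' @return Data frame: `feature`, `repaired_mean`, `complete_mean`,
#'   `complete_sd`, `z`.
#' @export
validate_repair <- function(repaired, complete_branch_features) {
  recs <- lapply(repaired, function(r)
    if (inherits(r, "spn_repair")) r$recon else r)
  feats <- do.call(rbind, lapply(recs, function(rc) {
    segs <- partition_segments(rc)
    do.call(rbind, lapply(split(segs, segs$branch_id), function(bs)
      as.data.frame(unclass(branch_morphometry(bs)))))
  }))
  common <- intersect(names(feats), names(complete_branch_features))
  out <- do.call(rbind, lapply(common, function(f) {
    mu <- mean(complete_branch_features[[f]], na.rm = TRUE)
    s <- stats::sd(complete_branch_features[[f]], na.rm = TRUE)
    data.frame(feature = f, repaired_mean = mean(feats[[f]], na.rm = TRUE),
               complete_mean = mu, complete_sd = s,
               z = if (s > 0) (mean(feats[[f]], na.rm = TRUE) - mu) / s
                 else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Per-branch morphometry table of a cohort
#'
#' @param recons list of [spn_recon]s (or an `spn_cohort`).
#' @return Data frame of [branch_morphometry] features, one row per
#'   branch, with `cell` and `branch_id` columns.
#' @export
cohort_branch_features <- function(recons) {
  if (inherits(recons, "spn_cohort")) recons <- lapply(recons, `[[`, "recon")
  out <- list()
  for (i in seq_along(recons)) {
    segs <- partition_segments(recons[[i]])
    for (b in unique(segs$branch_id)) {
      bm <- branch_morphometry(segs[segs$branch_id == b, , drop = FALSE])
      out[[length(out) + 1L]] <-
        cbind(data.frame(cell = i, branch_id = b),
              as.data.frame(unclass(bm)))
    }
  }
  do.call(rbind, out)
}

#' Neuron morphometry table of a cohort
#'
#' @param recons list of [spn_recon]s (or an `spn_cohort`).
#' @return Data frame of [neuron_morphometry] features, one row per cell.
#' @export
cohort_neuron_features <- function(recons) {
  if (inherits(recons, "spn_cohort")) recons <- lapply(recons, `[[`, "recon")
  do.call(rbind, lapply(seq_along(recons), function(i)
    cbind(data.frame(cell = i),
          as.data.frame(neuron_morphometry(recons[[i]])))))
}
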