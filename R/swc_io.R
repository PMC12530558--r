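#' Read an SWC reconstruction
#'
#' Parses a standard 7-column whitespace-delimited SWC file
#' (`id type x y z radius parent`, '#' comments allowed) into an
#' [spn_recon]. The tree is validated (unique ids, one root, no cycles or
#' orphans, positive radii) and nodes are reordered so that every parent
#' precedes its children. Axonal nodes (type 2) are dropped by default
#' because downstream morphometry is dendritic.
#'
#' @param path file path.
#' @param drop_axon drop type-2 nodes (and their subtrees)? Default `TRUE`.
#' @return An [spn_recon]. Header comment lines are kept in `provenance`.
#' @export
read_swc <- function(path, drop_axon = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- sub("^#\\s?", "", grep("^\\s*#", lines, value = TRUE))
  data <- grep("^\\s*(#|$)", lines, value = TRUE, invert = TRUE)
  if (!length(data)) stop("no data rows in ", path)
  fields <- strsplit(trimws(data), "\\s+")
  if (any(lengths(fields) != 7L))
    stop("SWC rows must have 7 columns; offending line: ",
         data[which(lengths(fields) != 7L)[1]])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in ", path)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], r = m[, 6],
                      parent = as.integer(m[, 7]))
  rec <- spn_recon(nodes, provenance = header)
  if (drop_axon && any(rec$nodes$type == 2L)) rec <- drop_subtrees(rec, 2L)
  n_soma <- sum(rec$nodes$type == 1L)
  if (n_soma == 0L) stop("no soma (type 1) node in ", path)
  if (n_soma > 1L)
    rec$provenance <- c(rec$provenance, "multi-point soma (not yet collapsed)")
  renumber_recon(rec)
}

drop_subtrees <- function(rec, type_code) {
  nd <- rec$nodes
  pr <- parent_index(rec)
  drop <- nd$type == type_code
  repeat {
    more <- !drop & !is.na(pr) & drop[pmax(pr, 1L)] & !is.na(pr)
    more[is.na(pr)] <- FALSE
    if (!any(more)) break
    drop <- drop | more
  }
  keep <- nd[!drop, , drop = FALSE]
  structure(list(nodes = keep, provenance = rec$provenance), class = "spn_recon")
}

#' Write a reconstruction to SWC
#'
#' Emits standard 7-column SWC with ids renumbered 1..N depth-first and the
#' provenance written as '#' header comments. Reading the file back yields
#' an identical node table.
#'
#' @param recon an [spn_recon].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_swc <- function(recon, path) {
  rec <- renumber_recon(recon)
  nd <- rec$nodes
  con <- file(path, "w")
  on.exit(close(con))
  if (length(rec$provenance))
    writeLines(paste("#", rec$provenance), con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     nd$id, nd$type, nd$x, nd$y, nd$z, nd$r, nd$parent), con)
  invisible(path)
}

#' Standardise a reconstruction
#'
#' Applies the fixed preprocessing used before any morphometry: the
#' (possibly multi-point) soma is replaced by a single sphere whose centre
#' is the mean of the soma points and whose radius is the mean distance of
#' the soma points from that centre (a single-point soma keeps its own
#' radius); all coordinates are translated so the soma centre is the
#' origin; and z coordinates are multiplied by `shrink_z` to undo tissue
#' shrinkage (no correction in the x,y plane).
#'
#' @param recon an [spn_recon].
#' @param shrink_z positive z-shrinkage correction factor. Sections mounted
#'   in ProLong need 1.7; glycerol-mounted sections need 1 (no correction).
#' @param z_jump_fix optional function applied to the node table before
#'   standardisation, a hook for reconstruction-specific z-jump repair.
#'   The default is the identity.
#' @return A standardised [spn_recon] with the soma at the origin.
#' @export
standardize <- function(recon, shrink_z = 1, z_jump_fix = NULL) {
  if (!is.numeric(shrink_z) || length(shrink_z) != 1L || shrink_z <= 0)
    stop("shrink_z must be a positive scalar")
  nd <- recon$nodes
  if (!is.null(z_jump_fix)) nd <- z_jump_fix(nd)
  soma <- which(nd$type == 1L)
  if (!length(soma)) stop("no soma node")
  ctr <- c(mean(nd$x[soma]), mean(nd$y[soma]), mean(nd$z[soma]))
  if (length(soma) > 1L) {
    d <- sqrt((nd$x[soma] - ctr[1])^2 + (nd$y[soma] - ctr[2])^2 +
                (nd$z[soma] - ctr[3])^2)
    srad <- mean(d)
  } else {
    srad <- nd$r[soma]
  }
  if (srad <= 0) srad <- mean(nd$r[soma])
  # reattach children of any soma point to the single sphere node
  soma_ids <- nd$id[soma]
  keep <- nd[nd$type != 1L, , drop = FALSE]
  keep$parent[keep$parent %in% soma_ids] <- 0L  # placeholder for new soma id
  new_soma_id <- max(nd$id) + 1L
  keep$parent[keep$parent == 0L] <- new_soma_id
  soma_row <- data.frame(id = new_soma_id, type = 1L,
                         x = ctr[1], y = ctr[2], z = ctr[3], r = srad,
                         parent = -1L)
  nodes <- rbind(soma_row, keep)
  nodes$x <- nodes$x - ctr[1]
  nodes$y <- nodes$y - ctr[2]
  nodes$z <- (nodes$z - ctr[3]) * shrink_z
  prov <- c(recon$provenance,
            sprintf("standardized: soma sphere r=%.2f um, shrink_z=%.2f",
                    srad, shrink_z))
  renumber_recon(structure(list(nodes = nodes, provenance = prov),
                           class = "spn_recon"))
}

#' Resample a reconstruction at fixed arc-length resolution
#'
#' Re-parameterises every dendritic segment by arc length at spacing
#' `step`, preserving branch points and terminals exactly (interior sample
#' points are discarded and regenerated; radii are interpolated linearly
#' along arc length). Chord-based resampling shortens curved paths, so all
#' coordinates are then scaled about the soma by `upscale` to recover the
#' lost dendritic length. Radii are never rescaled.
#'
#' @param recon a standardised [spn_recon] (soma at the origin).
#' @param step sampling step, micrometres (default 3).
#' @param upscale coordinate scale factor applied about the soma
#'   (default 1.01, i.e. +1 percent).
#' @return A resampled [spn_recon].
#' @export
resample <- function(recon, step = 3, upscale = 1.01) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive scalar")
  if (!is.numeric(upscale) || length(upscale) != 1L || upscale <= 0)
    stop("upscale must be a positive scalar")
  nd <- recon$nodes
  soma <- which(nd$type == 1L)
  paths <- segment_paths(recon)
  new_nodes <- nd[soma, , drop = FALSE]   # keep soma as-is
  new_nodes$id <- 1L
  new_nodes$parent <- -1L
  # map from old structural node row -> new id, filled as segments are laid
  id_of <- integer(nrow(nd))
  id_of[soma] <- 1L
  next_id <- 1L
  # process segments in an order where the base is already placed
  remaining <- paths
  while (length(remaining)) {
    placed <- FALSE
    for (k in seq_along(remaining)) {
      path <- remaining[[k]]
      if (id_of[path[1]] == 0L) next
      placed <- TRUE
      remaining[[k]] <- NULL
      base_new <- id_of[path[1]]
      geo <- path
      if (geo[1] %in% soma) geo <- geo[-1]
      if (length(geo) == 1L) {
        # single-node segment directly on the soma
        next_id <- next_id + 1L
        row <- nd[geo, , drop = FALSE]
        row$id <- next_id; row$parent <- base_new
        new_nodes <- rbind(new_nodes, row)
        id_of[geo] <- next_id
        break
      }
      s <- path_cumlen(nd, geo)
      L <- s[length(s)]
      inner <- if (L > step) seq(step, L - 1e-9, by = step) else numeric()
      # drop an inner point that collides with the endpoint
      if (length(inner) && (L - inner[length(inner)]) < 1e-6 * max(1, L))
        inner <- inner[-length(inner)]
      svals <- c(inner, L)
      # a primary segment's first dendritic node is the soma attachment
      # point and is preserved exactly, like branch points and terminals
      if (path[1] %in% soma) svals <- c(0, svals)
      xs <- stats::approx(s, nd$x[geo], xout = svals)$y
      ys <- stats::approx(s, nd$y[geo], xout = svals)$y
      zs <- stats::approx(s, nd$z[geo], xout = svals)$y
      rs <- stats::approx(s, nd$r[geo], xout = svals)$y
      parent <- base_new
      for (m in seq_along(svals)) {
        next_id <- next_id + 1L
        new_nodes <- rbind(new_nodes,
                           data.frame(id = next_id, type = nd$type[geo[1]],
                                      x = xs[m], y = ys[m], z = zs[m],
                                      r = rs[m], parent = parent))
        parent <- next_id
      }
      id_of[path[length(path)]] <- next_id
      break
    }
    if (!placed) stop("internal error: disconnected segment during resample")
  }
  new_nodes$x <- new_nodes$x * upscale
  new_nodes$y <- new_nodes$y * upscale
  new_nodes$z <- new_nodes$z * upscale
  prov <- c(recon$provenance,
            sprintf("resampled: step=%g um, upscale=%g", step, upscale))
  renumber_recon(structure(list(nodes = new_nodes, provenance = prov),
                           class = "spn_recon"))
}
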