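#' Neuronal reconstruction objects
#'
#' An `spn_recon` holds a rooted tree of 3D sample points with radii, the
#' standard content of an SWC file. The root is the soma node (type 1);
#' dendritic nodes are type 3. Coordinates are micrometres and radii (not
#' diameters) are stored; every reported diameter is `2 * radius`.
#'
#' @param nodes data frame with columns `id`, `type`, `x`, `y`, `z`, `r`,
#'   `parent`. Ids must be unique positive integers; the single root has
#'   `parent = -1`; all radii must be positive.
#' @param provenance character vector of free-text processing notes
#'   (species, corrections applied), carried through all transformations.
#' @return An object of class `spn_recon`: a list with elements `nodes`
#'   (the node table, parents preceding children) and `provenance`.
#' @examples
#' nodes <- data.frame(
#'   id = 1:3, type = c(1, 3, 3),
#'   x = c(0, 5, 10), y = 0, z = 0, r = c(6, 0.5, 0.5),
#'   parent = c(-1, 1, 2))
#' rec <- spn_recon(nodes)
#' rec
#' @export
spn_recon <- function(nodes, provenance = character()) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "type", "x", "y", "z", "r", "parent")
  if (!all(need %in% names(nodes)))
    stop("nodes must have columns: ", paste(need, collapse = ", "))
  nodes <- as.data.frame(nodes)[need]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  rec <- structure(list(nodes = nodes, provenance = as.character(provenance)),
                   class = "spn_recon")
  validate_recon(rec)
  rec
}

#' @export
print.spn_recon <- function(x, ...) {
  nd <- x$nodes
  dend <- nd$type != 1L
  cat("<spn_recon> ", nrow(nd), " nodes (", sum(dend), " dendritic)\n", sep = "")
  st <- recon_structure(x)
  cat("  primaries: ", st$n_primaries,
      "  terminals: ", st$n_terminals,
      "  bifurcations: ", st$n_bifurcations, "\n", sep = "")
  cat("  total dendritic length: ",
      format(round(total_dendritic_length(x), 1)), " um\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: ", paste(x$provenance, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.spn_recon <- function(object, ...) {
  print(object, ...)
  invisible(neuron_morphometry(object))
}

# ---- internal tree machinery -------------------------------------------------

validate_recon <- function(rec) {
  nd <- rec$nodes
  if (anyDuplicated(nd$id))
    stop("duplicate node id: ", nd$id[duplicated(nd$id)][1])
  if (any(nd$r <= 0))
    stop("non-positive radius at node id ", nd$id[nd$r <= 0][1])
  root <- which(nd$parent == -1L)
  if (length(root) != 1L)
    stop("reconstruction must have exactly one root, found ", length(root))
  if (any(nd$parent == nd$id))
    stop("node is its own parent: id ", nd$id[nd$parent == nd$id][1])
  pr <- match(nd$parent, nd$id)
  orphan <- which(is.na(pr) & nd$parent != -1L)
  if (length(orphan))
    stop("orphan node id ", nd$id[orphan[1]], ": parent ",
         nd$parent[orphan[1]], " not present")
  # reachability from root (also rules out cycles)
  n <- nrow(nd)
  depth <- rep.int(NA_integer_, n)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    kids <- which(pr %in% frontier & is.na(depth))
    if (!length(kids)) break
    depth[kids] <- 1L
    frontier <- kids
  }
  if (anyNA(depth)) {
    bad <- nd$id[which(is.na(depth))[1]]
    stop("cycle or disconnected component involving node id ", bad)
  }
  invisible(TRUE)
}

root_index <- function(rec) which(rec$nodes$parent == -1L)

# row index of each node's parent (NA for root)
parent_index <- function(rec) match(rec$nodes$parent, rec$nodes$id)

children_index <- function(rec) {
  pr <- parent_index(rec)
  n <- nrow(rec$nodes)
  kids <- vector("list", n)
  ok <- which(!is.na(pr))
  sp <- split(ok, pr[ok])
  kids[as.integer(names(sp))] <- sp
  kids
}

edge_length <- function(nd, i, j) {
  sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 + (nd$z[i] - nd$z[j])^2)
}

# Sum of dendrite-to-dendrite edge lengths. Edges leaving the soma sphere are
# not dendritic cable and are excluded everywhere lengths are reported.
total_dendritic_length <- function(rec) {
  nd <- rec$nodes
  pr <- parent_index(rec)
  i <- which(!is.na(pr) & nd$type != 1L & nd$type[pr] != 1L)
  if (!length(i)) return(0)
  sum(edge_length(nd, i, pr[i]))
}

# quick structural counts without full segment partition
recon_structure <- function(rec) {
  nd <- rec$nodes
  kids <- children_index(rec)
  root <- root_index(rec)
  dend <- which(nd$type != 1L)
  nkids <- lengths(kids)
  terminals <- intersect(dend, which(nkids == 0L))
  bifs <- intersect(dend, which(nkids >= 2L))
  list(n_primaries = length(kids[[root]]),
       n_terminals = length(terminals),
       n_bifurcations = length(bifs),
       terminal_rows = terminals,
       bifurcation_rows = bifs)
}

# Decompose the dendritic tree into unbranched segments between structural
# points (soma, branch points, terminals). Returns a list of integer vectors
# of row indices; each path starts at its structural base node (the soma row
# for primary segments) and ends at the next structural node.
segment_paths <- function(rec) {
  nd <- rec$nodes
  kids <- children_index(rec)
  root <- root_index(rec)
  nkids <- lengths(kids)
  paths <- list()
  # stack of (base structural node, first node of segment)
  stack <- lapply(kids[[root]], function(k) c(root, k))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    path <- top
    cur <- path[length(path)]
    while (nkids[cur] == 1L) {
      cur <- kids[[cur]][1]
      path <- c(path, cur)
    }
    paths[[length(paths) + 1L]] <- path
    if (nkids[cur] >= 2L)
      for (k in kids[[cur]]) stack[[length(stack) + 1L]] <- c(cur, k)
  }
  paths
}

# Arc length of a segment path. The leading soma row of primary segments
# contributes no cable, so start measuring at the first dendritic node.
path_arclength <- function(nd, path, soma_rows) {
  if (path[1] %in% soma_rows) path <- path[-1]
  if (length(path) < 2L) return(0)
  i <- path[-1]; j <- path[-length(path)]
  sum(edge_length(nd, i, j))
}

# cumulative arc positions along a path (0 at first point kept)
path_cumlen <- function(nd, path) {
  if (length(path) < 2L) return(0)
  i <- path[-1]; j <- path[-length(path)]
  c(0, cumsum(edge_length(nd, i, j)))
}

# Renumber nodes depth-first from the root so parents precede children,
# ids 1..N. Returns a new spn_recon.
renumber_recon <- function(rec) {
  nd <- rec$nodes
  kids <- children_index(rec)
  root <- root_index(rec)
  order <- integer(nrow(nd))
  cnt <- 0L
  stack <- root
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    cnt <- cnt + 1L
    order[cnt] <- cur
    ck <- kids[[cur]]
    if (length(ck)) stack <- c(stack, rev(ck))
  }
  new <- nd[order, , drop = FALSE]
  newid <- seq_len(nrow(new))
  map <- integer(nrow(nd))
  map[order] <- newid
  new$id <- newid
  new$parent <- ifelse(new$parent == -1L, -1L, map[match(new$parent, nd$id)])
  rownames(new) <- NULL
  structure(list(nodes = new, provenance = rec$provenance), class = "spn_recon")
}
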