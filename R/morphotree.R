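#' Decompose a reconstruction into dendritic segments
#'
#' A segment is the portion of a dendrite between two structural points
#' (soma, branch point or terminal tip). Each segment carries its
#' centrifugal branch order (primary dendrite = 1), its centripetal
#' breadth (number of terminal tips distal to it; terminal = 1), arc
#' length, base/end/mean diameters and its path distance from the soma.
#'
#' @param recon a standardised [spn_recon].
#' @return A data frame of class `spn_segments`, one row per segment, with
#'   columns `seg_id`, `parent_seg` (NA for primaries), `branch_id` (index
#'   of the primary dendrite the segment belongs to), `order`, `breadth`,
#'   `length_um`, `base_diam_um`, `end_diam_um`, `mean_diam_um`
#'   (arc-length-weighted), `base_dist_um` (path distance from the soma to
#'   the segment base), `subtree_length_um` (total dendritic length distal
#'   to the segment base, including the segment itself), `is_terminal`,
#'   `is_primary`, and a list column `path` of node row indices (starting
#'   at the structural base node).
#' @export
partition_segments <- function(recon) {
  nd <- recon$nodes
  soma <- which(nd$type == 1L)
  paths <- segment_paths(recon)
  n <- length(paths)
  if (n == 0L) {
    out <- data.frame(seg_id = integer(), parent_seg = integer(),
                      branch_id = integer(), order = integer(),
                      breadth = integer(), length_um = numeric(),
                      base_diam_um = numeric(), end_diam_um = numeric(),
                      mean_diam_um = numeric(), base_dist_um = numeric(),
                      subtree_length_um = numeric(), is_terminal = logical(),
                      is_primary = logical())
    out$path <- list()
    class(out) <- c("spn_segments", "data.frame")
    return(out)
  }
  base_node <- vapply(paths, function(p) p[1], integer(1))
  end_node <- vapply(paths, function(p) p[length(p)], integer(1))
  parent_seg <- match(base_node, end_node)        # NA for primaries
  is_primary <- base_node %in% soma
  len <- vapply(paths, function(p) path_arclength(nd, p, soma), numeric(1))
  kids_per_seg <- lapply(seq_len(n), function(i) which(parent_seg == i))
  is_terminal <- lengths(kids_per_seg) == 0L
  # centrifugal order by walking down from primaries
  ord <- integer(n)
  ord[is_primary] <- 1L
  queue <- which(is_primary)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (k in kids_per_seg[[i]]) {
      ord[k] <- ord[i] + 1L
      queue <- c(queue, k)
    }
  }
  # centripetal breadth and inclusive subtree length, leaves upward
  breadth <- integer(n)
  subtree <- numeric(n)
  done <- is_terminal
  breadth[done] <- 1L
  subtree[done] <- len[done]
  while (!all(done)) {
    ready <- which(!done & vapply(kids_per_seg, function(k) all(done[k]),
                                  logical(1)))
    for (i in ready) {
      breadth[i] <- sum(breadth[kids_per_seg[[i]]])
      subtree[i] <- len[i] + sum(subtree[kids_per_seg[[i]]])
      done[i] <- TRUE
    }
  }
  branch_id <- integer(n)
  branch_id[is_primary] <- seq_len(sum(is_primary))
  queue <- which(is_primary)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (k in kids_per_seg[[i]]) {
      branch_id[k] <- branch_id[i]
      queue <- c(queue, k)
    }
  }
  base_dist <- numeric(n)
  for (i in order(ord))  # parents (lower order) first
    if (!is.na(parent_seg[i])) base_dist[i] <- base_dist[parent_seg[i]] +
      len[parent_seg[i]]
  diam <- function(p) {
    geo <- if (p[1] %in% soma) p[-1] else p
    d <- 2 * nd$r[geo]
    if (length(geo) == 1L)
      return(c(base = d, end = d, mean = d))
    s <- path_cumlen(nd, geo)
    w <- diff(s)
    mids <- (d[-1] + d[-length(d)]) / 2
    c(base = d[1], end = d[length(d)],
      mean = if (sum(w) > 0) sum(mids * w) / sum(w) else mean(d))
  }
  dm <- t(vapply(paths, diam, numeric(3)))
  out <- data.frame(seg_id = seq_len(n), parent_seg = parent_seg,
                    branch_id = branch_id, order = ord, breadth = breadth,
                    length_um = len, base_diam_um = dm[, 1],
                    end_diam_um = dm[, 2], mean_diam_um = dm[, 3],
                    base_dist_um = base_dist, subtree_length_um = subtree,
                    is_terminal = is_terminal, is_primary = is_primary)
  out$path <- paths
  class(out) <- c("spn_segments", "data.frame")
  out
}

#' Morphometry of one dendritic branch
#'
#' Summarises the segments of a single dendritic branch (a primary
#' dendrite and its whole subtree).
#'
#' @param branch_segments rows of a [partition_segments] table belonging
#'   to one `branch_id`.
#' @return A list of class `branch_morphometry`: `total_length_um`,
#'   `n_terminals`, `max_order`, `mean_segment_length_um`,
#'   `mean_terminal_length_um`, `terminal_length_fraction` (in `[0, 1]`).
#' @export
branch_morphometry <- function(branch_segments) {
  segs <- branch_segments
  if (NROW(segs) == 0L) stop("empty segment set")
  if (length(unique(segs$branch_id)) != 1L)
    stop("segments of more than one branch supplied")
  tl <- sum(segs$length_um)
  term <- segs$length_um[segs$is_terminal]
  structure(list(
    total_length_um = tl,
    n_terminals = sum(segs$is_terminal),
    max_order = max(segs$order),
    mean_segment_length_um = mean(segs$length_um),
    mean_terminal_length_um = mean(term),
    terminal_length_fraction = if (tl > 0) sum(term) / tl else NA_real_
  ), class = "branch_morphometry")
}

#' @export
print.branch_morphometry <- function(x, ...) {
  cat("<branch_morphometry>\n")
  cat(sprintf("  total length %.1f um, %d terminals, max order %d\n",
              x$total_length_um, x$n_terminals, x$max_order))
  cat(sprintf("  terminal length fraction %.3f\n", x$terminal_length_fraction))
  invisible(x)
}

#' Whole-neuron morphometry
#'
#' Aggregate morphometric features over all dendritic branches: counts of
#' primaries, bifurcations and terminals, maximal centrifugal order and
#' centripetal breadth, total dendritic length, mean terminal segment
#' length and the mean branching ratio.
#'
#' @param recon a standardised [spn_recon].
#' @param branching_ratio `"daughters"` (default): mean number of daughter
#'   segments per bifurcation; `"terminals_per_primary"`: mean number of
#'   terminal tips per primary dendrite.
#' @return A list of class `neuron_morphometry` with fields `n_primaries`,
#'   `n_bifurcations`, `n_terminals`, `max_order`, `max_breadth`,
#'   `total_length_um`, `mean_terminal_length_um`, `mean_branching_ratio`.
#' @export
neuron_morphometry <- function(recon,
                               branching_ratio = c("daughters",
                                                   "terminals_per_primary")) {
  branching_ratio <- match.arg(branching_ratio)
  segs <- partition_segments(recon)
  if (NROW(segs) == 0L)
    return(structure(list(n_primaries = 0L, n_bifurcations = 0L,
                          n_terminals = 0L, max_order = 0L, max_breadth = 0L,
                          total_length_um = 0, mean_terminal_length_um = NA_real_,
                          mean_branching_ratio = NA_real_),
                     class = "neuron_morphometry"))
  daughters <- table(segs$parent_seg[!is.na(segs$parent_seg)])
  br <- switch(branching_ratio,
               daughters = if (length(daughters)) mean(daughters) else NA_real_,
               terminals_per_primary = sum(segs$is_terminal) /
                 sum(segs$is_primary))
  structure(list(
    n_primaries = sum(segs$is_primary),
    n_bifurcations = length(daughters),
    n_terminals = sum(segs$is_terminal),
    max_order = max(segs$order),
    max_breadth = max(segs$breadth),
    total_length_um = sum(segs$length_um),
    mean_terminal_length_um = mean(segs$length_um[segs$is_terminal]),
    mean_branching_ratio = as.numeric(br)
  ), class = "neuron_morphometry")
}

#' @export
print.neuron_morphometry <- function(x, ...) {
  cat("<neuron_morphometry>\n")
  cat(sprintf("  %d primaries, %d bifurcations, %d terminals\n",
              x$n_primaries, x$n_bifurcations, x$n_terminals))
  cat(sprintf("  max order %d, max breadth %d\n", x$max_order, x$max_breadth))
  cat(sprintf("  total length %.1f um, mean terminal length %.1f um\n",
              x$total_length_um, x$mean_terminal_length_um))
  invisible(x)
}

#' @export
as.data.frame.neuron_morphometry <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Sholl analysis
#'
#' Counts dendritic crossings of concentric spheres centred at the soma.
#' Crossings are found as sign changes of `(||p|| - r)` along each
#' dendritic edge (Euclidean radial distance, the standard convention).
#'
#' @param recon a standardised [spn_recon] (soma at origin).
#' @param step radius increment in micrometres (default 10).
#' @param max_radius largest radius; default: smallest multiple of `step`
#'   at or beyond the most distal node.
#' @return Data frame with columns `radius_um` and `crossings`.
#' @export
sholl <- function(recon, step = 10, max_radius = NULL) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive scalar")
  nd <- recon$nodes
  pr <- parent_index(recon)
  dend_edge <- which(!is.na(pr) & nd$type != 1L & nd$type[pr] != 1L)
  rad <- sqrt(nd$x^2 + nd$y^2 + nd$z^2)
  rmax_node <- if (any(nd$type != 1L)) max(rad[nd$type != 1L]) else 0
  if (is.null(max_radius)) max_radius <- step * max(1, ceiling(rmax_node / step))
  radii <- seq(step, max_radius, by = step)
  if (!length(dend_edge))
    return(data.frame(radius_um = radii, crossings = 0L))
  r1 <- rad[pr[dend_edge]]
  r2 <- rad[dend_edge]
  lo <- pmin(r1, r2)
  hi <- pmax(r1, r2)
  crossings <- vapply(radii, function(r) sum(lo < r & hi >= r), integer(1))
  data.frame(radius_um = radii, crossings = crossings)
}

#' Z-scores of morphometric features against a reference population
#'
#' @param candidate a [neuron_morphometry] / [branch_morphometry] object,
#'   or a named numeric vector of features.
#' @param reference data frame of the same features over a reference
#'   population (one row per cell or branch).
#' @return A list with `z` (named vector; features with zero reference SD
#'   are `NA`), `excluded` (names of zero-SD features) and `aggregate`
#'   (sum of `|z|` over non-excluded features).
#' @export
zscore_features <- function(candidate, reference) {
  if (is.list(candidate) && !is.data.frame(candidate))
    candidate <- unlist(candidate[vapply(candidate, is.numeric, logical(1))])
  feats <- intersect(names(candidate), names(reference))
  if (!length(feats)) stop("no common features between candidate and reference")
  mu <- vapply(feats, function(f) mean(reference[[f]], na.rm = TRUE), numeric(1))
  sd_ <- vapply(feats, function(f) stats::sd(reference[[f]], na.rm = TRUE),
                numeric(1))
  z <- (unlist(candidate[feats]) - mu) / sd_
  z[sd_ == 0] <- NA_real_
  list(z = z, excluded = feats[sd_ == 0],
       aggregate = sum(abs(z), na.rm = TRUE))
}

#' Two-group comparison statistics
#'
#' Welch's two-sided t-test for two independent samples, plus the Spearman
#' rank correlation (mid-rank ties) when the input is paired `(x, y)`.
#'
#' @param sample_a,sample_b numeric vectors. For the two-sample test they
#'   are the two groups; if `paired_xy = TRUE` they are interpreted as
#'   paired observations and only the Spearman correlation is computed.
#' @param paired_xy treat inputs as paired (x, y) for correlation only.
#' @return A list with `welch` (`statistic`, `p.value`, `df`) and, for
#'   paired input, `spearman` (`rho`, `p.value`).
#' @export
compare_groups <- function(sample_a, sample_b, paired_xy = FALSE) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("need at least 2 observations per sample")
  out <- list()
  if (paired_xy) {
    ct <- suppressWarnings(stats::cor.test(sample_a, sample_b,
                                           method = "spearman", exact = FALSE))
    out$spearman <- list(rho = unname(ct$estimate), p.value = ct$p.value)
  } else {
    if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
      eq <- isTRUE(all.equal(mean(sample_a), mean(sample_b)))
      out$welch <- list(statistic = if (eq) 0 else Inf,
                        p.value = if (eq) 1 else 0,
                        df = length(sample_a) + length(sample_b) - 2)
    } else {
      tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
      out$welch <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                        df = unname(tt$parameter))
    }
  }
  out
}
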