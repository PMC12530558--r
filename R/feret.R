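#' Feret (caliper) diameters of a 2D soma contour
#'
#' The maximal Feret diameter is the largest point-pair distance of the
#' outline; the minimal Feret diameter is the smallest projection width
#' over a dense angular scan of caliper directions; the mean caliper is
#' the angular average width. Used to characterise soma shape from a
#' reconstructed outline.
#'
#' @param points numeric matrix or data frame with two columns (x, y in
#'   micrometres), at least 3 non-collinear points forming a closed
#'   outline (the closing edge is implicit).
#' @param angle_step angular scan resolution in degrees (default 0.5).
#' @return Named numeric vector `c(min_feret, max_feret, mean_caliper)`
#'   in micrometres.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' feret_diameters(cbind(5 * cos(th), 5 * sin(th)))  # circle: 10, 10, 10
#' @export
feret_diameters <- function(points, angle_step = 0.5) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (x, y)")
  if (nrow(pts) < 3L) stop("need at least 3 contour points")
  if (!all(is.finite(pts))) stop("non-finite contour point")
  # collinearity check via the 2nd singular value
  ctr <- scale(pts, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate (collinear) contour")
  dmax <- max(stats::dist(pts))
  th <- seq(0, 180 - angle_step, by = angle_step) * pi / 180
  widths <- vapply(th, function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  c(min_feret = min(widths), max_feret = dmax, mean_caliper = mean(widths))
}
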