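#' Fit a taper law to pooled segment diameter profiles
#'
#' Fits a diameter-versus-arc-length model to pooled
#' `(arc position from segment base, diameter)` samples of one segment
#' class (primary, intermediate or terminal). Three kinds are supported:
#' \describe{
#'   \item{exponential}{`d(s) = d_end + (d_base - d_end) * exp(-s / rate)`,
#'     with `rate` the decay length in micrometres (nonlinear least
#'     squares).}
#'   \item{linear}{`d(s) = d_base + slope * s` (ordinary least squares);
#'     `rate` holds the slope in micrometres per micrometre.}
#'   \item{constant}{`d(s) = d_base`, the mean diameter.}
#' }
#'
#' @param s arc positions from segment base, micrometres.
#' @param d diameters, micrometres.
#' @param kind one of `"exponential"`, `"linear"`, `"constant"`.
#' @return An object of class `taper_fit` with fields `kind`, `d_base`,
#'   `d_end`, `rate`, `rss`, `sigma` (residual SD) and `n`. `coef()` and
#'   `predict()` methods are provided.
#' @examples
#' s <- seq(0, 100, 2)
#' d <- 0.5 + 1.5 * exp(-s / 30)
#' fit_taper(s, d, "exponential")
#' @export
fit_taper <- function(s, d, kind = c("exponential", "linear", "constant")) {
  kind <- match.arg(kind)
  ok <- is.finite(s) & is.finite(d)
  s <- s[ok]; d <- d[ok]
  npar <- switch(kind, exponential = 3L, linear = 2L, constant = 1L)
  if (length(s) < npar)
    stop("too few points (", length(s), ") for a ", kind, " fit")
  if (kind == "constant") {
    db <- mean(d)
    res <- d - db
    fit <- list(kind = kind, d_base = db, d_end = db, rate = 0,
                rss = sum(res^2),
                sigma = if (length(d) > 1) stats::sd(res) else 0,
                n = length(d))
  } else if (kind == "linear") {
    lmfit <- stats::lm(d ~ s)
    cf <- stats::coef(lmfit)
    smax <- max(s)
    fit <- list(kind = kind, d_base = unname(cf[1]),
                d_end = unname(cf[1] + cf[2] * smax), rate = unname(cf[2]),
                rss = sum(stats::resid(lmfit)^2),
                sigma = suppressWarnings(summary(lmfit)$sigma),
                n = length(d))
  } else {
    # exponential; starting values from the end-point diameters
    ord <- order(s)
    d0 <- mean(d[ord][seq_len(max(1, ceiling(length(d) / 10)))])
    dinf <- mean(d[ord][seq(length(d) - max(0, ceiling(length(d) / 10) - 1),
                            length(d))])
    if (abs(d0 - dinf) < 1e-6) d0 <- dinf + max(0.1, 0.1 * abs(dinf))
    start <- list(d_end = dinf, amp = d0 - dinf,
                  rate = max(diff(range(s)) / 3, 1e-3))
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(d ~ d_end + amp * exp(-s / rate), start = start,
                        lower = c(d_end = 0, amp = -Inf, rate = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("exponential taper fit failed: ",
                               conditionMessage(e)))
    cf <- stats::coef(nls_fit)
    res <- stats::resid(nls_fit)
    fit <- list(kind = kind, d_base = unname(cf["d_end"] + cf["amp"]),
                d_end = unname(cf["d_end"]), rate = unname(cf["rate"]),
                rss = sum(res^2),
                sigma = sqrt(sum(res^2) / max(1, length(d) - 3)),
                n = length(d))
  }
  structure(fit, class = "taper_fit")
}

#' @export
print.taper_fit <- function(x, ...) {
  cat("<taper_fit> kind:", x$kind, "\n")
  cat(sprintf("  d_base %.3f um, d_end %.3f um", x$d_base, x$d_end))
  if (x$kind == "exponential")
    cat(sprintf(", decay length %.1f um", x$rate))
  if (x$kind == "linear")
    cat(sprintf(", slope %.5f um/um", x$rate))
  cat(sprintf("\n  n = %d, residual SD %.4f um\n", x$n, x$sigma))
  invisible(x)
}

#' @export
coef.taper_fit <- function(object, ...) {
  c(d_base = object$d_base, d_end = object$d_end, rate = object$rate)
}

#' @export
predict.taper_fit <- function(object, s, ...) {
  switch(object$kind,
         constant = rep.int(object$d_base, length(s)),
         linear = object$d_base + object$rate * s,
         exponential = object$d_end +
           (object$d_base - object$d_end) * exp(-s / object$rate))
}

#' Fit the diameter versus subtree-length law
#'
#' In SPNs the mean diameter of a dendritic segment is linearly
#' proportional to the total dendritic length `L` of the subtree
#' originating at the segment's base (inclusive of the segment itself by
#' default). Fits `d = intercept + k * L` by ordinary least squares over
#' the segments of one or several reconstructions.
#'
#' @param segments a [partition_segments] table, or a list of them
#'   (a cohort).
#' @param inclusive use the inclusive subtree length (default `TRUE`);
#'   `FALSE` measures only the length distal to the segment's end.
#' @return A list of class `subtree_law`: `slope` (um diameter per um
#'   subtree length), `intercept` (um), `r_squared`, `n`.
#' @export
fit_subtree_law <- function(segments, inclusive = TRUE) {
  if (is.data.frame(segments)) segments <- list(segments)
  L <- unlist(lapply(segments, function(s)
    if (inclusive) s$subtree_length_um else s$subtree_length_um - s$length_um))
  d <- unlist(lapply(segments, function(s) s$mean_diam_um))
  if (length(L) < 2L) stop("need at least 2 segments")
  fit <- stats::lm(d ~ L)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(L)), class = "subtree_law")
}

#' @export
print.subtree_law <- function(x, ...) {
  cat(sprintf("<subtree_law> d = %.4g + %.4g * L (um), R^2 = %.3f, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Pool taper samples from a segment table
#'
#' Collects `(arc position from segment base, diameter)` samples for one
#' taper class. Classes follow the morphometric convention: primary =
#' order-1 non-terminal, terminal = breadth-1, intermediate = everything
#' else; non-bifurcating primary dendrites (both primary and terminal) are
#' excluded.
#'
#' @param recon a standardised [spn_recon].
#' @param class one of `"primary"`, `"intermediate"`, `"terminal"`.
#' @param segments optional precomputed [partition_segments] table.
#' @return Data frame with columns `s_um` (arc position from segment base)
#'   and `diam_um`.
#' @export
taper_samples <- function(recon, class = c("primary", "intermediate",
                                           "terminal"),
                          segments = NULL) {
  class <- match.arg(class)
  if (is.null(segments)) segments <- partition_segments(recon)
  segs <- segments
  keep <- switch(class,
                 primary = segs$is_primary & !segs$is_terminal,
                 terminal = segs$is_terminal & !segs$is_primary,
                 intermediate = !segs$is_primary & !segs$is_terminal)
  nd <- recon$nodes
  soma <- which(nd$type == 1L)
  out <- lapply(which(keep), function(i) {
    p <- segs$path[[i]]
    geo <- if (p[1] %in% soma) p[-1] else p
    data.frame(s_um = path_cumlen(nd, geo), diam_um = 2 * nd$r[geo])
  })
  if (!length(out)) return(data.frame(s_um = numeric(), diam_um = numeric()))
  do.call(rbind, out)
}
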