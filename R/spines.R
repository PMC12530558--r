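#' Sigmoid spine-density model
#'
#' Spine density along an SPN dendrite rises from near zero at the soma to
#' a plateau and is modelled as
#' `S(x) = a / (1 + exp((b - x) / c))`
#' where `x` is path distance from the soma (um), `a` the plateau density
#' (spines/um), `b` the half-rise distance (`S(b) = a/2`, um) and `c` the
#' rise length scale (um).
#'
#' @param a plateau density, spines/um (> 0).
#' @param b half-rise distance, um.
#' @param c slope scale, um (> 0).
#' @return Object of class `spine_density_model`.
#' @examples
#' m <- spine_density_model(1.6, 25, 8)
#' spine_density(c(25, 50), m)
#' @export
spine_density_model <- function(a, b, c) {
  if (a <= 0) stop("plateau a must be > 0")
  if (c <= 0) stop("slope scale c must be > 0")
  structure(list(a = a, b = b, c = c), class = "spine_density_model")
}

#' @export
print.spine_density_model <- function(x, ...) {
  cat(sprintf(
    "<spine_density_model> S(x) = %.3g / (1 + exp((%.3g - x)/%.3g)) spines/um\n",
    x$a, x$b, x$c))
  invisible(x)
}

#' @export
coef.spine_density_model <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' Evaluate spine density
#'
#' @param x path distance(s) from the soma, um.
#' @param model a [spine_density_model].
#' @return Spine density in spines/um, same length as `x`.
#' @export
spine_density <- function(x, model) {
  model$a / (1 + exp((model$b - x) / model$c))
}

#' @export
predict.spine_density_model <- function(object, x, ...) {
  spine_density(x, object)
}

# exact antiderivative of S(x); numerically stable log1p(exp(u))
spine_density_integral <- function(x, model) {
  u <- (x - model$b) / model$c
  lse <- ifelse(u > 30, u, log1p(exp(pmin(u, 30))))
  model$a * model$c * lse
}

#' Fit the sigmoid spine-density model to binned counts
#'
#' Spine counts are binned by path distance from the soma (10 um bins by
#' convention); the per-bin density `count / dendritic length in bin` is
#' fitted with the sigmoid model by nonlinear least squares, each bin
#' weighted by the dendritic length it samples.
#'
#' @param bins data frame with columns `x_um` (bin centre), `count`
#'   (spines in bin) and `length_um` (total dendritic length sampled in
#'   the bin). At least 4 bins with positive length are required.
#' @return Object of class `c("spine_density_fit", "spine_density_model")`
#'   with the fitted `a`, `b`, `c` plus `rss`, `n_bins`.
#' @export
fit_spine_density <- function(bins) {
  need <- c("x_um", "count", "length_um")
  if (!all(need %in% names(bins)))
    stop("bins must have columns: ", paste(need, collapse = ", "))
  bins <- bins[bins$length_um > 0, , drop = FALSE]
  if (nrow(bins) < 4L) stop("need at least 4 bins with positive length")
  dens <- bins$count / bins$length_um
  if (all(bins$count == 0)) stop("all-zero counts: nothing to fit")
  a0 <- max(dens)
  half <- which(dens >= a0 / 2)
  b0 <- if (length(half)) bins$x_um[half[1]] else stats::median(bins$x_um)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dens ~ a / (1 + exp((b - x_um) / c)),
      data = data.frame(dens = dens, x_um = bins$x_um),
      start = list(a = a0, b = b0, c = 10),
      weights = bins$length_um,
      lower = c(a = 1e-8, b = -Inf, c = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("spine density fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                 rss = sum(stats::resid(fit)^2), n_bins = nrow(bins)),
            class = c("spine_density_fit", "spine_density_model"))
}

#' Spine membrane-area factor
#'
#' `F_spines = (A_spines + A_shaft) / A_shaft`, the ratio of total
#' (shaft + spine) to shaft membrane area of a dendrite. Vector input is
#' treated as a cohort of dendrites and the per-dendrite factors are
#' returned together with their mean and SD.
#'
#' @param A_spines total spine membrane area(s), um^2 (>= 0).
#' @param A_shaft shaft membrane area(s), um^2 (> 0).
#' @return For scalars, the factor; for vectors, a list with `factors`,
#'   `mean`, `sd`.
#' @examples
#' f_spines(123, 100)  # 2.23
#' @export
f_spines <- function(A_spines, A_shaft) {
  if (any(A_shaft <= 0)) stop("A_shaft must be > 0")
  if (any(A_spines < 0)) stop("A_spines must be >= 0")
  fac <- (A_spines + A_shaft) / A_shaft
  if (length(fac) == 1L) return(fac)
  list(factors = fac, mean = mean(fac), sd = stats::sd(fac))
}

#' Distance-dependent membrane correction for spines
#'
#' Compartmental models omit explicit spines and instead scale the
#' membrane: `F(x) = 1 + (F_spines - 1) * S(x) / a`, which runs from 1
#' where spine density is zero up to `F_spines` at the density plateau.
#' Dendritic `C_m` is multiplied and `R_m` divided by `F(x)`.
#'
#' @param x path distance(s) from the soma, um.
#' @param model a [spine_density_model] (only the shape `S(x)/a` is used).
#' @param F_spines plateau area factor (>= 1); simulations use 2.0.
#' @return `F(x)`, in `[1, F_spines]`.
#' @export
spine_correction <- function(x, model, F_spines = 2) {
  if (F_spines < 1) stop("F_spines must be >= 1")
  1 + (F_spines - 1) * spine_density(x, model) / model$a
}

#' Expected spine counts of a reconstruction
#'
#' Integrates the spine-density model along every dendritic segment
#' (closed-form integral of the sigmoid in path distance) and reports the
#' per-segment expectations, their total and the fraction carried by
#' terminal segments.
#'
#' @param recon a standardised [spn_recon].
#' @param model a [spine_density_model].
#' @param segments optional precomputed [partition_segments] table.
#' @return List with `total` (expected spine count), `per_segment`
#'   (data frame `seg_id`, `count`, `is_terminal`) and
#'   `terminal_fraction`.
#' @export
expected_spine_counts <- function(recon, model, segments = NULL) {
  if (is.null(segments)) segments <- partition_segments(recon)
  x0 <- segments$base_dist_um
  x1 <- x0 + segments$length_um
  cnt <- spine_density_integral(x1, model) - spine_density_integral(x0, model)
  total <- sum(cnt)
  list(total = total,
       per_segment = data.frame(seg_id = segments$seg_id, count = cnt,
                                is_terminal = segments$is_terminal),
       terminal_fraction = if (total > 0)
         sum(cnt[segments$is_terminal]) / total else NA_real_)
}

#' Summary statistics of a spine inventory
#'
#' @param spines data frame with columns `distance_um` (path distance to
#'   soma) and `area_um2`, optionally `head_area_um2`, `neck_length_um`,
#'   `neck_diameter_um`. Rows with missing optional fields are excluded
#'   from the corresponding summaries and counted.
#' @param bin_width distance bin width for the area-versus-distance
#'   profile, um (default 10; bins are half-open `[lo, hi)` anchored at
#'   the soma).
#' @return List with `summary` (mean/SD/n per measured quantity),
#'   `profile` (per-bin mean, SEM and n of spine area) and `spearman`
#'   (rank correlation of area with distance, mid-rank ties).
#' @export
spine_geometry_stats <- function(spines, bin_width = 10) {
  if (nrow(spines) < 3L) stop("need at least 3 spine records")
  stopifnot(all(c("distance_um", "area_um2") %in% names(spines)))
  msum <- function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  fields <- intersect(c("area_um2", "head_area_um2", "neck_length_um",
                        "neck_diameter_um"), names(spines))
  summ <- lapply(spines[fields], msum)
  bin <- floor(spines$distance_um / bin_width)
  prof <- do.call(rbind, lapply(split(spines$area_um2, bin), function(v) {
    data.frame(mean_area_um2 = mean(v),
               sem_area_um2 = stats::sd(v) / sqrt(length(v)),
               n = length(v))
  }))
  prof$bin_centre_um <- (as.numeric(rownames(prof)) + 0.5) * bin_width
  rownames(prof) <- NULL
  ct <- suppressWarnings(stats::cor.test(spines$area_um2, spines$distance_um,
                                         method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  if (is.na(rho)) rho <- 0  # constant areas: no rank variation
  list(summary = summ,
       profile = prof[, c("bin_centre_um", "mean_area_um2", "sem_area_um2",
                          "n")],
       spearman = list(rho = rho, p.value = ct$p.value))
}
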