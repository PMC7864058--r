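#' Pearson product-moment correlation
#'
#' Standard sample correlation, with input validation tuned for trajectory
#' series (equal lengths, no degenerate variance) and the result clipped to
#' [-1, 1] against floating-point rounding.
#'
#' @param x,y Numeric series of equal length >= 3.
#' @param x_label,y_label Names used in degenerate-series error messages.
#' @return The correlation coefficient r.
#' @export
pearson <- function(x, y, x_label = "x", y_label = "y") {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in series '", x_label, "'", call. = FALSE)
  if (stats::var(y) == 0) stop("zero variance in series '", y_label, "'", call. = FALSE)
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Standard error of a correlation coefficient
#'
#' SE_r = sqrt((1 - r^2) / (n - 2)). For r near 0 and n = 22,400 this is
#' about 0.007, which sets the scale for judging trajectory correlations.
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @param n Sample count (>= 3).
#' @return SE_r, same length as `r`.
#' @export
se_of_r <- function(r, n) {
  if (any(n < 3)) stop("n must be >= 3", call. = FALSE)
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  sqrt((1 - r^2) / (n - 2))
}

#' Null significance of a sample correlation
#'
#' Probability that n independent samples of two uncorrelated variables
#' give |r| >= |r0|: twice the integral of the null density of the sample
#' correlation, (1 - r^2)^((n-4)/2) * Gamma((n-1)/2) /
#' (sqrt(pi) Gamma((n-2)/2)), from |r0| to 1. The integral is evaluated by
#' adaptive quadrature on a log-scale integrand and cross-checked against
#' the exactly equivalent two-sided t tail with n - 2 degrees of freedom
#' (t = r sqrt((n-2)/(1-r^2))); disagreement beyond 1e-6 raises an
#' internal-consistency error. The quadrature value is returned.
#'
#' @param r0 Threshold correlation magnitude, 0 <= |r0| <= 1.
#' @param n Sample count (>= 5).
#' @param tol Cross-check tolerance (default 1e-6).
#' @return P_N(|r| >= |r0|), a probability in [0, 1]. Vectorized over `r0`.
#' @export
pn_significance <- function(r0, n, tol = 1e-6) {
  if (n < 5) stop("n must be >= 5", call. = FALSE)
  if (any(abs(r0) > 1)) stop("|r0| must be <= 1", call. = FALSE)
  vapply(abs(r0), function(a) {
    if (a == 0) return(1)
    if (a >= 1) return(0)
    lc <- lgamma((n - 1) / 2) - lgamma((n - 2) / 2) - 0.5 * log(pi)
    dens <- function(r) exp(lc + ((n - 4) / 2) * log1p(-r^2))
    quad <- 2 * stats::integrate(dens, a, 1, rel.tol = 1e-12, abs.tol = 1e-14,
                                 subdivisions = 2000L)$value
    t0 <- a * sqrt((n - 2) / (1 - a^2))
    ttail <- 2 * stats::pt(t0, df = n - 2, lower.tail = FALSE)
    if (abs(quad - ttail) > tol)
      stop(sprintf(paste0("null-probability routes disagree beyond %g ",
                          "(quadrature %.10g vs t-tail %.10g)"), tol, quad, ttail),
           call. = FALSE)
    min(1, max(0, quad))
  }, numeric(1))
}

#' Correlate contact-number series with interdomain distances
#'
#' Full cross table of Pearson correlations between every contact series
#' and every distance series, with SE_r, the null probability of the
#' observed |r|, and a significance flag |r| >= `cutoff` (inclusive; the
#' default 0.05 is roughly 7 SE_r at trajectory sample sizes). Constant
#' contact series are excluded and reported in `attr(, "degenerate")`.
#'
#' @param contacts Named list of contact series (each with `counts`), or a
#'   named list of plain numeric series.
#' @param distances Named list of distance series (each with `values`), or
#'   plain numeric series.
#' @param cutoff Significance cutoff on |r| (default 0.05).
#' @return Data.frame with `x_label` (contact), `y_label` (distance), `r`,
#'   `se_r`, `p_n`, `n`, `significant`.
#' @export
correlate_contacts_with_distances <- function(contacts, distances, cutoff = 0.05) {
  getv <- function(s) if (is.list(s)) (if (!is.null(s$counts)) s$counts else s$values) else s
  cs <- lapply(contacts, getv)
  ds <- lapply(distances, getv)
  n <- unique(c(vapply(cs, length, integer(1)), vapply(ds, length, integer(1))))
  if (length(n) != 1) stop("frame-count mismatch between series", call. = FALSE)
  degenerate <- names(cs)[vapply(cs, function(v) stats::var(v) == 0, logical(1))]
  cs <- cs[setdiff(names(cs), degenerate)]
  rows <- list()
  for (cx in names(cs)) for (dy in names(ds)) {
    r <- pearson(cs[[cx]], ds[[dy]], cx, dy)
    rows[[length(rows) + 1L]] <- data.frame(
      x_label = cx, y_label = dy, r = r, se_r = se_of_r(r, n),
      p_n = pn_significance(r, n), n = n,
      significant = abs(r) >= cutoff, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Top-fraction selection of correlation records
#'
#' Selects the records with the largest-magnitude correlations: the top
#' `fraction/2` of the positive coefficients by value, plus the top
#' `fraction/2` of the negative coefficients by magnitude. Each side keeps
#' `ceiling(n_side * fraction / 2)` records, where `n_side` counts the
#' records with that sign; ties are broken by (|r| descending, x_label,
#' y_label) for determinism.
#'
#' @param records Data.frame with columns `r`, `x_label`, `y_label`.
#' @param fraction Total fraction to keep, in (0, 1] (default 0.05).
#' @return The selected subset of `records`.
#' @export
top_fraction <- function(records, fraction = 0.05) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  pick <- function(side) {
    d <- records[side(records$r), , drop = FALSE]
    if (!nrow(d)) return(d[0, , drop = FALSE])
    k <- ceiling(nrow(d) * fraction / 2)
    d <- d[order(-abs(d$r), d$x_label, d$y_label), , drop = FALSE]
    d[seq_len(min(k, nrow(d))), , drop = FALSE]
  }
  out <- rbind(pick(function(r) r > 0), pick(function(r) r < 0))
  rownames(out) <- NULL
  out
}

#' Two-dimensional histogram with marginals
#'
#' Joint summary of an interdomain distance against a per-frame scalar
#' (e.g. a domain radius of gyration): a counts matrix over a regular
#' bin grid plus the axis marginals (which equal the row and column sums).
#'
#' @param x,y Aligned per-frame series (a distance series list or numeric).
#' @param bins Number of bins per axis (>= 2) or a list with `x`, `y`
#'   break vectors.
#' @return List with `counts` (x-bins by y-bins), `x_breaks`, `y_breaks`,
#'   `x_marginal`, `y_marginal`.
#' @export
joint_summary <- function(x, y, bins = 30L) {
  if (is.list(x)) x <- x$values
  if (is.list(y)) y <- y$values
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (is.list(bins)) {
    bx <- bins$x; by <- bins$y
  } else {
    if (bins < 2) stop("bins must be >= 2", call. = FALSE)
    pad <- function(v) if (diff(range(v)) == 0) range(v) + c(-0.5, 0.5) else range(v)
    bx <- seq(pad(x)[1], pad(x)[2], length.out = bins + 1)
    by <- seq(pad(y)[1], pad(y)[2], length.out = bins + 1)
  }
  ix <- findInterval(x, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, by, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(bx) - 1, length(by) - 1)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  list(counts = counts, x_breaks = bx, y_breaks = by,
       x_marginal = rowSums(counts), y_marginal = colSums(counts))
}
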