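# Spatial statistics: global Moran's I, centrography (weighted mean
# center, standard deviational ellipse, nearest-neighbour index) and
# point counts per zone.

# Moran's I statistic only, no guards (shared by morans_i and tests).
.moran_stat <- function(y, w) {
  yc <- y - mean(y)
  s0 <- sum(w)
  (length(y) / s0) * as.numeric(t(yc) %*% w %*% yc) / sum(yc^2)
}

#' Global Moran's I
#'
#' Classic (raw-weight) Moran's I of a variable observed on zones:
#' I = (n / S0) * sum_ij w_ij (y_i - ybar)(y_j - ybar) / sum_i (y_i -
#' ybar)^2, with expectation -1/(n-1) under no spatial autocorrelation.
#' Significance defaults to the normality assumption (the variance used
#' with plain z-scores); set \code{assumption = "randomization"} for the
#' permutation-moment variance.
#'
#' @param y numeric vector of zone values (n >= 3, non-constant).
#' @param w n x n spatial weight matrix (e.g.
#'   \code{\link{queen_contiguity}} or
#'   \code{\link{inverse_distance_squared_weights}}), used raw — not row
#'   standardized — unless you standardize it yourself.
#' @param assumption \code{"normality"} (default) or
#'   \code{"randomization"}.
#' @return Object of class \code{"moran_test"}: \code{I},
#'   \code{expected}, \code{variance}, \code{z}, \code{p_value}
#'   (two-sided normal), \code{n}, \code{assumption}.
#' @export
morans_i <- function(y, w, assumption = c("normality", "randomization")) {
  assumption <- match.arg(assumption)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("Moran's I needs n >= 3 zones", call. = FALSE)
  if (any(is.na(y))) stop("y contains missing values", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant y: Moran's I undefined", call. = FALSE)
  stopifnot(is.matrix(w), nrow(w) == n, ncol(w) == n)
  s0 <- sum(w)
  if (s0 <= 0) stop("weight matrix has no positive entries", call. = FALSE)
  I <- .moran_stat(y, w)
  ei <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  if (assumption == "normality") {
    v <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - ei^2
  } else {
    yc <- y - mean(y)
    b2 <- n * sum(yc^4) / sum(yc^2)^2
    v <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
            b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - ei^2
  }
  z <- (I - ei) / sqrt(v)
  structure(list(I = I, expected = ei, variance = v, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), n = n,
                 assumption = assumption, kind = attr(w, "kind")),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat("Global Moran's I", if (!is.null(x$kind)) sprintf("(%s weights)", x$kind),
      "\n")
  cat(sprintf("  I = %.4f  E[I] = %.4f  z = %.3f  p = %.4g  (n = %d, %s)\n",
              x$I, x$expected, x$z, x$p_value, x$n, x$assumption))
  invisible(x)
}

#' Weighted mean center
#'
#' The average location of a point set, optionally weighted (e.g. clinics
#' weighted by their physician counts).
#'
#' @param points planar points.
#' @param weights non-negative weights, sum > 0; equal if NULL.
#' @return Named numeric c(x, y) in meters.
#' @export
weighted_mean_center <- function(points, weights = NULL) {
  p <- .as_points(points, "points")
  if (is.null(weights)) weights <- rep(1, nrow(p))
  if (length(weights) != nrow(p) || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum, one per point",
         call. = FALSE)
  }
  c(x = sum(weights * p[, 1]) / sum(weights),
    y = sum(weights * p[, 2]) / sum(weights))
}

#' Standard deviational ellipse
#'
#' Directional dispersion of a (weighted) point set: the ellipse centered
#' on the weighted mean center whose axes are the standard deviations of
#' the coordinates along the rotated principal directions. The rotation
#' comes from the standard arctangent expression on the centered second
#' moments; those moments are uncorrected (divided by the weight sum, not
#' n - 1). \code{theta_deg} is the orientation of the major axis in
#' degrees counterclockwise from the positive x axis, in (-90, 90], so
#' \code{sigma_x >= sigma_y} always.
#'
#' @param points planar points, at least 3.
#' @param weights optional non-negative weights.
#' @return list: \code{center}, \code{sigma_x}, \code{sigma_y} (meters,
#'   along the rotated x and y axes), \code{theta_deg},
#'   \code{degenerate} (TRUE when the points are collinear or coincident).
#' @export
standard_deviational_ellipse <- function(points, weights = NULL) {
  p <- .as_points(points, "points")
  if (nrow(p) < 3) stop("need at least 3 points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(p))
  ctr <- weighted_mean_center(p, weights)
  xt <- p[, 1] - ctr[["x"]]; yt <- p[, 2] - ctr[["y"]]
  wsum <- sum(weights)
  sxx <- sum(weights * xt^2); syy <- sum(weights * yt^2)
  sxy <- sum(weights * xt * yt)
  # principal direction of maximum dispersion
  theta <- 0.5 * atan2(2 * sxy, sxx - syy)
  ct <- cos(theta); st <- sin(theta)
  sig_x <- sqrt(sum(weights * (xt * ct + yt * st)^2) / wsum)
  sig_y <- sqrt(sum(weights * (-xt * st + yt * ct)^2) / wsum)
  degenerate <- min(sig_x, sig_y) < 1e-12 * max(sig_x, sig_y, 1)
  if (degenerate) {
    warning("degenerate point configuration (collinear or coincident points)",
            call. = FALSE)
  }
  list(center = ctr, sigma_x = sig_x, sigma_y = sig_y,
       theta_deg = theta * 180 / pi, degenerate = degenerate)
}

#' Nearest-neighbour index
#'
#' Clark-Evans test of spatial dispersion: the observed mean distance to
#' each point's single nearest neighbour over its expectation under
#' complete spatial randomness, 0.5 * sqrt(A / n). Index < 1 indicates
#' clustering, > 1 dispersion. z uses the standard error
#' 0.26136 / sqrt(n^2 / A); the p-value is two-sided normal. The study
#' area A is a modelling choice and must be supplied; no edge correction
#' is applied.
#'
#' @param points planar points, n >= 2 (coincident points are retained,
#'   with a warning, and contribute zero distances).
#' @param area study-region area in square meters, > 0.
#' @return Object of class \code{"nni"}: \code{observed_mean},
#'   \code{expected_mean} (meters), \code{index}, \code{z},
#'   \code{p_value}, \code{n}, \code{area}.
#' @export
nearest_neighbour_index <- function(points, area) {
  p <- .as_points(points, "points")
  n <- nrow(p)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  .check_scalar(area, "area")
  d <- euclidean_distance_matrix(p, p)
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  if (any(nnd == 0)) warning("coincident points: zero nearest-neighbour distances",
                             call. = FALSE)
  obs <- mean(nnd)
  expd <- 0.5 * sqrt(area / n)
  se <- 0.26136 / sqrt(n^2 / area)
  z <- (obs - expd) / se
  structure(list(observed_mean = obs, expected_mean = expd,
                 index = obs / expd, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), n = n, area = area),
            class = "nni")
}

#' @export
print.nni <- function(x, ...) {
  cat("Nearest-neighbour index (Clark-Evans)\n")
  cat(sprintf("  observed %.1f m, expected %.1f m, index = %.3f (%s)\n",
              x$observed_mean, x$expected_mean, x$index,
              if (x$index < 1) "clustered" else "dispersed"))
  cat(sprintf("  z = %.3f, p = %.4g (n = %d, A = %.3g m^2)\n",
              x$z, x$p_value, x$n, x$area))
  invisible(x)
}

# Boundary-inclusive point-in-ring test (even-odd rule), vectorized over
# points; eps scales with the ring's extent.
.points_in_ring <- function(pts, ring) {
  nx <- nrow(pts)
  inside <- rep(FALSE, nx)
  on_edge <- rep(FALSE, nx)
  eps <- 1e-9 * max(1, diff(range(ring[, 1])), diff(range(ring[, 2])))
  px <- pts[, 1]; py <- pts[, 2]
  nv <- nrow(ring)
  for (k in seq_len(nv - 1)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    within_seg <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | (abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
                            within_seg)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Count points per zone
#'
#' Point-in-polygon counts (e.g. clinic density per zone). The boundary
#' rule is inclusive, and a point lying on a shared boundary is assigned
#' to a single zone (the first, in zone order) so the total is preserved;
#' points inside no polygon land in an \code{unassigned} bucket.
#'
#' @param points planar points.
#' @param zn a \code{\link{zones}} object with polygons.
#' @return list: \code{counts} (named integer vector per zone),
#'   \code{unassigned} (count), \code{assignment} (zone id per point, NA
#'   when unassigned).
#' @export
points_per_zone <- function(points, zn) {
  stopifnot(inherits(zn, "zones"))
  if (is.null(zn$polygon) || any(vapply(zn$polygon, is.null, logical(1)))) {
    stop("points_per_zone requires a polygon for every zone", call. = FALSE)
  }
  p <- .as_points(points, "points")
  assign_ <- rep(NA_character_, nrow(p))
  todo <- rep(TRUE, nrow(p))
  for (z in seq_along(zn$id)) {
    if (!any(todo)) break
    ring <- zn$polygon[[z]]
    cand <- which(todo &
                    p[, 1] >= min(ring[, 1]) & p[, 1] <= max(ring[, 1]) &
                    p[, 2] >= min(ring[, 2]) & p[, 2] <= max(ring[, 2]))
    if (!length(cand)) next
    hit <- cand[.points_in_ring(p[cand, , drop = FALSE], ring)]
    assign_[hit] <- zn$id[z]
    todo[hit] <- FALSE
  }
  counts <- table(factor(assign_, levels = zn$id))
  list(counts = stats::setNames(as.integer(counts), zn$id),
       unassigned = sum(is.na(assign_)),
       assignment = assign_)
}
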