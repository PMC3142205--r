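# Spatial weight matrices: queen contiguity and inverse distance squared.

#' Queen contiguity weights
#'
#' Binary spatial weights: w_ij = 1 when two zone polygons share at least
#' one boundary point (an edge or a single vertex — queen, not rook),
#' 0 otherwise; zero diagonal; symmetric.
#'
#' Adjacency is detected geometrically: exactly coincident vertices are
#' found by hashing coordinates, and for polygons whose bounding boxes
#' touch without a shared vertex, vertex-on-edge incidence is tested within
#' \code{tolerance} meters (default 0, exact coordinates — appropriate for
#' tilings built from shared arithmetic; raise it for digitized data).
#'
#' @param zn a \code{\link{zones}} object; every zone needs a polygon.
#' @param tolerance snapping tolerance in meters for boundary matching.
#' @return n x n 0/1 matrix with zone-id dimnames and attribute
#'   \code{kind = "queen"}.
#' @export
queen_contiguity <- function(zn, tolerance = 0) {
  stopifnot(inherits(zn, "zones"))
  if (is.null(zn$polygon) || any(vapply(zn$polygon, is.null, logical(1)))) {
    stop("queen contiguity requires a polygon for every zone", call. = FALSE)
  }
  n <- length(zn$id)
  w <- matrix(0, n, n, dimnames = list(zn$id, zn$id))

  # open rings (closing vertex dropped)
  rings <- lapply(zn$polygon, function(p) p[-nrow(p), , drop = FALSE])

  # 1. shared-vertex pass via coordinate hashing
  key <- lapply(rings, function(r) paste(r[, 1], r[, 2], sep = "_"))
  owner <- rep(seq_len(n), lengths(key))
  byv <- split(owner, unlist(key))
  for (zs in byv) {
    zs <- unique(zs)
    if (length(zs) > 1) {
      pr <- utils::combn(zs, 2)
      w[t(pr)] <- 1
      w[t(pr[2:1, , drop = FALSE])] <- 1
    }
  }

  # 2. vertex-on-edge pass for bbox-touching pairs not caught above
  bb <- t(vapply(rings, function(r) c(min(r[, 1]), max(r[, 1]),
                                      min(r[, 2]), max(r[, 2])), numeric(4)))
  tol <- tolerance
  for (i in seq_len(n - 1)) {
    j <- which(bb[, 1] <= bb[i, 2] + tol & bb[, 2] >= bb[i, 1] - tol &
               bb[, 3] <= bb[i, 4] + tol & bb[, 4] >= bb[i, 3] - tol)
    j <- j[j > i & w[i, j] == 0]
    for (jj in j) {
      if (.shares_boundary_point(rings[[i]], rings[[jj]], tol)) {
        w[i, jj] <- w[jj, i] <- 1
      }
    }
  }
  attr(w, "kind") <- "queen"
  w
}

# Any vertex of one ring within tol of a vertex or edge of the other.
.shares_boundary_point <- function(r1, r2, tol) {
  .vert_near(r1, r2, tol) || .vert_near(r2, r1, tol)
}

.vert_near <- function(pts, ring, tol) {
  rc <- rbind(ring, ring[1, , drop = FALSE])
  for (k in seq_len(nrow(rc) - 1)) {
    a <- rc[k, ]; b <- rc[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t_ <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2))
    dx <- pts[, 1] - (a[1] + t_ * ab[1])
    dy <- pts[, 2] - (a[2] + t_ * ab[2])
    if (any(sqrt(dx^2 + dy^2) <= tol)) return(TRUE)
  }
  FALSE
}

#' Inverse-distance-squared weights
#'
#' w_ij = 1 / d_ij^2 (meters^-2) between zone centroids, zero diagonal,
#' symmetric. Coincident centroids make the weight undefined and raise an
#' error naming the offending pair.
#'
#' @param centroids planar points (data.frame with x, y, optionally id, or
#'   a two-column matrix), or a \code{\link{zones}} object.
#' @return n x n weight matrix with attribute
#'   \code{kind = "inverse_distance_squared"}.
#' @export
inverse_distance_squared_weights <- function(centroids) {
  if (inherits(centroids, "zones")) centroids <- centroids$centroid
  d <- euclidean_distance_matrix(centroids, centroids)
  zero <- which(d == 0 & row(d) != col(d), arr.ind = TRUE)
  if (nrow(zero)) {
    stop(sprintf("coincident centroids: %s and %s",
                 rownames(d)[zero[1, 1]], colnames(d)[zero[1, 2]]), call. = FALSE)
  }
  w <- 1 / d^2
  diag(w) <- 0
  attr(w, "metric") <- NULL
  attr(w, "kind") <- "inverse_distance_squared"
  w
}

#' Row-standardize a spatial weight matrix
#'
#' Divides each row by its sum; rows with no neighbours are left at zero.
#' The classic (raw-weight) Moran form is the package default; this is the
#' usual alternative.
#'
#' @param w spatial weight matrix.
#' @return Row-standardized matrix (kind attribute preserved).
#' @export
row_standardize <- function(w) {
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  out <- w / rs
  attr(out, "kind") <- attr(w, "kind")
  out
}
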