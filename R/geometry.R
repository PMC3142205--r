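# Planar geometry: zone container, Euclidean and street-network travel
# distances, nearest-node snapping, catchment membership.
#
# All coordinates are projected planar meters. Geographic (lon/lat) layers
# must be projected upstream; inputs tagged with attr(x, "crs") ==
# "geographic" are rejected.

#' Zone set
#'
#' Container for demand zones: an id, a centroid, and optionally a polygon
#' boundary (a closed ring). When a polygon is supplied its area centroid is
#' used unless an explicit centroid is given (census sources often publish
#' population-weighted centroids, which differ from geometric ones).
#'
#' @param id character vector of unique zone identifiers.
#' @param centroids two-column matrix or data.frame (columns \code{x},
#'   \code{y}) of centroid coordinates in meters; may be \code{NULL} when
#'   polygons are given, in which case area centroids are computed.
#' @param polygons optional list of closed rings (matrices with columns
#'   x, y; first and last vertex equal), one per zone, or \code{NULL}.
#' @return An object of class \code{"zones"}: a list with elements
#'   \code{id}, \code{centroid} (n x 2 matrix) and \code{polygon}.
#' @export
zones <- function(id, centroids = NULL, polygons = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate zone id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(id)
  if (!is.null(polygons)) {
    if (length(polygons) != n) stop("one polygon per zone required", call. = FALSE)
    polygons <- lapply(polygons, function(p) {
      if (is.null(p)) return(NULL)
      p <- .as_points(p, "polygon ring")
      if (nrow(p) < 4 || any(p[1, ] != p[nrow(p), ])) {
        stop("polygon rings must be closed (first vertex repeated last)", call. = FALSE)
      }
      p
    })
  }
  if (is.null(centroids)) {
    if (is.null(polygons) || any(vapply(polygons, is.null, logical(1)))) {
      stop("centroids required when polygons are absent", call. = FALSE)
    }
    centroids <- t(vapply(polygons, .ring_centroid, numeric(2)))
    colnames(centroids) <- c("x", "y")
  } else {
    centroids <- .as_points(centroids, "centroids")
    if (nrow(centroids) != n) stop("one centroid per zone required", call. = FALSE)
  }
  rownames(centroids) <- id
  structure(list(id = id, centroid = centroids, polygon = polygons),
            class = "zones")
}

#' @export
print.zones <- function(x, ...) {
  cat(sprintf("Zone set: %d zones (%s polygons)\n", length(x$id),
              if (is.null(x$polygon)) "without" else "with"))
  invisible(x)
}

# Area centroid of a closed ring (shoelace formulas).
.ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  i <- seq_len(n - 1)
  cr <- x[i] * y[i + 1] - x[i + 1] * y[i]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x[i]), mean(y[i])))
  c(sum((x[i] + x[i + 1]) * cr), sum((y[i] + y[i + 1]) * cr)) / (6 * a)
}

.ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  i <- seq_len(nrow(ring) - 1)
  abs(sum(x[i] * y[i + 1] - x[i + 1] * y[i])) / 2
}

#' Euclidean origin-destination distance matrix
#'
#' Straight-line distances in meters between two planar point sets.
#'
#' @param origins,destinations point sets (data.frame with columns
#'   \code{x}, \code{y} and optionally \code{id}, or a two-column matrix).
#' @return Numeric matrix (origins x destinations) of distances in meters,
#'   with attribute \code{metric = "euclidean"}.
#' @export
euclidean_distance_matrix <- function(origins, destinations) {
  o <- .as_points(origins, "origins")
  d <- .as_points(destinations, "destinations")
  m <- sqrt(outer(o[, 1], d[, 1], "-")^2 + outer(o[, 2], d[, 2], "-")^2)
  dimnames(m) <- list(.point_ids(o, "o"), .point_ids(d, "d"))
  attr(m, "metric") <- "euclidean"
  m
}

#' Street network
#'
#' An undirected street network as a node table and an edge table with
#' lengths in meters. Edge lengths must be positive; when built from planar
#' coordinates they should be at least the Euclidean distance between the
#' endpoints.
#'
#' @param nodes data.frame with columns \code{id}, \code{x}, \code{y}.
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{length} (meters).
#' @return Object of class \code{"street_network"}.
#' @export
street_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("id", "x", "y") %in% names(nodes))) {
    stop("nodes need columns id, x, y", call. = FALSE)
  }
  if (!all(c("from", "to", "length") %in% names(edges))) {
    stop("edges need columns from, to, length", call. = FALSE)
  }
  if (nrow(nodes) == 0) stop("empty network", call. = FALSE)
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y))) {
    stop("non-finite node coordinates", call. = FALSE)
  }
  if (any(!is.finite(edges$length)) || any(edges$length <= 0)) {
    stop("edge lengths must be positive and finite", call. = FALSE)
  }
  miss <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(miss)) stop("edge endpoints not in node table: ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "street_network")
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf("Street network: %d nodes, %d edges, total length %.0f m\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length)))
  invisible(x)
}

.network_graph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to", "length")],
    directed = FALSE,
    vertices = network$nodes[, c("id", "x", "y")]
  )
}

#' Snap points to the nearest network node
#'
#' Each point attaches to its single nearest node; ties are broken by the
#' lowest node id (lexicographic on the id string, numeric ids compared as
#' numbers).
#'
#' @param network a \code{\link{street_network}}.
#' @param points planar points.
#' @return data.frame with columns \code{node} (id of nearest node) and
#'   \code{snap_distance} (meters from point to node).
#' @export
snap_to_network <- function(network, points) {
  stopifnot(inherits(network, "street_network"))
  p <- .as_points(points, "points")
  nd <- network$nodes
  ids <- nd$id
  num <- suppressWarnings(as.numeric(ids))
  ord_key <- if (!anyNA(num)) order(num) else order(ids)
  d <- euclidean_distance_matrix(p, nd[, c("x", "y")])
  node <- character(nrow(p)); sdist <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    best <- which(d[i, ] == min(d[i, ]))
    if (length(best) > 1) best <- best[order(match(best, ord_key))][1]
    node[i] <- ids[best]
    sdist[i] <- d[i, best]
  }
  data.frame(node = node, snap_distance = sdist,
             row.names = .point_ids(p, "p"), stringsAsFactors = FALSE)
}

#' Shortest-path origin-destination distance matrix
#'
#' Network travel distances: points snap to their nearest node and
#' Dijkstra shortest-path lengths are computed on the edge lengths.
#' Unreachable pairs get \code{Inf} and are excluded from every catchment
#' downstream. By default the point-to-node access hop is not added to the
#' path length; set \code{add_access_distance = TRUE} to add the Euclidean
#' snap distances at both ends.
#'
#' @param network a \code{\link{street_network}}.
#' @param origins,destinations planar point sets.
#' @param add_access_distance add snap distances to each path length?
#' @return Numeric matrix (origins x destinations) in meters with attribute
#'   \code{metric = "network"}.
#' @export
shortest_path_distance_matrix <- function(network, origins, destinations,
                                          add_access_distance = FALSE) {
  stopifnot(inherits(network, "street_network"))
  o <- .as_points(origins, "origins")
  d <- .as_points(destinations, "destinations")
  so <- snap_to_network(network, o)
  sd_ <- snap_to_network(network, d)
  g <- .network_graph(network)
  uo <- unique(so$node); ud <- unique(sd_$node)
  dm <- igraph::distances(g, v = uo, to = ud, weights = igraph::E(g)$length,
                          algorithm = "dijkstra")
  m <- dm[match(so$node, uo), match(sd_$node, ud), drop = FALSE]
  if (add_access_distance) {
    m <- m + outer(so$snap_distance, rep(1, nrow(d))) +
      outer(rep(1, nrow(o)), sd_$snap_distance)
  }
  dimnames(m) <- list(.point_ids(o, "o"), .point_ids(d, "d"))
  attr(m, "metric") <- "network"
  m
}

#' Catchment membership at a distance threshold
#'
#' Closed-threshold membership (d <= d0) read off a distance matrix, in
#' both directions: the demand units within reach of each supply site and
#' the supply sites within reach of each demand unit. Both directions come
#' from the same matrix, so catchments are symmetric.
#'
#' @param dm distance matrix (demand rows x supply columns), meters.
#' @param d0 threshold distance in meters, > 0.
#' @return list with \code{demand_by_supply} (one character vector of
#'   demand ids per supply column) and \code{supply_by_demand}.
#' @export
catchment_members <- function(dm, d0) {
  .check_scalar(d0, "d0")
  stopifnot(is.matrix(dm))
  within <- dm <= d0
  rn <- rownames(dm); cn <- colnames(dm)
  list(
    demand_by_supply = stats::setNames(
      lapply(seq_len(ncol(dm)), function(j) rn[within[, j]]), cn),
    supply_by_demand = stats::setNames(
      lapply(seq_len(nrow(dm)), function(i) cn[within[i, ]]), rn)
  )
}
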