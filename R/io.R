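# Readers and writers (CSV tables, GeoJSON layers) and the full
# reporting workflow.

.check_unique_ids <- function(id, what) {
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
}

#' Read a supply table
#'
#' CSV with columns \code{id}, \code{x}, \code{y} and optionally
#' \code{capacity} (default 1) and \code{physicians} (default 1).
#' Row-level problems are reported with their line number (header is
#' line 1).
#'
#' @param path CSV file path.
#' @return Validated supply data.frame.
#' @export
read_supply <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(tab))) {
    stop("supply file lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab$id <- as.character(tab$id)
  .check_unique_ids(tab$id, "supply")
  bad <- which(!is.finite(tab$x) | !is.finite(tab$y))
  if (length(bad)) {
    stop("non-finite coordinates at line(s): ",
         paste(utils::head(bad + 1, 5), collapse = ", "), call. = FALSE)
  }
  .validate_supply(tab)
}

#' Read a demand table
#'
#' CSV with columns \code{id}, \code{x}, \code{y} and the nine age-bin
#' populations \code{pop_0_14} ... \code{pop_80_plus}. Negative
#' populations and duplicate ids are errors naming the offending line.
#'
#' @param path CSV file path.
#' @param schedule utilization schedule used to add \code{pop_total} and
#'   \code{users} (see \code{\link{add_potential_users}}).
#' @return Validated demand data.frame with totals and potential users.
#' @export
read_demand <- function(path, schedule = "montreal") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", .age_cols())
  if (!all(need %in% names(tab))) {
    stop("demand file lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab$id <- as.character(tab$id)
  .check_unique_ids(tab$id, "zone")
  neg <- which(apply(tab[, .age_cols()], 1, function(r) any(r < 0)))
  if (length(neg)) {
    stop("negative population at line(s): ",
         paste(utils::head(neg + 1, 5), collapse = ", "), call. = FALSE)
  }
  add_potential_users(tab, schedule)
}

#' Write supply / demand tables
#'
#' Plain CSV mirrors of the reader schemas; a write-then-read round trip
#' is the identity.
#'
#' @param x supply or demand data.frame.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_supply <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_supply
#' @export
write_demand <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a street network as node and edge CSVs
#'
#' Nodes: \code{id}, \code{x}, \code{y}. Edges: \code{from}, \code{to},
#' \code{length} (meters).
#'
#' @param nodes_path,edges_path CSV paths.
#' @return A \code{\link{street_network}}.
#' @export
read_network <- function(nodes_path, edges_path) {
  street_network(utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                                 colClasses = c(id = "character")),
                 utils::read.csv(edges_path, stringsAsFactors = FALSE,
                                 colClasses = c(from = "character", to = "character")))
}

#' @rdname read_network
#' @param network a \code{\link{street_network}}.
#' @export
write_network <- function(network, nodes_path, edges_path) {
  utils::write.csv(network$nodes, nodes_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(network$edges, edges_path, row.names = FALSE, quote = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Export a distance matrix in long format
#'
#' Columns: \code{origin_id}, \code{destination_id}, \code{meters}.
#'
#' @param dm distance matrix.
#' @param path output CSV path.
#' @export
write_distance_long <- function(dm, path) {
  long <- data.frame(origin_id = rep(rownames(dm), ncol(dm)),
                     destination_id = rep(colnames(dm), each = nrow(dm)),
                     meters = as.vector(dm))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- GeoJSON (RFC 7946); coordinates are planar meters, which GeoJSON
# tolerates for local CRSs declared out of band.

.geojson_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write zones (with optional attributes) as GeoJSON polygons
#'
#' @param zn a \code{\link{zones}} object with polygons.
#' @param path output path.
#' @param properties optional data.frame of per-zone attributes with an
#'   \code{id} column to join on.
#' @export
write_zones_geojson <- function(zn, path, properties = NULL) {
  stopifnot(inherits(zn, "zones"))
  if (is.null(zn$polygon)) stop("zones have no polygons to export", call. = FALSE)
  if (!is.null(properties)) {
    stopifnot("id" %in% names(properties))
    properties <- properties[match(zn$id, properties$id), , drop = FALSE]
  }
  features <- lapply(seq_along(zn$id), function(k) {
    props <- list(id = zn$id[k])
    if (!is.null(properties)) {
      for (col in setdiff(names(properties), "id")) {
        v <- properties[[col]][k]
        props[[col]] <- if (is.na(v)) NULL else v
      }
    }
    ring <- zn$polygon[[k]]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  .geojson_write(features, path)
}

#' Read zones from GeoJSON polygons
#'
#' Expects a FeatureCollection of Polygon features with an \code{id}
#' property (outer ring only; holes are not supported). A top-level
#' geographic CRS declaration is rejected: coordinates must be planar
#' meters.
#'
#' @param path GeoJSON path.
#' @return A \code{\link{zones}} object.
#' @export
read_zones_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  crs_name <- tryCatch(g$crs$properties$name, error = function(e) NULL)
  if (!is.null(crs_name) && grepl("CRS84|4326", crs_name)) {
    stop("geographic (lon/lat) GeoJSON rejected: project to planar meters first",
         call. = FALSE)
  }
  feats <- g$features
  ids <- vapply(feats, function(f) as.character(f$properties$id), character(1))
  polys <- lapply(feats, function(f) {
    stopifnot(identical(f$geometry$type, "Polygon"))
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    colnames(m) <- c("x", "y")
    m
  })
  zones(ids, polygons = polys)
}

#' Write points as GeoJSON
#'
#' @param df data.frame with \code{id}, \code{x}, \code{y} plus any
#'   attribute columns (all exported as properties).
#' @param path output path.
#' @export
write_points_geojson <- function(df, path) {
  attr_cols <- setdiff(names(df), c("x", "y"))
  features <- lapply(seq_len(nrow(df)), function(k) {
    list(type = "Feature",
         properties = as.list(df[k, attr_cols, drop = FALSE]),
         geometry = list(type = "Point",
                         coordinates = c(df$x[k], df$y[k])))
  })
  .geojson_write(features, path)
}

#' Write accessibility scores as CSV
#'
#' Columns: \code{zone_id}, \code{method}, \code{metric}, \code{d0_m},
#' \code{A}, \code{defined}.
#'
#' @param fit an \code{\link{fca}} fit.
#' @param path output CSV path.
#' @export
write_scores_csv <- function(fit, path) {
  stopifnot(inherits(fit, "fca"))
  out <- data.frame(zone_id = fit$scores$id, method = fit$method,
                    metric = fit$metric, d0_m = fit$d0,
                    A = fit$scores$score, defined = fit$scores$defined)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full reporting workflow
#'
#' Runs both 2SFCA methods at every threshold on one city instance and
#' writes the complete comparison apparatus to \code{out_dir}:
#' \itemize{
#'   \item \code{demand_summary.csv} — population / potential-user
#'     descriptives;
#'   \item \code{accessibility_scores.csv} — per-zone scores, long format;
#'   \item \code{accessibility_summary.csv} — score descriptives per
#'     method and threshold;
#'   \item \code{comparison_<d0>m.csv} and
#'     \code{difference_<d0>m.geojson} — per-zone method comparison and
#'     the difference layer;
#'   \item \code{spearman.csv}, \code{differences_summary.csv},
#'     \code{moran.csv} — rank correlations, difference percentile rows,
#'     and Moran's I of D under queen and inverse-distance-squared
#'     weights;
#'   \item \code{run_log.json} — per-stage bookkeeping (zones with
#'     access, clinics with empty catchments) and the configuration.
#' }
#' Everything is deterministic given the city instance, so two runs on
#' the same instance produce identical files.
#'
#' @param city a \code{\link{generate_city}} result, or a list with
#'   \code{supply}, \code{demand}, \code{zones} (and \code{network} when
#'   \code{metric = "network"}).
#' @param out_dir output directory (created if needed).
#' @param thresholds catchment thresholds in meters, strictly increasing.
#' @param metric \code{"euclidean"} or \code{"network"} travel distance.
#' @param schedule utilization schedule for the optimized method.
#' @return Invisibly, a list with the summary tables.
#' @export
run_report <- function(city, out_dir,
                       thresholds = c(500, 1000, 2000, 3000),
                       metric = c("euclidean", "network"),
                       schedule = "montreal") {
  metric <- match.arg(metric)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0)) {
    stop("thresholds must be positive and strictly increasing", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  demand <- add_potential_users(city$demand, schedule)
  supply <- .validate_supply(city$supply)
  dm <- if (metric == "euclidean") {
    euclidean_distance_matrix(demand, supply)
  } else {
    if (is.null(city$network)) stop("network metric requires city$network", call. = FALSE)
    shortest_path_distance_matrix(city$network, demand, supply)
  }

  utils::write.csv(cbind(statistic = rownames(summarize_demand(demand)),
                         summarize_demand(demand)),
                   file.path(out_dir, "demand_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  scores_long <- list(); summ <- list(); spear <- list()
  diffsum <- list(); moran <- list(); log_counts <- list()
  qw_full <- if (!is.null(city$zones) && !is.null(city$zones$polygon)) {
    queen_contiguity(city$zones)
  } else NULL

  for (d0 in thresholds) {
    fits <- lapply(c(conventional = "conventional", optimized = "optimized"),
                   function(m) {
                     withCallingHandlers(
                       fca(supply, demand, dm, d0, method = m, schedule = schedule),
                       warning = function(w) invokeRestart("muffleWarning"))
                   })
    for (m in names(fits)) {
      f <- fits[[m]]
      scores_long[[paste(m, d0)]] <- data.frame(
        zone_id = f$scores$id, method = m, metric = metric, d0_m = d0,
        A = f$scores$score, defined = f$scores$defined)
      summ[[paste(m, d0)]] <- data.frame(
        method = m, d0_m = d0, t(summarize_scores(f)))
      log_counts[[paste(m, d0)]] <- list(
        method = m, d0_m = d0, zones_with_access = f$n_defined,
        zones_without_access = f$n_zones - f$n_defined,
        clinics_empty_catchment = f$n_empty_catchment_sites)
    }
    cmp <- compare_methods(fits$conventional, fits$optimized)
    d <- cmp$differences
    utils::write.csv(
      data.frame(zone_id = d$id, A_conv = d$score_conv, A_opt = d$score_opt,
                 resc_conv = d$rescaled_conv, resc_opt = d$rescaled_opt,
                 D = d$D),
      file.path(out_dir, sprintf("comparison_%dm.csv", d0)),
      row.names = FALSE, quote = FALSE)
    if (!is.null(city$zones) && !is.null(city$zones$polygon)) {
      write_zones_geojson(
        city$zones, file.path(out_dir, sprintf("difference_%dm.geojson", d0)),
        properties = data.frame(id = d$id, D = d$D,
                                A_conv = d$score_conv, A_opt = d$score_opt))
    }
    spear[[as.character(d0)]] <- data.frame(
      d0_m = d0, rho = cmp$spearman$rho, p_value = cmp$spearman$p_value,
      n = cmp$spearman$n)
    diffsum[[as.character(d0)]] <- cbind(d0_m = d0, cmp$percentiles)

    # Moran's I of the difference scores under both weight matrices
    idx <- match(d$id, city$demand$id)
    if (!is.null(qw_full)) {
      mq <- morans_i(d$D, qw_full[d$id, d$id])
      moran[[paste("queen", d0)]] <- data.frame(
        weights = "queen", d0_m = d0, I = mq$I, expected = mq$expected,
        z = mq$z, p_value = mq$p_value, n = mq$n)
    }
    wi <- inverse_distance_squared_weights(
      data.frame(id = d$id, x = demand$x[idx], y = demand$y[idx]))
    mi <- morans_i(d$D, wi)
    moran[[paste("idw2", d0)]] <- data.frame(
      weights = "inverse_distance_squared", d0_m = d0, I = mi$I,
      expected = mi$expected, z = mi$z, p_value = mi$p_value, n = mi$n)
  }

  tabs <- list(
    scores = do.call(rbind, scores_long),
    accessibility_summary = do.call(rbind, summ),
    spearman = do.call(rbind, spear),
    differences_summary = do.call(rbind, diffsum),
    moran = do.call(rbind, moran)
  )
  utils::write.csv(tabs$scores, file.path(out_dir, "accessibility_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tabs$accessibility_summary,
                   file.path(out_dir, "accessibility_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tabs$spearman, file.path(out_dir, "spearman.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tabs$differences_summary,
                   file.path(out_dir, "differences_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tabs$moran, file.path(out_dir, "moran.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(metric = metric, thresholds = thresholds, schedule = schedule,
         config = if (!is.null(city$config)) unclass(city$config) else NULL,
         counts = unname(log_counts)),
    file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tabs)
}
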