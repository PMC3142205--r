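# Seeded generator of synthetic city instances: a rectangular grid of
# demand zones with age-structured populations, clinics clustered around
# a central business district (CBD), and a grid street network. Test and
# demonstration infrastructure emulating the study geography (thousands
# of small census zones, a few hundred clustered clinics).

#' City generator configuration
#'
#' Parameters of the synthetic city. Defaults echo the study geography at
#' toy scale: zone populations are lognormal with median 542 and mean
#' about 586 persons, split over the nine age bins by a Dirichlet draw
#' around a fixed Montreal-like age profile; a fraction
#' \code{clinic_clustering} of clinics is drawn from a Gaussian around the
#' CBD (the rectangle center) and the rest uniformly; physician counts
#' per clinic are 1 + Poisson(\code{physician_lambda}).
#'
#' @param rows,cols zone grid dimensions (rows x cols zones).
#' @param cell_size zone cell side in meters.
#' @param n_clinics number of clinics.
#' @param clinic_clustering fraction of clinics drawn around the CBD, in
#'   [0, 1].
#' @param cbd_sd standard deviation (meters) of the CBD Gaussian;
#'   defaults to a sixth of the smaller rectangle side.
#' @param physician_lambda Poisson mean of physicians per clinic minus 1.
#' @param pop_median,pop_sdlog lognormal parameters of zone population
#'   (median = exp(meanlog) persons; sdlog on the log scale).
#' @param age_conc Dirichlet concentration around the packaged age
#'   profile (larger = less zone-to-zone age-mix variation).
#' @param network_spacing street grid spacing in meters; defaults to
#'   \code{cell_size}.
#' @param seed integer seed; every draw is reproducible from it.
#' @return Object of class \code{"city_config"} (a validated list).
#' @export
city_config <- function(rows = 3, cols = 3, cell_size = 500,
                        n_clinics = 2, clinic_clustering = 0.8,
                        cbd_sd = NULL, physician_lambda = 4.5,
                        pop_median = 542, pop_sdlog = 0.3953,
                        age_conc = 200, network_spacing = NULL,
                        seed = 1L) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              cell_size = cell_size, n_clinics = as.integer(n_clinics),
              clinic_clustering = clinic_clustering,
              cbd_sd = if (is.null(cbd_sd)) min(rows, cols) * cell_size / 6 else cbd_sd,
              physician_lambda = physician_lambda,
              pop_median = pop_median, pop_sdlog = pop_sdlog,
              age_conc = age_conc,
              network_spacing = if (is.null(network_spacing)) cell_size else network_spacing,
              seed = as.integer(seed))
  with(cfg, {
    if (rows < 1 || cols < 1 || n_clinics < 1) stop("counts must be >= 1", call. = FALSE)
    if (cell_size <= 0 || network_spacing <= 0) stop("sizes must be > 0", call. = FALSE)
    if (clinic_clustering < 0 || clinic_clustering > 1) {
      stop("clinic_clustering must lie in [0, 1]", call. = FALSE)
    }
    if (physician_lambda < 0 || pop_median <= 0 || pop_sdlog < 0 || age_conc <= 0) {
      stop("invalid distribution parameters", call. = FALSE)
    }
  })
  structure(cfg, class = "city_config")
}

#' @export
print.city_config <- function(x, ...) {
  cat(sprintf("City config: %dx%d zones (%g m cells), %d clinics (clustering %.2f), seed %d\n",
              x$rows, x$cols, x$cell_size, x$n_clinics,
              x$clinic_clustering, x$seed))
  invisible(x)
}

#' Scenario presets
#'
#' Named ready-made configurations: \code{toy9}, a 3x3 / 2-clinic smoke
#' instance, and \code{montreal_like}, sized after the study region
#' (3,150 zones of about 0.15 km^2 each over roughly 480 km^2, 236
#' clinics holding 1,344 physicians on average, clustered near the CBD).
#'
#' @param seed seed stored in each preset.
#' @return Named list of \code{\link{city_config}} objects.
#' @export
scenario_presets <- function(seed = 1L) {
  list(
    toy9 = city_config(rows = 3, cols = 3, cell_size = 500, n_clinics = 2,
                       clinic_clustering = 0.8, physician_lambda = 4.5,
                       seed = seed),
    montreal_like = city_config(rows = 45, cols = 70, cell_size = 390,
                                n_clinics = 236,
                                clinic_clustering = 0.8, cbd_sd = 3000,
                                physician_lambda = 1344 / 236 - 1,
                                seed = seed)
  )
}

.age_profile <- function() {
  path <- system.file("extdata", "age_profile.csv",
                      package = "twostepfca", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  stats::setNames(tab$share, tab$age_group)[age_bins()]
}

# Dirichlet draw via normalized gammas.
.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

#' Generate a synthetic city
#'
#' Draws a full instance — supply, demand, zone polygons and street
#' network — from a \code{\link{city_config}}. Deterministic given the
#' config seed: each component (populations, clinic locations, physician
#' counts) uses its own seed derived from it, so outputs are reproducible
#' draw for draw.
#'
#' @param config a \code{\link{city_config}} (or a preset from
#'   \code{\link{scenario_presets}}).
#' @return list of class \code{"city"}: \code{supply} (id, x, y,
#'   capacity = 1, physicians), \code{demand} (id, x, y, nine pop_*
#'   columns, pop_total), \code{zones} (a \code{\link{zones}} object with
#'   square polygons tiling the rectangle), \code{network} (grid
#'   \code{\link{street_network}}), \code{config}.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  rows <- config$rows; cols <- config$cols; cs <- config$cell_size
  n <- rows * cols
  width <- cols * cs; height <- rows * cs

  # zones: row-major grid of square cells
  ij <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x0 <- (ij$col - 1) * cs; y0 <- (ij$row - 1) * cs
  ids <- sprintf("z%04d", seq_len(n))
  polys <- lapply(seq_len(n), function(k) {
    cbind(x = c(x0[k], x0[k] + cs, x0[k] + cs, x0[k], x0[k]),
          y = c(y0[k], y0[k], y0[k] + cs, y0[k] + cs, y0[k]))
  })
  zn <- zones(ids, polygons = polys)

  # demand: lognormal totals, Dirichlet-multinomial age split
  set.seed(config$seed + 1L)
  tot <- pmax(1, round(stats::rlnorm(n, log(config$pop_median), config$pop_sdlog)))
  alpha <- .age_profile() * config$age_conc
  agemat <- t(vapply(seq_len(n), function(k) {
    as.numeric(stats::rmultinom(1, tot[k], .rdirichlet1(alpha)))
  }, numeric(9)))
  colnames(agemat) <- .age_cols()
  demand <- data.frame(id = ids,
                       x = zn$centroid[, 1], y = zn$centroid[, 2],
                       agemat, pop_total = tot,
                       stringsAsFactors = FALSE, row.names = NULL)

  # supply: clustered + uniform clinic locations inside the rectangle
  set.seed(config$seed + 2L)
  m <- config$n_clinics
  n_clust <- round(config$clinic_clustering * m)
  cbd <- c(width / 2, height / 2)
  cx <- cy <- numeric(0)
  if (n_clust > 0) {
    cx <- pmin(width, pmax(0, stats::rnorm(n_clust, cbd[1], config$cbd_sd)))
    cy <- pmin(height, pmax(0, stats::rnorm(n_clust, cbd[2], config$cbd_sd)))
  }
  if (m - n_clust > 0) {
    cx <- c(cx, stats::runif(m - n_clust, 0, width))
    cy <- c(cy, stats::runif(m - n_clust, 0, height))
  }
  set.seed(config$seed + 3L)
  phys <- 1L + stats::rpois(m, config$physician_lambda)
  supply <- data.frame(id = sprintf("c%03d", seq_len(m)),
                       x = cx, y = cy, capacity = 1, physicians = phys,
                       stringsAsFactors = FALSE)

  # street network: grid graph covering the rectangle
  sp <- config$network_spacing
  nx <- max(2, floor(width / sp) + 1)
  ny <- max(2, floor(height / sp) + 1)
  gid <- function(i, j) (j - 1) * nx + i
  gg <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  nodes <- data.frame(id = as.character(gid(gg$i, gg$j)),
                      x = (gg$i - 1) * sp, y = (gg$j - 1) * sp,
                      stringsAsFactors = FALSE)
  he <- gg[gg$i < nx, ]
  ve <- gg[gg$j < ny, ]
  edges <- data.frame(
    from = as.character(c(gid(he$i, he$j), gid(ve$i, ve$j))),
    to = as.character(c(gid(he$i + 1, he$j), gid(ve$i, ve$j + 1))),
    length = sp, stringsAsFactors = FALSE)
  network <- street_network(nodes, edges)

  structure(list(supply = supply, demand = demand, zones = zn,
                 network = network, config = config),
            class = "city")
}

#' @export
print.city <- function(x, ...) {
  cat(sprintf("Synthetic city: %d zones, %d clinics (%d physicians), %d street nodes\n",
              nrow(x$demand), nrow(x$supply), sum(x$supply$physicians),
              nrow(x$network$nodes)))
  cat(sprintf("  population %d, seed %d\n", sum(x$demand$pop_total),
              x$config$seed))
  invisible(x)
}
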