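# Two-step floating catchment area accessibility.
#
# Step 1: each clinic j gets a supply-to-demand ratio R_j per 1,000
# persons over the demand falling within d0 of it. Step 2: each zone i
# sums the R_j of all clinics within d0 of it. The conventional method
# uses clinic capacity S_j against total population D_k; the optimized
# method uses physician counts P_j against potential users W_k.

.fca_methods <- c("conventional", "optimized")

.validate_supply <- function(supply) {
  stopifnot(is.data.frame(supply))
  if (!all(c("id", "x", "y") %in% names(supply))) {
    stop("supply needs columns id, x, y", call. = FALSE)
  }
  supply$id <- as.character(supply$id)
  if (anyDuplicated(supply$id)) {
    stop("duplicate supply id(s): ",
         paste(unique(supply$id[duplicated(supply$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(supply$capacity)) supply$capacity <- 1
  if (is.null(supply$physicians)) supply$physicians <- 1L
  if (any(supply$capacity <= 0)) stop("capacity must be > 0", call. = FALSE)
  if (any(supply$physicians < 1)) stop("physicians must be >= 1", call. = FALSE)
  supply
}

.demand_weights <- function(demand, method, schedule) {
  if (method == "conventional") {
    if (is.null(demand$pop_total)) demand <- add_potential_users(demand, schedule)
    demand$pop_total
  } else {
    if (is.null(demand$users)) demand <- add_potential_users(demand, schedule)
    demand$users
  }
}

#' Step 1: supply-to-demand ratios
#'
#' For each supply site, the ratio of capacity to the demand located
#' within the threshold, scaled per 1,000 persons:
#' conventional R_j = 1000 * S_j / sum(D_k over d_kj <= d0); optimized
#' R_j = 1000 * P_j / sum(W_k over d_kj <= d0). Sites with no demand in
#' their catchment get an undefined ratio (NA) and a warning.
#'
#' @param supply supply data.frame: \code{id}, \code{x}, \code{y}, and
#'   \code{capacity} (clinic units, default 1) and/or \code{physicians}.
#' @param demand demand data.frame (see \code{\link{add_potential_users}}).
#' @param dm distance matrix, demand rows x supply columns, meters.
#' @param d0 catchment threshold in meters (> 0); membership is d <= d0.
#' @param method \code{"conventional"} or \code{"optimized"}.
#' @param schedule utilization schedule for W (optimized), see
#'   \code{\link{potential_users}}.
#' @return data.frame \code{id}, \code{ratio} (supply units per 1,000
#'   persons, NA when undefined), \code{demand_in_catchment},
#'   \code{defined}; attributes \code{d0}, \code{method}.
#' @export
step1_supply_ratios <- function(supply, demand, dm, d0,
                                method = c("conventional", "optimized"),
                                schedule = "montreal") {
  method <- match.arg(method)
  .check_scalar(d0, "d0")
  supply <- .validate_supply(supply)
  demand$id <- as.character(demand$id)
  if (!all(supply$id %in% colnames(dm)) || !all(demand$id %in% rownames(dm))) {
    stop("distance matrix does not cover all supply/demand ids", call. = FALSE)
  }
  dmat <- dm[demand$id, supply$id, drop = FALSE]
  within <- dmat <= d0
  wts <- .demand_weights(demand, method, schedule)
  denom <- as.numeric(crossprod(within, wts))
  num <- if (method == "conventional") supply$capacity else supply$physicians
  ratio <- ifelse(denom > 0, 1000 * num / denom, NA_real_)
  n_empty <- sum(denom == 0)
  if (n_empty > 0) {
    warning(sprintf("%d supply site(s) with no demand within %g m: ratio undefined",
                    n_empty, d0), call. = FALSE)
  }
  out <- data.frame(id = supply$id, ratio = ratio,
                    demand_in_catchment = denom,
                    defined = denom > 0, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "method") <- method
  out
}

#' Step 2: accessibility scores
#'
#' For each demand zone, the sum of the defined supply-to-demand ratios of
#' all supply sites within the threshold. Zones with no site within d0 get
#' a missing score (NA, not zero) — they are outside every catchment.
#'
#' @param ratios output of \code{\link{step1_supply_ratios}}.
#' @param demand demand data.frame.
#' @param dm distance matrix, demand rows x supply columns, meters.
#' @param d0 threshold in meters; must equal the step-1 threshold unless
#'   \code{allow_threshold_mismatch}.
#' @param allow_threshold_mismatch permit a different step-2 threshold.
#' @return data.frame \code{id}, \code{score} (supply units per 1,000
#'   persons; NA when no site in range), \code{defined}; attributes
#'   \code{d0}, \code{method}.
#' @export
step2_accessibility <- function(ratios, demand, dm, d0,
                                allow_threshold_mismatch = FALSE) {
  .check_scalar(d0, "d0")
  r_d0 <- attr(ratios, "d0")
  if (!is.null(r_d0) && !isTRUE(all.equal(r_d0, d0)) && !allow_threshold_mismatch) {
    stop(sprintf("step-1 threshold (%g m) differs from step-2 threshold (%g m); ",
                 r_d0, d0),
         "set allow_threshold_mismatch = TRUE to override", call. = FALSE)
  }
  demand$id <- as.character(demand$id)
  dmat <- dm[demand$id, ratios$id, drop = FALSE]
  within <- dmat <= d0
  rvals <- ifelse(ratios$defined, ratios$ratio, 0)
  score <- as.numeric(within %*% rvals)
  reachable <- rowSums(within) > 0
  score[!reachable] <- NA_real_
  out <- data.frame(id = demand$id, score = score, defined = reachable,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "method") <- attr(ratios, "method")
  out
}

#' Two-step floating catchment area accessibility
#'
#' Fits the 2SFCA accessibility surface for one method and one catchment
#' threshold. Distances default to straight-line meters between supply and
#' demand coordinates; pass a precomputed matrix (e.g. from
#' \code{\link{shortest_path_distance_matrix}}) for network travel
#' distances.
#'
#' @inheritParams step1_supply_ratios
#' @param distances optional distance matrix (demand rows x supply
#'   columns, meters). Computed as Euclidean from coordinates when NULL.
#' @return Object of class \code{"fca"}: list with \code{scores} (data
#'   frame id, score, defined), \code{ratios}, \code{d0}, \code{method},
#'   \code{metric}, \code{n_defined}, \code{n_zones},
#'   \code{n_empty_catchment_sites}, plus the input tables. Methods:
#'   \code{print}, \code{summary}, \code{coef} (named score vector),
#'   \code{plot}, \code{as.data.frame}.
#' @examples
#' city <- generate_city(scenario_presets()$toy9)
#' fit <- fca(city$supply, city$demand, d0 = 1000, method = "conventional")
#' summary(fit)
#' @export
fca <- function(supply, demand, distances = NULL, d0 = 1000,
                method = c("conventional", "optimized"),
                schedule = "montreal") {
  method <- match.arg(method)
  supply <- .validate_supply(supply)
  stopifnot(is.data.frame(demand))
  demand$id <- as.character(demand$id)
  demand <- if (all(c("pop_total", "users") %in% names(demand))) demand
            else add_potential_users(demand, schedule)
  if (is.null(distances)) {
    distances <- euclidean_distance_matrix(demand, supply)
  }
  metric <- attr(distances, "metric")
  if (is.null(metric)) metric <- "unknown"
  ratios <- step1_supply_ratios(supply, demand, distances, d0, method, schedule)
  scores <- step2_accessibility(ratios, demand, distances, d0)
  structure(list(
    call = match.call(),
    scores = scores,
    ratios = ratios,
    supply = supply,
    demand = demand[, intersect(c("id", "x", "y", "pop_total", "users"),
                                names(demand))],
    d0 = d0,
    method = method,
    metric = metric,
    n_zones = nrow(demand),
    n_defined = sum(scores$defined),
    n_empty_catchment_sites = sum(!ratios$defined)
  ), class = "fca")
}

#' @rdname fca
#' @export
run_2sfca <- fca

#' @export
print.fca <- function(x, ...) {
  unit <- if (x$method == "conventional") "clinics" else "physicians"
  cat(sprintf("Two-step floating catchment area (%s method)\n", x$method))
  cat(sprintf("  threshold: %g m (%s distance)\n", x$d0, x$metric))
  cat(sprintf("  zones with access: %d of %d\n", x$n_defined, x$n_zones))
  if (x$n_empty_catchment_sites > 0) {
    cat(sprintf("  supply sites with empty catchment: %d\n",
                x$n_empty_catchment_sites))
  }
  s <- x$scores$score[x$scores$defined]
  if (length(s)) {
    cat(sprintf("  accessibility (%s per 1,000): mean %.4f, range [%.4f, %.4f]\n",
                unit, mean(s), min(s), max(s)))
  }
  invisible(x)
}

#' @export
summary.fca <- function(object, ...) {
  structure(list(
    method = object$method, d0 = object$d0, metric = object$metric,
    n_zones = object$n_zones, n_defined = object$n_defined,
    n_empty_catchment_sites = object$n_empty_catchment_sites,
    stats = summarize_scores(object)
  ), class = "summary.fca")
}

#' @export
print.summary.fca <- function(x, ...) {
  cat(sprintf("2SFCA accessibility, %s method, d0 = %g m (%s)\n",
              x$method, x$d0, x$metric))
  cat(sprintf("zones: %d (%d with access, %d without)\n",
              x$n_zones, x$n_defined, x$n_zones - x$n_defined))
  if (x$n_empty_catchment_sites > 0)
    cat(sprintf("supply sites with empty catchment: %d\n",
                x$n_empty_catchment_sites))
  cat("\nAccessibility scores (supply units per 1,000 persons):\n")
  print(round(x$stats, 4))
  invisible(x)
}

#' @export
coef.fca <- function(object, ...) {
  stats::setNames(object$scores$score, object$scores$id)
}

#' @export
as.data.frame.fca <- function(x, ...) {
  cbind(x$scores, method = x$method, d0_m = x$d0, metric = x$metric,
        stringsAsFactors = FALSE)
}

#' @export
plot.fca <- function(x, ...) {
  ok <- x$scores$defined
  s <- x$scores$score
  pal <- grDevices::hcl.colors(9, "YlOrRd", rev = TRUE)
  col <- rep("grey85", length(s))
  if (any(ok)) {
    br <- stats::quantile(s[ok], probs = seq(0, 1, length.out = 10), type = 7)
    br[1] <- br[1] - 1e-9
    col[ok] <- pal[cut(s[ok], breaks = unique(br), include.lowest = TRUE)]
  }
  graphics::plot(x$demand$x, x$demand$y, col = col, pch = 15, asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("2SFCA %s, d0 = %g m", x$method, x$d0), ...)
  graphics::points(x$supply$x, x$supply$y, pch = 17, cex = 1.1)
  invisible(x)
}

#' Descriptive statistics of accessibility scores
#'
#' N, mean, SD, min, max and the 5/25/50/75/95 percentiles of the defined
#' scores only; zones without access are excluded, so N varies with the
#' threshold.
#'
#' @param scores an \code{fca} fit, a step-2 scores data.frame, or a
#'   numeric vector (NA = missing).
#' @return Named numeric vector of statistics.
#' @export
summarize_scores <- function(scores) {
  s <- if (inherits(scores, "fca")) scores$scores$score
       else if (is.data.frame(scores)) scores$score
       else as.numeric(scores)
  if (all(is.na(s))) stop("all accessibility scores are missing", call. = FALSE)
  .summary_stats(s)
}
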