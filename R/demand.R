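# Demand weighting: convert age-structured zone populations into
# potential clinic users with age-specific utilization proportions.

#' Age group labels
#'
#' The nine age bins the utilization schedules are defined over:
#' 0-14, 15-19, then ten-year groups to 79, and 80+.
#'
#' @return Character vector of the nine bin labels, in order.
#' @export
age_bins <- function() {
  c("0-14", "15-19", "20-29", "30-39", "40-49",
    "50-59", "60-69", "70-79", "80+")
}

# demand-table population column names, aligned with age_bins()
.age_cols <- function() {
  paste0("pop_", c("0_14", "15_19", "20_29", "30_39", "40_49",
                   "50_59", "60_69", "70_79", "80_plus"))
}

#' Utilization schedule
#'
#' Validates a set of utilization coefficients: one proportion in [0, 1]
#' per age bin, the fraction of that age group who visited a clinic in the
#' past year.
#'
#' @param x named numeric vector over exactly the bins of
#'   \code{\link{age_bins}}.
#' @return The validated vector, reordered to the canonical bin order,
#'   with class \code{"utilization_schedule"}.
#' @export
utilization_schedule <- function(x) {
  bins <- age_bins()
  if (is.null(names(x)) || !setequal(names(x), bins)) {
    miss <- setdiff(bins, names(x))
    stop("schedule must cover exactly the nine age bins",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  x <- x[bins]
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("utilization coefficients must lie in [0, 1]", call. = FALSE)
  }
  class(x) <- "utilization_schedule"
  x
}

#' Packaged utilization schedules
#'
#' Loads the utilization schedules shipped with the package: past-year
#' clinic-utilization proportions by age group for Montreal, Quebec and
#' Canada (2005-2006 community health survey estimates). The Montreal
#' column is the default demand weighting.
#'
#' @return Named list of three \code{\link{utilization_schedule}} objects:
#'   \code{montreal}, \code{quebec}, \code{canada}.
#' @export
load_default_schedules <- function() {
  path <- system.file("extdata", "utilization_schedules.csv",
                      package = "twostepfca", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  out <- lapply(c("montreal", "quebec", "canada"), function(col) {
    utilization_schedule(stats::setNames(tab[[col]], tab$age_group))
  })
  names(out) <- c("montreal", "quebec", "canada")
  out
}

.resolve_schedule <- function(schedule) {
  if (is.null(schedule)) schedule <- "montreal"
  if (is.character(schedule) && length(schedule) == 1) {
    defaults <- load_default_schedules()
    if (!schedule %in% names(defaults)) {
      stop("unknown schedule '", schedule, "'; packaged: ",
           paste(names(defaults), collapse = ", "), call. = FALSE)
    }
    return(defaults[[schedule]])
  }
  utilization_schedule(schedule)
}

#' Potential users of clinics
#'
#' Weights an age-structured population by the utilization schedule:
#' W = sum over age bins of c_x * P_x, where P_x is the head count in bin
#' x and c_x the proportion of that bin using clinics in the past year.
#' W is kept fractional (not rounded).
#'
#' @param age_counts a named numeric vector over the bins of
#'   \code{\link{age_bins}}, or a matrix/data.frame with one column per bin
#'   (bin labels or the demand-table \code{pop_*} column names).
#' @param schedule a \code{\link{utilization_schedule}}, a packaged
#'   schedule name ("montreal", "quebec", "canada"), or NULL for montreal.
#' @return Numeric: potential users per row (persons).
#' @export
potential_users <- function(age_counts, schedule = "montreal") {
  sched <- .resolve_schedule(schedule)
  bins <- age_bins()
  if (is.null(dim(age_counts))) {
    age_counts <- matrix(age_counts, nrow = 1,
                         dimnames = list(NULL, names(age_counts)))
  }
  m <- as.matrix(age_counts)
  cn <- colnames(m)
  if (!is.null(cn) && all(.age_cols() %in% cn)) {
    m <- m[, .age_cols(), drop = FALSE]
  } else if (!is.null(cn) && all(bins %in% cn)) {
    m <- m[, bins, drop = FALSE]
  } else if (ncol(m) != length(bins)) {
    stop("age_counts must cover the nine age bins", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("age counts must be finite and non-negative", call. = FALSE)
  }
  as.numeric(m %*% unclass(sched))
}

#' Attach totals and potential users to a demand table
#'
#' Adds (or recomputes) \code{pop_total} = sum of the nine age-bin counts
#' and \code{users} = \code{\link{potential_users}} under the given
#' schedule.
#'
#' @param demand demand data.frame with columns \code{id}, \code{x},
#'   \code{y} and the nine \code{pop_*} age-bin columns.
#' @inheritParams potential_users
#' @return The demand data.frame with \code{pop_total} and \code{users}.
#' @export
add_potential_users <- function(demand, schedule = "montreal") {
  stopifnot(is.data.frame(demand))
  if (!all(.age_cols() %in% names(demand))) {
    stop("demand table lacks age-bin columns: ",
         paste(setdiff(.age_cols(), names(demand)), collapse = ", "),
         call. = FALSE)
  }
  demand$pop_total <- rowSums(demand[, .age_cols()])
  demand$users <- potential_users(demand[, .age_cols()], schedule)
  demand
}

#' Descriptive statistics of population and potential users
#'
#' N, mean, SD, min, max and the 5/25/50/75/95 percentiles (linear
#' interpolation between order statistics) of total population and
#' potential users across zones.
#'
#' @param demand demand data.frame (with \code{pop_total} and \code{users};
#'   computed from the age bins via the montreal schedule if absent).
#' @return data.frame with one row per statistic and columns
#'   \code{total_population}, \code{potential_users}.
#' @export
summarize_demand <- function(demand) {
  stopifnot(is.data.frame(demand), nrow(demand) > 0)
  if (!all(c("pop_total", "users") %in% names(demand))) {
    demand <- add_potential_users(demand)
  }
  out <- data.frame(
    total_population = .summary_stats(demand$pop_total),
    potential_users = .summary_stats(demand$users)
  )
  out
}
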