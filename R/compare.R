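# Comparison of the conventional and optimized accessibility surfaces:
# 0-100 rescaling, per-zone difference scores D, Spearman rank
# correlation, t-tests, and the difference percentile table.

#' Rescale scores to 0-100
#'
#' value -> 100 * (value - min) / (max - min), computed over the defined
#' (non-NA) values; NA positions are preserved. The minimum maps to 0 and
#' the maximum to 100. Constant input has no defined rescaling and errors.
#'
#' @param x numeric vector with at least two defined values and a
#'   positive range.
#' @return Numeric vector on [0, 100] (NA preserved).
#' @export
rescale_0_100 <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least two defined values to rescale", call. = FALSE)
  rng <- range(x[ok])
  if (diff(rng) == 0) stop("cannot rescale a constant vector (zero range)", call. = FALSE)
  out <- x
  out[ok] <- 100 * (x[ok] - rng[1]) / (rng[2] - rng[1])
  out
}

#' Difference scores between the two methods
#'
#' Rescales the conventional and the optimized accessibility scores to
#' 0-100 (within the zones where both are defined) and takes
#' D = rescaled(conventional) - rescaled(optimized). A negative D means
#' the conventional method under-estimates accessibility relative to the
#' optimized one; positive D, over-estimation.
#'
#' @param conv,opt two \code{\link{fca}} fits (or step-2 score data
#'   frames) at the same threshold over the same zones.
#' @return data.frame of class \code{"fca_diff"}: \code{id},
#'   \code{score_conv}, \code{score_opt}, \code{rescaled_conv},
#'   \code{rescaled_opt}, \code{D}; attribute \code{d0}.
#' @export
difference_scores <- function(conv, opt) {
  sc <- if (inherits(conv, "fca")) conv$scores else conv
  so <- if (inherits(opt, "fca")) opt$scores else opt
  d0c <- if (inherits(conv, "fca")) conv$d0 else attr(conv, "d0")
  d0o <- if (inherits(opt, "fca")) opt$d0 else attr(opt, "d0")
  if (!is.null(d0c) && !is.null(d0o) && !isTRUE(all.equal(d0c, d0o))) {
    stop(sprintf("threshold mismatch: %g m vs %g m", d0c, d0o), call. = FALSE)
  }
  if (!setequal(sc$id, so$id)) {
    stop("the two fits cover different zone sets", call. = FALSE)
  }
  so <- so[match(sc$id, so$id), ]
  both <- sc$defined & so$defined
  if (sum(both) < 2) stop("fewer than two zones with both scores defined", call. = FALSE)
  out <- data.frame(
    id = sc$id[both],
    score_conv = sc$score[both],
    score_opt = so$score[both],
    stringsAsFactors = FALSE
  )
  out$rescaled_conv <- rescale_0_100(out$score_conv)
  out$rescaled_opt <- rescale_0_100(out$score_opt)
  out$D <- out$rescaled_conv - out$rescaled_opt
  attr(out, "d0") <- d0c
  class(out) <- c("fca_diff", "data.frame")
  out
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of the average-ranked data (ties get
#' average ranks); the two-sided p-value uses the t approximation with
#' n - 2 degrees of freedom.
#'
#' @param a,b numeric vectors of equal length >= 3 (pairs with any NA are
#'   dropped).
#' @return list with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("inputs differ in length", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}

#' t-test on difference scores
#'
#' Default mode is a one-sample t-test of mean(D) = 0 over zones. The
#' alternative \code{two_sample} mode is a Welch two-sample test of the
#' rescaled conventional against the rescaled optimized scores. Both
#' report the mean of D. Zero-variance input with a non-zero mean is
#' degenerate: t is +/- Inf and p = 0, flagged.
#'
#' @param D an \code{\link{difference_scores}} result or a numeric vector
#'   of difference scores.
#' @param mode \code{"one_sample"} (default) or \code{"two_sample"}.
#' @return list with \code{t}, \code{p_value}, \code{mean_D}, \code{n},
#'   \code{mode}, \code{degenerate}.
#' @export
t_test_differences <- function(D, mode = c("one_sample", "two_sample")) {
  mode <- match.arg(mode)
  diff_tab <- if (inherits(D, "fca_diff")) D else NULL
  d <- if (!is.null(diff_tab)) diff_tab$D else as.numeric(D)
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need at least two difference scores", call. = FALSE)
  mean_d <- mean(d)
  if (mode == "two_sample") {
    if (is.null(diff_tab)) {
      stop("two_sample mode needs a difference_scores() result ",
           "(rescaled score columns required)", call. = FALSE)
    }
    a <- diff_tab$rescaled_conv; b <- diff_tab$rescaled_opt
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      deg <- TRUE
      tval <- if (mean_d == 0) 0 else sign(mean_d) * Inf
      p <- if (mean_d == 0) 1 else 0
    } else {
      deg <- FALSE
      tt <- stats::t.test(a, b, var.equal = FALSE)
      tval <- unname(tt$statistic); p <- tt$p.value
    }
  } else {
    if (stats::sd(d) == 0) {
      deg <- mean_d != 0
      tval <- if (mean_d == 0) 0 else sign(mean_d) * Inf
      p <- if (mean_d == 0) 1 else 0
    } else {
      deg <- FALSE
      tt <- stats::t.test(d, mu = 0)
      tval <- unname(tt$statistic); p <- tt$p.value
    }
  }
  list(t = tval, p_value = p, mean_D = mean_d, n = length(d),
       mode = mode, degenerate = deg)
}

#' Difference percentile table
#'
#' One-row summary of the difference scores at a threshold: mean, p-value
#' of the one-sample t-test against 0, and the 5/10/25/50/75/90/95
#' percentiles (linear interpolation).
#'
#' @param D a \code{\link{difference_scores}} result or numeric vector.
#' @return One-row data.frame: \code{mean}, \code{p_value}, \code{P5},
#'   \code{P10}, \code{P25}, \code{P50}, \code{P75}, \code{P90},
#'   \code{P95}.
#' @export
difference_percentile_table <- function(D) {
  d <- if (inherits(D, "fca_diff")) D$D else as.numeric(D)
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no difference scores", call. = FALSE)
  probs <- c(.05, .10, .25, .50, .75, .90, .95)
  q <- stats::quantile(d, probs = probs, type = 7, names = FALSE)
  p <- if (length(d) >= 2 && stats::sd(d) > 0) {
    stats::t.test(d, mu = 0)$p.value
  } else if (length(d) >= 2 && mean(d) == 0) 1 else NA_real_
  out <- data.frame(mean = mean(d), p_value = p)
  out[paste0("P", probs * 100)] <- as.list(q)
  out
}

#' Compare conventional and optimized accessibility
#'
#' Convenience wrapper producing the full method comparison at one
#' threshold: difference scores, Spearman rank correlation between the
#' raw scores, the t-test on D, and the difference percentile table.
#'
#' @inheritParams difference_scores
#' @return list with \code{differences}, \code{spearman}, \code{t_test},
#'   \code{percentiles}, \code{d0}.
#' @export
compare_methods <- function(conv, opt) {
  d <- difference_scores(conv, opt)
  list(
    differences = d,
    spearman = spearman_rho(d$score_conv, d$score_opt),
    t_test = t_test_differences(d),
    percentiles = difference_percentile_table(d),
    d0 = attr(d, "d0")
  )
}
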