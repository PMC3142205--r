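# Shared helpers: point coercion, summary statistics, validation.

# Coerce point input (data.frame with x/y, two-column matrix, or length-2
# numeric) to a numeric matrix with columns x, y and optional id rownames.
.as_points <- function(p, name = "points") {
  if (is.data.frame(p)) {
    if (!all(c("x", "y") %in% names(p))) {
      stop(sprintf("'%s' must have columns 'x' and 'y'", name), call. = FALSE)
    }
    m <- cbind(x = as.numeric(p$x), y = as.numeric(p$y))
    if (!is.null(p$id)) rownames(m) <- as.character(p$id)
  } else if (is.matrix(p)) {
    if (ncol(p) < 2) stop(sprintf("'%s' must have two columns", name), call. = FALSE)
    m <- p[, 1:2, drop = FALSE]
    colnames(m) <- c("x", "y")
  } else if (is.numeric(p) && length(p) == 2) {
    m <- matrix(as.numeric(p), nrow = 1, dimnames = list(NULL, c("x", "y")))
  } else {
    stop(sprintf("cannot interpret '%s' as planar points", name), call. = FALSE)
  }
  if (nrow(m) == 0) stop(sprintf("'%s' is empty", name), call. = FALSE)
  if (!all(is.finite(m))) {
    stop(sprintf("'%s' contains non-finite coordinates", name), call. = FALSE)
  }
  if (identical(attr(p, "crs"), "geographic")) {
    stop(sprintf("'%s' carries geographic (lon/lat) coordinates; planar meters required", name),
         call. = FALSE)
  }
  m
}

.point_ids <- function(m, prefix) {
  if (!is.null(rownames(m))) rownames(m) else paste0(prefix, seq_len(nrow(m)))
}

# N / mean / SD / min / max / percentiles, linear interpolation between
# order statistics (quantile type 7).
.summary_stats <- function(x, probs = c(.05, .25, .50, .75, .95)) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no defined values to summarize", call. = FALSE)
  q <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
  out <- c(length(x), mean(x), stats::sd(x), min(x), max(x), q)
  names(out) <- c("N", "Mean", "SD", "Min", "Max",
                  paste0("P", round(probs * 100)))
  out
}

.check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
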