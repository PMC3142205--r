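# Independent brute-force oracles used to check the vectorized
# implementations, plus small random-instance builders.

# pairwise distances by explicit double loop
loop_euclid <- function(o, d) {
  m <- matrix(NA_real_, nrow(o), nrow(d))
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(nrow(d))) {
      m[i, j] <- sqrt((o[i, 1] - d[j, 1])^2 + (o[i, 2] - d[j, 2])^2)
    }
  }
  m
}

# literal two-step floating catchment area: step 1 and step 2 as written,
# one site / one zone at a time
fca_oracle <- function(sup_weight, dem_weight, dmat, d0) {
  nj <- length(sup_weight); ni <- length(dem_weight)
  R <- rep(NA_real_, nj)
  for (j in seq_len(nj)) {
    denom <- 0
    for (k in seq_len(ni)) if (dmat[k, j] <= d0) denom <- denom + dem_weight[k]
    if (denom > 0) R[j] <- 1000 * sup_weight[j] / denom
  }
  A <- rep(NA_real_, ni)
  for (i in seq_len(ni)) {
    in_range <- FALSE; acc <- 0
    for (j in seq_len(nj)) {
      if (dmat[i, j] <= d0) {
        in_range <- TRUE
        if (!is.na(R[j])) acc <- acc + R[j]
      }
    }
    if (in_range) A[i] <- acc
  }
  list(R = R, A = A)
}

# Moran's I by explicit double loop over all ordered pairs
moran_oracle <- function(y, w) {
  n <- length(y); yb <- mean(y)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (y[i] - yb) * (y[j] - yb)
      s0 <- s0 + w[i, j]
    }
  }
  (n / s0) * num / sum((y - yb)^2)
}

# shortest path by exhaustive simple-path enumeration (tiny graphs only)
enumerate_shortest <- function(edges, from, to) {
  if (from == to) return(0)
  best <- Inf
  nbrs <- function(v) {
    rbind(edges[edges$from == v, c("to", "length")],
          stats::setNames(edges[edges$to == v, c("from", "length")],
                          c("to", "length")))
  }
  walk <- function(v, visited, len) {
    if (len >= best) return(invisible())
    nb <- nbrs(v)
    for (k in seq_len(nrow(nb))) {
      u <- nb$to[k]
      if (u == to) {
        best <<- min(best, len + nb$length[k])
      } else if (!u %in% visited) {
        walk(u, c(visited, u), len + nb$length[k])
      }
    }
  }
  walk(from, from, 0)
  best
}

# random small supply/demand instance on a square of given side (meters)
rand_instance <- function(seed, n_zones = 40, n_clinics = 12, side = 5000) {
  set.seed(seed)
  demand <- data.frame(
    id = paste0("z", seq_len(n_zones)),
    x = runif(n_zones, 0, side), y = runif(n_zones, 0, side))
  age <- t(vapply(seq_len(n_zones), function(k) {
    as.numeric(rmultinom(1, sample(100:1500, 1), rep(1 / 9, 9)))
  }, numeric(9)))
  colnames(age) <- paste0("pop_", c("0_14", "15_19", "20_29", "30_39", "40_49",
                                    "50_59", "60_69", "70_79", "80_plus"))
  demand <- cbind(demand, age)
  supply <- data.frame(
    id = paste0("c", seq_len(n_clinics)),
    x = runif(n_clinics, 0, side), y = runif(n_clinics, 0, side),
    capacity = sample(1:3, n_clinics, replace = TRUE),
    physicians = sample(1:12, n_clinics, replace = TRUE))
  list(supply = supply, demand = demand)
}

# identity schedule (every coefficient 1) for reduction checks
identity_schedule <- function() {
  utilization_schedule(stats::setNames(rep(1, 9), age_bins()))
}

# unit-square grid of zone polygons (nr x nc), cell side `cs`
grid_zones <- function(nr, nc, cs = 1) {
  ij <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  polys <- lapply(seq_len(nr * nc), function(k) {
    x0 <- (ij$col[k] - 1) * cs; y0 <- (ij$row[k] - 1) * cs
    cbind(x = c(x0, x0 + cs, x0 + cs, x0, x0),
          y = c(y0, y0, y0 + cs, y0 + cs, y0))
  })
  zones(sprintf("g%03d", seq_len(nr * nc)), polygons = polys)
}
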