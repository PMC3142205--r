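test_that("Moran's I matches direct evaluation and its null expectation", {
  # two-unit toy, statistic core only (the user-facing guard needs n >= 3)
  w2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(twostepfca:::.moran_stat(c(1, -1), w2), -1)

  expect_equal(morans_i(rnorm(5), diag(0, 5) + 1 - diag(5))$expected, -0.25)

  set.seed(9)
  zn <- grid_zones(4, 4)
  w <- queen_contiguity(zn)
  y <- rnorm(16)
  m <- morans_i(y, w)
  expect_equal(m$I, moran_oracle(y, unclass(w)), tolerance = 1e-12)
  expect_equal(m$z, (m$I - m$expected) / sqrt(m$variance))

  # affine invariance of the statistic
  expect_equal(morans_i(3 * y - 7, w)$I, m$I)

  expect_error(morans_i(rep(1, 16), w), "constant")
  expect_error(morans_i(y, matrix(0, 16, 16)), "positive entries")
})

test_that("Moran's I agrees with an independent reference implementation", {
  skip_if_not_installed("ape")
  set.seed(31)
  zn <- grid_zones(5, 5)
  w <- queen_contiguity(zn)
  y <- rnorm(25)
  # ape row-standardizes and uses the randomization variance
  m <- morans_i(y, row_standardize(w), assumption = "randomization")
  ref <- ape::Moran.I(y, unclass(w), scaled = FALSE)
  expect_equal(m$I, ref$observed, tolerance = 1e-12)
  expect_equal(m$expected, ref$expected, tolerance = 1e-12)
  expect_equal(sqrt(m$variance), ref$sd, tolerance = 1e-10)
})

test_that("Moran's I separates smooth surfaces from checkerboards", {
  zn <- grid_zones(5, 5)
  w <- queen_contiguity(zn)
  ij <- expand.grid(col = 1:5, row = 1:5)
  smooth <- ij$col + ij$row              # gradient surface
  checker <- (-1)^(ij$col + ij$row)      # alternating surface
  ms <- morans_i(smooth, w)
  mc <- morans_i(checker, w)
  expect_gt(ms$I, ms$expected)
  expect_gt(ms$z, 0)
  expect_lt(mc$I, mc$expected)
  expect_lt(mc$z, 0)
})

test_that("weighted mean center averages locations by weight", {
  expect_equal(weighted_mean_center(matrix(c(4, 9), 1)), c(x = 4, y = 9))
  expect_equal(weighted_mean_center(matrix(c(0, 0, 2, 0), 2, byrow = TRUE),
                                    weights = c(1, 3)),
               c(x = 1.5, y = 0))
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_equal(weighted_mean_center(sq), c(x = .5, y = .5))
  # translation equivariance
  expect_equal(weighted_mean_center(sq + 10), c(x = 10.5, y = 10.5))
  expect_error(weighted_mean_center(sq, weights = rep(0, 4)), "positive sum")
})

test_that("the deviational ellipse matches a covariance-eigen oracle", {
  set.seed(17)
  p <- cbind(x = rnorm(5, sd = 30), y = rnorm(5, sd = 8))
  wts <- c(1, 2, 1, 3, 1)
  sde <- standard_deviational_ellipse(p, wts)
  # oracle: eigenvalues of the weighted (uncorrected) covariance matrix
  ctr <- weighted_mean_center(p, wts)
  xc <- p[, 1] - ctr["x"]; yc <- p[, 2] - ctr["y"]
  cm <- matrix(c(sum(wts * xc^2), sum(wts * xc * yc),
                 sum(wts * xc * yc), sum(wts * yc^2)), 2) / sum(wts)
  ev <- sort(sqrt(eigen(cm, symmetric = TRUE)$values))
  expect_equal(sort(c(sde$sigma_x, sde$sigma_y)), ev, tolerance = 1e-10)

  # directional limit: near-horizontal line -> theta near 0, sigma_x >> sigma_y
  line <- cbind(x = seq(0, 100, length.out = 20),
                y = rnorm(20, sd = 1e-3))
  sl <- standard_deviational_ellipse(line)
  expect_lt(abs(sl$theta_deg), 1)
  expect_gt(sl$sigma_x / sl$sigma_y, 100)

  # isotropy limit: axis ratio tends to 1 for a large circular cloud
  set.seed(18)
  cloud <- cbind(x = rnorm(4000), y = rnorm(4000))
  sc <- standard_deviational_ellipse(cloud)
  expect_equal(sc$sigma_x / sc$sigma_y, 1, tolerance = 0.1)

  expect_warning(standard_deviational_ellipse(cbind(0:4, 0:4)), "degenerate")
})

test_that("nearest-neighbour index separates lattices from clusters", {
  lat <- as.matrix(expand.grid(x = 0:9, y = 0:9))
  nni <- nearest_neighbour_index(lat, area = 100)
  expect_equal(nni$observed_mean, 1)
  expect_equal(nni$expected_mean, 0.5)
  expect_equal(nni$index, 2)
  expect_gt(nni$z, 0)

  expect_warning(
    co <- nearest_neighbour_index(matrix(c(5, 5, 5, 5), 2, byrow = TRUE),
                                  area = 100),
    "coincident")
  expect_equal(co$index, 0)

  set.seed(23)
  clust <- cbind(x = rnorm(50, 500, 10), y = rnorm(50, 500, 10))
  expect_lt(nearest_neighbour_index(clust, area = 1000^2)$index, 1)
  expect_error(nearest_neighbour_index(lat, area = -3), "> 0")
})

test_that("points are counted per zone with an inclusive boundary and no loss", {
  zn <- grid_zones(3, 3, cs = 10)
  # centroid of first cell, a shared-boundary point, and an outside point
  pts <- rbind(c(5, 5), c(10, 10), c(200, 200))
  r <- points_per_zone(pts, zn)
  expect_equal(sum(r$counts) + r$unassigned, 3)
  expect_equal(unname(r$counts["g001"]), 2)   # boundary point assigned once
  expect_equal(r$unassigned, 1)

  set.seed(41)
  rp <- cbind(x = runif(200, 0, 30), y = runif(200, 0, 30))
  rr <- points_per_zone(rp, zn)
  expect_equal(sum(rr$counts), 200)
  # loop oracle: integer cell arithmetic for interior points
  cell <- pmin(floor(rp[, 1] / 10), 2) + 3 * pmin(floor(rp[, 2] / 10), 2) + 1
  expect_equal(unname(rr$counts), as.integer(table(factor(cell, levels = 1:9))))
})
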