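test_that("Euclidean distances match hand values and a loop oracle", {
  d <- euclidean_distance_matrix(matrix(c(0, 0), 1), matrix(c(3, 4), 1))
  expect_equal(as.numeric(d), 5)
  expect_equal(as.numeric(euclidean_distance_matrix(c(2, 7), c(2, 7))), 0)

  set.seed(11)
  o <- matrix(runif(10, 0, 100), 5)
  dd <- matrix(runif(8, 0, 100), 4)
  expect_equal(unclass(euclidean_distance_matrix(o, dd)),
               loop_euclid(o, dd), ignore_attr = TRUE)
  expect_identical(attr(euclidean_distance_matrix(o, dd), "metric"), "euclidean")

  expect_error(euclidean_distance_matrix(matrix(c(NA, 0), 1), dd), "non-finite")
  expect_error(euclidean_distance_matrix(matrix(numeric(0), 0, 2), dd), "empty")
})

test_that("network shortest paths follow Dijkstra with Inf for unreachable pairs", {
  nodes <- data.frame(id = c("a", "b", "c", "d", "e"),
                      x = c(0, 10, 5, 100, 110), y = c(0, 0, 8, 0, 0))
  edges <- data.frame(from = c("a", "b", "a", "d"),
                      to = c("b", "c", "c", "e"),
                      length = c(7, 1, 3, 4))
  net <- street_network(nodes, edges)
  pts <- nodes[, c("x", "y")]

  # two nodes joined by a single edge of length 7
  pair <- street_network(nodes[1:2, ], edges[1, ])
  expect_equal(as.numeric(shortest_path_distance_matrix(pair, pts[1, ], pts[2, ])), 7)

  # triangle with edges 1, 1, 3: the two short edges beat the direct one
  tn <- street_network(
    data.frame(id = 1:3, x = c(0, 1, 2), y = 0),
    data.frame(from = c(1, 2, 1), to = c(2, 3, 3), length = c(1, 1, 3)))
  d13 <- shortest_path_distance_matrix(tn, c(0, 0), c(2, 0))
  expect_equal(as.numeric(d13), 2)

  # disconnected component
  dae <- shortest_path_distance_matrix(net, pts[1, ], pts[5, ])
  expect_identical(as.numeric(dae), Inf)

  expect_error(street_network(nodes, transform(edges, length = c(7, -1, 3, 4))),
               "positive")
})

test_that("Dijkstra agrees with exhaustive path enumeration on small graphs", {
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    nodes <- data.frame(id = as.character(seq_len(n)),
                        x = runif(n, 0, 10), y = runif(n, 0, 10))
    pairs <- t(combn(seq_len(n), 2))
    keep <- pairs[runif(nrow(pairs)) < 0.6, , drop = FALSE]
    # ensure a connected backbone
    backbone <- cbind(seq_len(n - 1), 2:n)
    em <- unique(rbind(backbone, keep))
    edges <- data.frame(from = as.character(em[, 1]), to = as.character(em[, 2]),
                        length = round(runif(nrow(em), 1, 9), 2))
    net <- street_network(nodes, edges)
    dm <- shortest_path_distance_matrix(net, nodes[, c("x", "y")],
                                        nodes[, c("x", "y")])
    i <- sample(n, 1); j <- sample(n, 1)
    expect_equal(dm[i, j], enumerate_shortest(edges, as.character(i), as.character(j)),
                 tolerance = 1e-12)
  }
})

test_that("snapping picks the nearest node with lowest-id tie-break", {
  net <- street_network(
    data.frame(id = c("7", "2"), x = c(0, 10), y = c(0, 0)),
    data.frame(from = "7", to = "2", length = 10))
  s <- snap_to_network(net, matrix(c(5, 0), 1)) # equidistant
  expect_identical(s$node, "2")
  expect_equal(s$snap_distance, 5)
})

test_that("network distance dominates Euclidean on a grid built from planar edges", {
  city <- generate_city(city_config(rows = 4, cols = 4, cell_size = 250,
                                    n_clinics = 3, seed = 3))
  de <- euclidean_distance_matrix(city$demand, city$supply)
  dn <- shortest_path_distance_matrix(city$network, city$demand, city$supply,
                                      add_access_distance = TRUE)
  expect_true(all(dn - de >= -1e-9))
})

test_that("catchment membership is closed at the threshold and monotone", {
  dm <- matrix(c(400, 600), 2, 1, dimnames = list(c("d1", "d2"), "c1"))
  m <- catchment_members(dm, 500)
  expect_identical(m$demand_by_supply$c1, "d1")
  expect_identical(m$supply_by_demand$d2, character(0))

  # exact tie included (closed inequality)
  mt <- catchment_members(dm, 400)
  expect_identical(mt$demand_by_supply$c1, "d1")

  set.seed(21)
  big <- matrix(runif(200, 0, 2000), 20, 10,
                dimnames = list(paste0("d", 1:20), paste0("c", 1:10)))
  d0 <- median(big)
  mm <- catchment_members(big, d0)
  for (j in 1:10) {
    expect_identical(mm$demand_by_supply[[j]],
                     rownames(big)[which(big[, j] <= d0)])
  }
  # saturation and monotonicity
  all_in <- catchment_members(big, max(big) + 1)
  expect_true(all(lengths(all_in$demand_by_supply) == 20))
  m1 <- catchment_members(big, 500); m2 <- catchment_members(big, 900)
  for (j in 1:10) {
    expect_true(all(m1$demand_by_supply[[j]] %in% m2$demand_by_supply[[j]]))
  }
  expect_error(catchment_members(big, 0), "> 0")
})

test_that("queen contiguity links edge and corner neighbours", {
  zn2 <- grid_zones(1, 2)
  w2 <- queen_contiguity(zn2)
  expect_equal(unname(w2[1, 2]), 1)

  # corner-only contact still counts (queen, not rook)
  corner <- zones(c("a", "b"), polygons = list(
    cbind(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0)),
    cbind(x = c(1, 2, 2, 1, 1), y = c(1, 1, 2, 2, 1))))
  expect_equal(unname(queen_contiguity(corner)["a", "b"]), 1)

  zn9 <- grid_zones(3, 3)
  w9 <- queen_contiguity(zn9)
  expect_identical(w9, t(w9))
  expect_true(all(diag(w9) == 0))
  expect_equal(unname(rowSums(w9)), c(3, 5, 3, 5, 8, 5, 3, 5, 3))

  # 5x5: corner 3, edge 5, interior 8 (geometric enumeration)
  w25 <- queen_contiguity(grid_zones(5, 5))
  expect_equal(sort(unique(rowSums(w25))), c(3, 5, 8))

  expect_error(queen_contiguity(zones("a", centroids = c(0, 0))), "polygon")
})

test_that("inverse-distance-squared weights match 1/d^2 with zero diagonal", {
  w <- inverse_distance_squared_weights(matrix(c(0, 0, 2, 0), 2, byrow = TRUE))
  expect_equal(unname(w[1, 2]), 0.25)
  expect_true(all(diag(w) == 0))

  set.seed(5)
  p <- matrix(runif(12, 0, 50), 6)
  w6 <- inverse_distance_squared_weights(p)
  dl <- loop_euclid(p, p)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(unname(w6[i, j]), if (i == j) 0 else 1 / dl[i, j]^2)
  }
  # homogeneity: scaling coordinates by c scales weights by 1/c^2
  expect_equal(unclass(inverse_distance_squared_weights(3 * p)),
               unclass(w6) / 9, ignore_attr = TRUE)

  expect_error(inverse_distance_squared_weights(rbind(p, p[1, ])), "coincident")
})
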