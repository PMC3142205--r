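# one demand zone with a chosen total population at given coordinates
.zone_row <- function(id, x, y, pop) {
  age <- stats::setNames(as.list(c(pop, rep(0, 8))), twostepfca:::.age_cols())
  cbind(data.frame(id = id, x = x, y = y), age)
}

test_that("step 1 computes per-1000 supply-to-demand ratios with undefined empties", {
  demand <- rbind(.zone_row("z1", 0, 0, 500), .zone_row("z2", 100, 0, 300),
                  .zone_row("z3", 9999, 0, 400))
  supply <- data.frame(id = "c1", x = 0, y = 0, capacity = 2, physicians = 5)
  dm <- euclidean_distance_matrix(demand, supply)
  r <- step1_supply_ratios(supply, demand, dm, 500, "conventional")
  expect_equal(r$ratio, 1000 * 2 / 800)

  one <- .zone_row("z1", 0, 0, 1000)
  s1 <- data.frame(id = "c1", x = 0, y = 0, capacity = 1)
  r1 <- step1_supply_ratios(s1, one, euclidean_distance_matrix(one, s1),
                            500, "conventional")
  expect_equal(r1$ratio, 1)

  far <- data.frame(id = "c2", x = 1e6, y = 0, capacity = 1)
  expect_warning(
    r2 <- step1_supply_ratios(far, one, euclidean_distance_matrix(one, far),
                              500, "conventional"),
    "no demand")
  expect_true(is.na(r2$ratio))
  expect_false(r2$defined)
})

test_that("step 2 sums in-range ratios and distinguishes missing from zero", {
  demand <- rbind(.zone_row("z1", 0, 0, 1000), .zone_row("z2", 50000, 0, 500))
  supply <- data.frame(id = c("c1", "c2"), x = c(0, 10), y = 0,
                       capacity = c(1, 1))
  dm <- euclidean_distance_matrix(demand, supply)
  r <- step1_supply_ratios(supply, demand, dm, 500, "conventional")
  a <- step2_accessibility(r, demand, dm, 500)
  expect_equal(a$score[1], sum(r$ratio))       # both clinics in range
  expect_true(is.na(a$score[2]))               # out of every catchment
  expect_false(a$defined[2])

  expect_error(step2_accessibility(r, demand, dm, 1000), "threshold")
  a2 <- step2_accessibility(r, demand, dm, 1000, allow_threshold_mismatch = TRUE)
  expect_equal(a2$score[1], sum(r$ratio))
})

test_that("optimized reduces to conventional when P = S = 1 and coefficients are 1", {
  for (seed in 1:20) {
    inst <- rand_instance(seed, n_zones = 30, n_clinics = 8)
    inst$supply$capacity <- 1
    inst$supply$physicians <- 1L
    demand <- add_potential_users(inst$demand, identity_schedule())
    d0 <- runif(1, 500, 3000)
    suppressWarnings({
      fc <- fca(inst$supply, demand, d0 = d0, method = "conventional")
      fo <- fca(inst$supply, demand, d0 = d0, method = "optimized")
    })
    expect_identical(is.na(fc$scores$score), is.na(fo$scores$score))
    ok <- fc$scores$defined
    expect_true(all(abs(fc$scores$score[ok] - fo$scores$score[ok]) < 1e-12))
  }
})

test_that("accessibility is homogeneous in supply and inverse in demand", {
  inst <- rand_instance(99, n_zones = 25, n_clinics = 6)
  demand <- add_potential_users(inst$demand)
  base <- suppressWarnings(fca(inst$supply, demand, d0 = 2000, method = "optimized"))

  sup2 <- inst$supply; sup2$physicians <- sup2$physicians * 2L
  dbl <- suppressWarnings(fca(sup2, demand, d0 = 2000, method = "optimized"))
  ok <- base$scores$defined
  expect_equal(dbl$scores$score[ok], 2 * base$scores$score[ok])

  dem3 <- demand
  cols <- twostepfca:::.age_cols()
  dem3[cols] <- dem3[cols] * 3
  dem3 <- add_potential_users(dem3)
  tri <- suppressWarnings(fca(inst$supply, dem3, d0 = 2000, method = "optimized"))
  expect_equal(tri$scores$score[ok], base$scores$score[ok] / 3)
})

test_that("vectorized 2SFCA equals the literal double-loop implementation", {
  for (seed in 1:25) {
    set.seed(seed + 1000)
    nz <- sample(10:60, 1); nc <- sample(3:15, 1)
    inst <- rand_instance(seed, n_zones = nz, n_clinics = nc)
    demand <- add_potential_users(inst$demand)
    dm <- euclidean_distance_matrix(demand, inst$supply)
    d0 <- runif(1, 300, 4000)
    for (method in c("conventional", "optimized")) {
      sw <- if (method == "conventional") inst$supply$capacity else inst$supply$physicians
      dw <- if (method == "conventional") demand$pop_total else demand$users
      oracle <- fca_oracle(sw, dw, unclass(dm), d0)
      suppressWarnings({
        r <- step1_supply_ratios(inst$supply, demand, dm, d0, method)
        a <- step2_accessibility(r, demand, dm, d0)
      })
      expect_equal(r$ratio, oracle$R)
      expect_equal(a$score, oracle$A)
    }
  }
})

test_that("supply and demand totals balance when coverage is complete", {
  city <- generate_city(city_config(rows = 8, cols = 8, cell_size = 150,
                                    n_clinics = 6, clinic_clustering = 0.5,
                                    seed = 12))
  # clinics at zone centroids so no catchment is empty and no zone is out of range
  city$supply <- data.frame(id = paste0("c", 1:6),
                            x = city$demand$x[c(1, 10, 20, 30, 45, 60)],
                            y = city$demand$y[c(1, 10, 20, 30, 45, 60)],
                            capacity = c(1, 2, 1, 1, 3, 1),
                            physicians = c(4, 1, 7, 2, 5, 3))
  demand <- add_potential_users(city$demand)
  fc <- fca(city$supply, demand, d0 = 2000, method = "conventional")
  fo <- fca(city$supply, demand, d0 = 2000, method = "optimized")
  expect_equal(fc$n_defined, nrow(demand))
  expect_equal(sum(demand$pop_total * fc$scores$score) / 1000,
               sum(city$supply$capacity), tolerance = 1e-9)
  expect_equal(sum(demand$users * fo$scores$score) / 1000,
               sum(city$supply$physicians), tolerance = 1e-9)
})

test_that("score summaries cover defined scores only", {
  expect_equal(unname(summarize_scores(c(1, 1, 1))[c("Mean", "SD")]), c(1, 0))
  s <- summarize_scores(c(1, 2, NA))
  expect_equal(unname(s["N"]), 2)
  expect_equal(unname(s["Mean"]), 1.5)
  expect_error(summarize_scores(c(NA_real_, NA_real_)), "missing")

  set.seed(2)
  x <- rlnorm(100)
  s100 <- summarize_scores(x)
  xs <- sort(x)
  expect_equal(unname(s100["P50"]), (xs[50] + xs[51]) / 2)
  expect_equal(unname(s100["Min"]), xs[1])
  expect_equal(unname(s100["P25"]),
               unname(quantile(x, .25, type = 7)))
})

test_that("coverage grows with the threshold and the fca object is well-formed", {
  inst <- rand_instance(7, n_zones = 50, n_clinics = 5, side = 8000)
  demand <- add_potential_users(inst$demand)
  ns <- vapply(c(500, 1000, 2000, 3000), function(d0) {
    suppressWarnings(fca(inst$supply, demand, d0 = d0)$n_defined)
  }, numeric(1))
  expect_true(all(diff(ns) >= 0))

  fit <- suppressWarnings(fca(inst$supply, demand, d0 = 1500))
  expect_s3_class(fit, "fca")
  expect_named(coef(fit), demand$id)
  expect_output(print(fit), "conventional")
  expect_output(print(summary(fit)), "per 1,000")
  df <- as.data.frame(fit)
  expect_identical(nrow(df), nrow(demand))
})
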