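demand_from <- function(map) dplyr::select(class_areas(map), name, area_ha)

# a mosaic with a UB block and free agricultural space
block_map <- function(n = 30) {
  m <- matrix(1L, n, n)
  m[1:5, 1:5] <- 5L
  cat_grid(m)
}

test_that("neighbourhood cover fraction counts Moore neighbours", {
  # single UB cell in a sea of AG: its 8 neighbours see 1/8
  m <- matrix(1L, 5, 5); m[3, 3] <- 5L
  omega <- neighborhood_cover_fraction(cat_grid(m), 5L)
  expect_equal(omega$values[2, 2], 1 / 8)
  expect_equal(omega$values[3, 2], 1 / 8)
  expect_equal(omega$values[3, 3], 0)  # own cell not counted
  expect_equal(omega$values[1, 1], 0)
  # uniform map: every cell fully surrounded (borders use available neighbours)
  u <- neighborhood_cover_fraction(cat_grid(matrix(5L, 4, 4)), 5L)
  expect_true(all(u$values == 1))
  # weight scales the fraction
  w <- neighborhood_cover_fraction(cat_grid(m), 5L, weight = 0.5)
  expect_equal(w$values[2, 2], 0.5 / 8)
  expect_true(all(omega$values >= 0 & omega$values <= 1))
})

test_that("inertia adapts by the ratio of successive residuals", {
  expect_equal(adapt_inertia(1, -5, -5), 1)            # equal magnitudes
  expect_equal(adapt_inertia(1, -10, -5), 0.5)         # worsening deficit
  expect_equal(adapt_inertia(1, 10, 5), 2)             # worsening surplus
  expect_equal(adapt_inertia(2, -10, -5), 1)           # scales current value
  expect_equal(adapt_inertia(1, -3, -5), 1)            # improving: unchanged
  expect_equal(adapt_inertia(1, 5, -5), 1)             # sign change: unchanged
  expect_equal(adapt_inertia(1, 10, 0), 1)             # zero history guarded
  expect_equal(adapt_inertia(c(1, 1), c(-10, 10), c(-5, 5)), c(0.5, 2))
})

test_that("the spontaneous-seed branch has the stated conditional expectation", {
  # P = 1, Omega = 0, I = 1, mu_k = 0.9: every cell seeds, OP = r * 0.9,
  # E[OP] = 0.45 for r ~ U(0,1)
  n <- 200
  set.seed(99)
  op <- overall_probability(flat(1, n, n), flat(0, n, n),
                            inertia = 1, mu_k = 0.9, pos = 1)
  expect_equal(mean(op$values), 0.45, tolerance = 0.01)
  expect_true(all(op$values >= 0 & op$values <= 0.9))

  # organic-only limit: Omega > 0 everywhere means OP = P * Omega * I exactly
  set.seed(1)
  p <- cont_grid(matrix(runif(100), 10, 10))
  om <- cont_grid(matrix(runif(100, 0.1, 1), 10, 10))
  op2 <- overall_probability(p, om, inertia = 0.8, mu_k = 0.9, pos = 1)
  expect_equal(op2$values, p$values * om$values * 0.8)

  # PoS = 0: the seed branch is never taken
  set.seed(2)
  op3 <- overall_probability(p, flat(0, 10, 10), inertia = 1, mu_k = 0.9,
                             pos = 0)
  expect_true(all(op3$values == 0))
})

test_that("roulette frequencies match the weights within 3-sigma binomial", {
  n <- 1e5
  set.seed(123)
  w <- matrix(rep(c(0.2, 0.3, 0.5), each = n), n, 3)
  draws <- roulette_draw(w)
  for (j in 1:3) {
    p <- c(0.2, 0.3, 0.5)[j]
    expect_lt(abs(sum(draws == j) - n * p), 3 * sqrt(n * p * (1 - p)))
  }
  # zero rows yield NA
  expect_true(is.na(roulette_draw(matrix(0, 1, 3))))
})

test_that("simulation meets demand, conserves cells and is deterministic", {
  map <- block_map(30)
  # demand: +200 UB cells (0.09 ha each), taken from AG
  dem <- demand_from(map)
  dem$area_ha[dem$name == "UB"] <- dem$area_ha[dem$name == "UB"] + 200 * 0.09
  dem$area_ha[dem$name == "AG"] <- dem$area_ha[dem$name == "AG"] - 200 * 0.09
  surf <- list(UB = flat(0.8, 30, 30))
  cfg <- simulation_config(dem, pos = 0.05, step = 20, seed = 4)
  sim <- simulate_landuse(map, surf, cfg)
  expect_true(sim$converged)
  ub_cells <- class_areas(sim$map)$cells[5]
  expect_lt(abs(ub_cells - (25 + 200)), max(0.01 * 200, 10) + 1e-9)
  # conservation
  expect_equal(sum(!is.na(sim$map$values)), 900)
  expect_equal(sum(class_areas(sim$map)$cells), 900)
  # determinism
  sim2 <- simulate_landuse(map, surf, cfg)
  expect_identical(sim$map$values, sim2$map$values)
  # growth only where OP could be positive: everywhere here, but no class
  # other than UB/AG may change
  changed <- sim$map$values != map$values
  expect_true(all(map$values[changed] == 1L))
  expect_true(all(sim$map$values[changed] == 5L))
})

test_that("demand equal to current areas returns the map unchanged", {
  map <- block_map(20)
  cfg <- simulation_config(demand_from(map), seed = 1)
  sim <- simulate_landuse(map, list(UB = flat(0.9, 20, 20)), cfg)
  expect_identical(sim$map$values, map$values)
  expect_true(sim$converged)
  expect_equal(sim$iterations, 0)
})

test_that("the cost matrix is never violated", {
  map <- block_map(30)
  dem <- demand_from(map)
  dem$area_ha[dem$name == "UB"] <- dem$area_ha[dem$name == "UB"] + 150 * 0.09
  dem$area_ha[dem$name == "AG"] <- dem$area_ha[dem$name == "AG"] - 150 * 0.09
  tm <- matrix(1, 8, 8)
  tm[1, 5] <- 0  # forbid AG -> UB: demand cannot be met
  cfg <- simulation_config(dem, cost_matrix = tm, max_iterations = 15,
                           seed = 2)
  sim <- suppressWarnings(
    simulate_landuse(map, list(UB = flat(0.9, 30, 30)), cfg))
  # the only donors are AG cells, so nothing may change at all
  expect_identical(sim$map$values, map$values)
  expect_false(sim$converged)

  # permissive matrix: audit every committed transition against TM
  tm2 <- matrix(1, 8, 8); tm2[2, 5] <- 0
  cfg2 <- simulation_config(dem, cost_matrix = tm2, seed = 2, step = 20)
  sim2 <- simulate_landuse(map, list(UB = flat(0.9, 30, 30)), cfg2)
  from <- map$values[sim2$map$values != map$values]
  to <- sim2$map$values[sim2$map$values != map$values]
  expect_true(all(tm2[cbind(from, to)] == 1))
})

test_that("with PoS = 0 every new cell is 8-connected to an existing patch", {
  map <- block_map(40)
  dem <- demand_from(map)
  dem$area_ha[dem$name == "UB"] <- dem$area_ha[dem$name == "UB"] + 300 * 0.09
  dem$area_ha[dem$name == "AG"] <- dem$area_ha[dem$name == "AG"] - 300 * 0.09
  cfg <- simulation_config(dem, pos = 0, step = 20, seed = 8)
  sim <- simulate_landuse(map, list(UB = flat(0.9, 40, 40)), cfg)
  expect_true(sim$converged)
  # organic growth never creates a new patch
  expect_equal(count_patches(sim$map, 5L), count_patches(map, 5L))
})

test_that("patch count rises with PoS across seeded replicates", {
  pos_levels <- c(0, 0.01, 0.1, 0.5)
  n_rep <- 20
  map <- block_map(40)
  dem <- demand_from(map)
  dem$area_ha[dem$name == "UB"] <- dem$area_ha[dem$name == "UB"] + 250 * 0.09
  dem$area_ha[dem$name == "AG"] <- dem$area_ha[dem$name == "AG"] - 250 * 0.09
  surf <- list(UB = flat(0.7, 40, 40))
  mean_patches <- vapply(pos_levels, function(pos) {
    counts <- vapply(seq_len(n_rep), function(r) {
      cfg <- simulation_config(dem, pos = pos, step = 20, seed = 1000 + r,
                               max_iterations = 120)
      sim <- suppressWarnings(simulate_landuse(map, surf, cfg))
      count_patches(sim$map, 5L)
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  rho <- stats::cor(seq_along(pos_levels), mean_patches, method = "spearman")
  expect_gt(rho, 0)
  # and the PoS = 0 mean is the organic floor
  expect_true(all(mean_patches >= mean_patches[1]))
})

test_that("infeasible demand is rejected before iterating", {
  map <- block_map(10)
  dem <- demand_from(map)
  dem$area_ha[dem$name == "UB"] <- dem$area_ha[dem$name == "UB"] + 500
  expect_error(
    simulate_landuse(map, list(UB = flat(1, 10, 10)),
                     simulation_config(dem, seed = 1)),
    "infeasible"
  )
})
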