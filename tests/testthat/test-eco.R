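test_that("service formulas evaluate cellwise as stated", {
  f <- function(x) flat(x, 2, 2)
  # unit factors, flat terrain
  wr <- compute_service("WR", list(npp = f(1), fsic = f(1), fpre = f(1),
                                   fslo = f(0)))
  expect_equal(wr$values, matrix(1, 2, 2))
  # saturated slope kills water and soil conservation
  wr0 <- compute_service("WR", list(npp = f(1), fsic = f(0.7), fpre = f(0.9),
                                    fslo = f(1)))
  sp0 <- compute_service("Spro", list(npp = f(1), k = f(0.2), fslo = f(1)))
  expect_true(all(wr0$values == 0) && all(sp0$values == 0))
  # direct arithmetic
  wr2 <- compute_service("WR", list(npp = f(0.5), fsic = f(0.8),
                                    fpre = f(0.6), fslo = f(0.2)))
  expect_equal(wr2$values[1, 1], 0.5 * 0.8 * 0.6 * 0.8)
  # soil conservation decreases with erodibility
  sp_lo <- compute_service("Spro", list(npp = f(1), k = f(0.1), fslo = f(0)))
  sp_hi <- compute_service("Spro", list(npp = f(1), k = f(0.9), fslo = f(0)))
  expect_gt(sp_lo$values[1], sp_hi$values[1])
  # biodiversity formula
  sb <- compute_service("Sbio", list(npp = f(0.5), fpre = f(0.5),
                                     ftem = f(0.5), falt = f(0.5)))
  expect_equal(sb$values[1, 1], 0.5^3 * 0.5)
  # missing fields are named
  expect_error(compute_service("WR", list(npp = f(1))), "fsic")
  expect_error(compute_service("Spro", list(npp = f(1), fslo = f(0))), "'k'")
})

test_that("sensitivity formulas follow the stated forms", {
  f <- function(x) flat(x, 2, 2)
  ss1 <- compute_sensitivity("SS", list(r = f(1), ki = f(1), ls = f(1),
                                        c = f(1)))
  expect_equal(ss1$values, matrix(1, 2, 2))
  ss2 <- compute_sensitivity("SS", list(r = f(16), ki = f(1), ls = f(1),
                                        c = f(1)))
  expect_equal(ss2$values[1, 1], 2)  # fourth root of 16
  expect_error(compute_sensitivity("SS", list(r = f(-1), ki = f(1),
                                              ls = f(1), c = f(1))),
               "non-negative")
  sf <- compute_sensitivity("SF", list(tn = f(1), tp = f(1), tk = f(1),
                                       tom = f(1)))
  expect_equal(sf$values[1, 1], 0.15 + 0.3 + 0.4 + 0.15)
  sf2 <- compute_sensitivity("SF", list(tn = f(1), tp = f(0), tk = f(0),
                                        tom = f(0)))
  expect_equal(sf2$values[1, 1], 0.15)
})

test_that("MCR matches the closed form on a uniform corridor", {
  res <- flat(1, 1, 4, cell_size = 30)
  src <- matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4)
  mcr <- minimal_cumulative_resistance(res, src)
  expect_equal(as.vector(mcr$values), c(0, 30, 60, 90))
  # linear scaling in resistance
  mcr2 <- minimal_cumulative_resistance(
    cont_grid(matrix(2, 1, 4)), src)
  expect_equal(mcr2$values, 2 * mcr$values)
})

test_that("MCR equals exhaustive-path brute force on small random grids", {
  for (s in 1:3) {
    set.seed(s)
    res <- cont_grid(matrix(runif(25, 0.2, 3), 5, 5))
    src <- matrix(FALSE, 5, 5); src[sample(25, 2)] <- TRUE
    mcr <- minimal_cumulative_resistance(res, src)
    expect_equal(mcr$values, brute_mcr(res, src), tolerance = 1e-9)
  }
})

test_that("adding a source never increases any MCR value", {
  set.seed(7)
  res <- cont_grid(matrix(runif(36, 0.5, 2), 6, 6))
  s1 <- matrix(FALSE, 6, 6); s1[1, 1] <- TRUE
  s2 <- s1; s2[6, 6] <- TRUE
  m1 <- minimal_cumulative_resistance(res, s1)
  m2 <- minimal_cumulative_resistance(res, s2)
  expect_true(all(m2$values <= m1$values + 1e-12))
  expect_error(minimal_cumulative_resistance(res, matrix(FALSE, 6, 6)),
               "source")
})

test_that("natural breaks find the optimal partition", {
  # well-separated pairs: each pair its own class
  x <- c(1, 2, 10, 11, 20, 21, 30, 31, 40, 41)
  br <- jenks_breaks(x, 5)
  expect_equal(br, c(2, 11, 21, 31))
  # equals the brute-force optimum for random small inputs
  for (s in 1:10) {
    set.seed(s)
    n <- sample(8:20, 1)
    x <- round(runif(n, 0, 100), 1)
    k <- sample(2:4, 1)
    if (length(unique(x)) < k) next
    br <- jenks_breaks(x, k)
    bf <- brute_jenks(x, k)
    expect_equal(jenks_total_ssd(x, br), bf$ssd, tolerance = 1e-9)
  }
  expect_error(jenks_breaks(c(1, 1, 1, 2, 2), 5), "distinct")
})

test_that("grading preserves order and reports the break table", {
  set.seed(11)
  g <- cont_grid(matrix(runif(100), 10, 10))
  graded <- grade_natural_breaks(g, 5)
  expect_true(all(graded$values %in% 1:5))
  # higher value implies grade at least as high
  ord <- order(as.vector(g$values))
  expect_true(all(diff(as.vector(graded$values)[ord]) >= 0))
  tab <- attr(graded, "breaks")
  expect_equal(sum(tab$cells), 100)
  expect_true(all(diff(tab$break_high) > 0))
})

test_that("the indicator set produces six graded surfaces", {
  set.seed(5)
  f <- function() cont_grid(matrix(runif(400), 20, 20))
  src <- matrix(FALSE, 20, 20); src[10, 10] <- TRUE
  inputs <- list(npp = f(), fsic = f(), fpre = f(), fslo = f(), ftem = f(),
                 falt = f(), k = f(), r = f(), ki = f(), ls = f(), c = f(),
                 tn = f(), tp = f(), tk = f(), tom = f(),
                 resistance = cont_grid(matrix(runif(400, 0.5, 2), 20, 20)),
                 sources = src)
  ind <- indicator_set(inputs)
  expect_named(ind$surfaces, c("WR", "Spro", "Sbio", "SS", "RS", "SF"))
  for (s in ind$surfaces) expect_true(all(s$values >= 0, na.rm = TRUE))
  for (g in ind$grades) expect_true(all(g$values %in% 1:5))
  # riverside sensitivity peaks at the source
  expect_equal(ind$surfaces$RS$values[10, 10], 1)
})
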