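small_spec <- function(seed = 1, ...) {
  synthetic_spec(
    n_rows = 60, n_cols = 60, seed = seed,
    growth = tibble::tibble(class = c("UB", "IM"),
                            cells = c(150L, 100L),
                            organic_frac = c(0.7, 0.5),
                            seeds = c(4L, 5L)),
    ...
  )
}

test_that("region generation is deterministic and hits the class mixture", {
  spec <- synthetic_spec(n_rows = 200, n_cols = 200, seed = 33)
  r1 <- generate_region(spec)
  r2 <- generate_region(spec)
  expect_identical(r1$map$values, r2$map$values)
  expect_identical(r1$drivers$d_centre$values, r2$drivers$d_centre$values)
  expect_identical(r1$eco$npp$values, r2$eco$npp$values)
  # AG share within 2 percentage points of the spec at 200x200
  share <- mean(r1$map$values == 1L)
  expect_lt(abs(share - 0.35), 0.02)
  # all 8 classes present
  expect_setequal(unique(as.vector(r1$map$values)), 1:8)
})

test_that("the radial driver is the distance transform from the centre cell", {
  spec <- small_spec()
  reg <- generate_region(spec)
  m <- matrix(1L, 60, 60); m[30, 30] <- 5L
  d <- euclidean_distance(cat_grid(m), 5L)
  expect_equal(reg$drivers$d_centre$values, d$values)
})

test_that("eco fields are normalised and the resistance surface positive", {
  reg <- generate_region(small_spec(seed = 9))
  for (nm in c("npp", "fpre", "fslo", "tn")) {
    v <- reg$eco[[nm]]$values
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_true(all(reg$eco$resistance$values > 0))
  expect_identical(reg$eco$sources, reg$map$values == 4L)
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(proportions = c(AG = 0.5, WL = 0.4)), "sum to 1")
  expect_error(synthetic_spec(n_rows = 3, n_cols = 3), "more initial patches")
})

test_that("reference growth respects the organic/spontaneous recipe", {
  spec <- small_spec(seed = 21)
  reg <- generate_region(spec)
  ev <- evolve_reference_growth(reg$map, reg$drivers, spec)
  counts <- dplyr::count(ev$truth, class, mode)
  expect_equal(sum(counts$n[counts$class == "UB"]), 150)
  expect_equal(sum(counts$n[counts$class == "IM"]), 100)
  # organic split honoured
  expect_equal(counts$n[counts$class == "UB" & counts$mode == "organic"],
               round(150 * 0.7))
  # every truth cell did change to its class
  expect_true(all(ev$map$values[ev$truth$cell] ==
                    land_classes()$code[match(ev$truth$class,
                                              land_classes()$name)]))
  expect_true(all(reg$map$values[ev$truth$cell] !=
                    ev$map$values[ev$truth$cell]))
})

test_that("organic fraction 1 creates no detached patches", {
  spec <- synthetic_spec(
    n_rows = 60, n_cols = 60, seed = 5,
    growth = tibble::tibble(class = "UB", cells = 150L,
                            organic_frac = 1, seeds = 0L))
  reg <- generate_region(spec)
  ev <- evolve_reference_growth(reg$map, reg$drivers, spec)
  # organic growth may merge existing patches but never founds new ones
  expect_lte(count_patches(ev$map, 5L), count_patches(reg$map, 5L))
  # every new cell is reachable from a pre-existing patch within the final
  # UB mask: dilate the old patches inside the mask to a fixed point
  final_ub <- ev$map$values == 5L
  reach <- reg$map$values == 5L
  repeat {
    grown <- reach
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nr <- nrow(reach); nc <- ncol(reach)
      sh <- matrix(FALSE, nr, nc)
      rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
      rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
      sh[which(rok), which(cok)] <- reach[rs[rok], cs[cok]]
      grown <- grown | (sh & final_ub)
    }
    if (identical(grown, reach)) break
    reach <- grown
  }
  expect_true(all(reach[ev$truth$cell]))
  expect_true(all(ev$truth$mode == "organic"))
})

test_that("spontaneous seeds found the demanded number of detached patches", {
  spec <- synthetic_spec(
    n_rows = 80, n_cols = 80, seed = 13,
    growth = tibble::tibble(class = "IM", cells = 40L,
                            organic_frac = 0, seeds = 5L))
  reg <- generate_region(spec)
  ev <- evolve_reference_growth(reg$map, reg$drivers, spec)
  seeds <- dplyr::filter(ev$truth, mode == "spontaneous")
  # the 5 seed cells are detached from pre-existing IM and from each other
  first5 <- seeds$cell[1:5]
  pre <- reg$map$values
  for (s0 in first5) {
    r <- ((s0 - 1) %% 80) + 1; c0 <- ((s0 - 1) %/% 80) + 1
    nb <- expand.grid(r = pmax(1, r - 1):pmin(80, r + 1),
                      c = pmax(1, c0 - 1):pmin(80, c0 + 1))
    nb_idx <- (nb$c - 1) * 80 + nb$r
    nb_idx <- setdiff(nb_idx, s0)
    expect_false(any(pre[nb_idx] == 8L))
    expect_false(any(first5 %in% nb_idx))
  }
})

test_that("growth is placed preferentially at high driver scores", {
  spec <- small_spec(seed = 17)
  reg <- generate_region(spec)
  ev <- evolve_reference_growth(reg$map, reg$drivers, spec)
  # IM is driven by the west-east gradient: new IM cells sit further east
  # than the average convertible cell
  im_new <- dplyr::filter(ev$truth, class == "IM")
  conv <- which(matrix(reg$map$values %in% c(1L, 2L, 3L), 60, 60) &
                  ev$map$values != 8L)
  col_of <- function(i) ((i - 1) %/% 60) + 1
  expect_gt(mean(col_of(im_new$cell)), mean(col_of(conv)))
})

test_that("growth demanding more cells than convertible space errors", {
  spec <- synthetic_spec(
    n_rows = 20, n_cols = 20, seed = 2,
    proportions = c(AG = 0.05, WL = 0.05, GL = 0.05, WT = 0.05, UB = 0.4,
                    BC = 0.1, RS = 0.2, IM = 0.1),
    growth = tibble::tibble(class = "UB", cells = 300L, organic_frac = 0.5,
                            seeds = 2L))
  reg <- generate_region(spec)
  expect_error(evolve_reference_growth(reg$map, reg$drivers, spec),
               "insufficient convertible")
})
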