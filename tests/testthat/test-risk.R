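# 60x60 cells at 30 m = 1800 m x 1800 m -> 9 zones of 600 m
base_region <- function() {
  m <- matrix(1L, 60, 60)
  m[1:10, 1:10] <- 5L        # UB block in zone 1
  m[40:45, 40:45] <- 4L      # water
  cat_grid(m)
}

flat_grades <- function(value, nr = 60, nc = 60) {
  g <- categorical_grid(matrix(as.integer(value), nr, nc),
                        class_table = tibble::tibble(
                          code = 1:5,
                          name = c("extremely_low", "low", "medium", "high",
                                   "extremely_high")))
  g
}

test_that("the fishnet tiles the extent exactly", {
  fn <- build_fishnet(base_region(), 600)
  expect_equal(nrow(fn$zones), 9)
  expect_equal(sum(fn$zones$n_cells), 3600)
  expect_equal(sum(fn$zones$area_ha), 3600 * 0.09)
  expect_true(all(fn$zones$n_cells == 400))  # 20x20 cells nest exactly
  # clipped edge zones when the extent is not a multiple of the side
  fn2 <- build_fishnet(cat_grid(matrix(1L, 25, 25)), 600)
  expect_equal(sum(fn2$zones$n_cells), 625)
  expect_equal(max(fn2$zones$zrow), 2)
  expect_error(build_fishnet(base_region(), 10), "at least one raster cell")
})

test_that("stress occupancy separates core and buffer at the right levels", {
  map <- base_region()
  fn <- build_fishnet(map, 600)
  spec <- stress_spec()
  occ <- stress_occupancy(map, spec, fn)
  ub <- dplyr::filter(occ, class == "UB")
  # zone 1 is 25% UB core
  expect_equal(ub$core_ha[ub$zone == 1], 100 * 0.09)
  expect_equal(ub$level[1], 2)
  # no IM or RS anywhere
  expect_true(all(dplyr::filter(occ, class != "UB")[c("core_ha",
                                                      "buffer_ha")] == 0))
  # buffer ring: cells within 1 km of the UB block, outside it
  d <- euclidean_distance(map, 5L)
  ring_cells <- sum(d$values <= 1000 & map$values != 5L)
  expect_equal(sum(ub$buffer_ha), ring_cells * 0.09)
  # weighted occupancy: core at w, ring at w/2
  expect_equal(ub$weighted_ha,
               ub$core_ha * 2 + ub$buffer_ha * 2 * 0.5)
})

test_that("a single stress cell's buffer ring is a distance-transform disc", {
  m <- matrix(1L, 60, 60); m[30, 30] <- 8L  # one IM cell, buffer 1.5 km
  map <- cat_grid(m)
  fn <- build_fishnet(map, 600)
  occ <- dplyr::filter(stress_occupancy(map, stress_spec(), fn),
                       class == "IM")
  d <- euclidean_distance(map, 8L)
  expect_equal(sum(occ$core_ha), 0.09)
  expect_equal(sum(occ$buffer_ha), (sum(d$values <= 1500) - 1) * 0.09)
  expect_equal(sum(occ$weighted_ha),
               0.09 * 3 + (sum(d$values <= 1500) - 1) * 0.09 * 1.5)
})

test_that("the risk index follows its bilinear algebra", {
  map <- base_region()
  fn <- build_fishnet(map, 600)
  occ <- stress_occupancy(map, stress_spec(), fn)
  means1 <- zone_indicator_means(
    purrr::map(setNames(nm = c("WR", "Spro", "Sbio", "SS", "RS", "SF")),
               function(nm) flat_grades(5)),
    fn, converted = matrix(FALSE, 60, 60), exposed = matrix(FALSE, 60, 60))
  eri <- ecological_risk_index(occ, means1, fn$zones)
  # hand value: zone 1 grade means all 1 (grade 5/5), equal weights -> bracket = 1;
  # stress term = (core 100 cells * 2 + ring cells * 1) * 0.09 / 36 ha
  ub <- dplyr::filter(occ, class == "UB", zone == 1)
  expect_equal(eri$eri[eri$zone == 1],
               (ub$core_ha * 2 + ub$buffer_ha * 1) / 36)
  # zones without stress have ERI 0
  far <- dplyr::filter(occ, zone == 9)
  if (all(far$weighted_ha == 0)) expect_equal(eri$eri[eri$zone == 9], 0)
  # doubling the indicator means doubles the ERI
  means_half <- means1
  means_half[-1] <- means1[-1] / 2
  eri_half <- ecological_risk_index(occ, means_half, fn$zones)
  expect_equal(eri$eri, 2 * eri_half$eri)
  # weight validation
  expect_error(ecological_risk_index(occ, means1, fn$zones,
                                     weights = rep(0.5, 6)), "sum to 1")
})

test_that("converting a buffer cell to core strictly increases zone ERI", {
  m <- matrix(1L, 60, 60); m[30, 30] <- 8L
  map1 <- cat_grid(m)
  m2 <- m; m2[30, 31] <- 8L  # a ring cell becomes core
  map2 <- cat_grid(m2)
  fn <- build_fishnet(map1, 600)
  grades <- purrr::map(setNames(nm = c("WR", "Spro", "Sbio", "SS", "RS", "SF")),
                       function(nm) flat_grades(3))
  no_mask <- matrix(FALSE, 60, 60)
  means <- zone_indicator_means(grades, fn, no_mask, no_mask)
  z <- 5  # centre zone
  e1 <- ecological_risk_index(
    stress_occupancy(map1, stress_spec(), fn), means, fn$zones)
  e2 <- ecological_risk_index(
    stress_occupancy(map2, stress_spec(), fn), means, fn$zones)
  expect_gt(e2$eri[e2$zone == z], e1$eri[e1$zone == z])
})

test_that("risk levels classify by natural breaks and conserve area", {
  set.seed(42)
  map <- base_region()
  fn <- build_fishnet(map, 600)
  # synthetic bimodal ERI across 9 zones
  eri <- tibble::tibble(
    zone = fn$zones$zone, area_ha = fn$zones$area_ha,
    stress_term = NA_real_, indicator_term = NA_real_,
    eri = c(0.1, 0.12, 0.11, 0.5, 0.52, 0.9, 0.95, 0.05, 0.3))
  cls <- classify_risk_levels(eri, fn)
  expect_equal(sum(cls$areas$area_ha), sum(fn$zones$area_ha))
  expect_true(all(cls$zones$level %in% 1:5))
  # boundaries match the brute-force Jenks optimum
  bf <- brute_jenks(eri$eri, 5)
  expect_equal(jenks_total_ssd(eri$eri, jenks_breaks(eri$eri, 5)), bf$ssd,
               tolerance = 1e-12)
  # degenerate distribution errors
  eri_flat <- dplyr::mutate(eri, eri = 1)
  expect_error(classify_risk_levels(eri_flat, fn), "distinct")
})

test_that("the end-to-end risk assessment runs and exposes tidy views", {
  base <- base_region()
  scen <- base
  scen$values[11:14, 1:10] <- 5L   # UB grows south
  scen$values[50:55, 50:55] <- 8L  # new IM patch
  set.seed(1)
  grades <- purrr::map(setNames(nm = c("WR", "Spro", "Sbio", "SS", "RS", "SF")),
                       function(nm) {
                         grade_natural_breaks(
                           cont_grid(matrix(runif(3600), 60, 60)), 5)
                       })
  ra <- risk_assessment(base, scen, grades)
  expect_s3_class(tidy(ra), "tbl_df")
  expect_equal(nrow(tidy(ra)), 9)
  expect_true(all(glance(ra)[-1] >= 0))
  # stressed zones carry positive risk, and ERI = 0 only without stress
  stressed <- dplyr::summarise(
    dplyr::group_by(ra$occupancy, zone),
    w = sum(weighted_ha))
  joined <- dplyr::left_join(tidy(ra), stressed, by = "zone")
  expect_true(all((joined$eri > 0) == (joined$w > 0)))
})
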