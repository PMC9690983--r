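# Fishnet zoning, buffered stress occupancy and the zonal ecological risk
# index with five-level classification.

#' Stress specification for construction-land risk sources
#'
#' Relative stress levels, buffer distances and the buffer attenuation for the
#' three construction classes. Defaults: industrial/mining land level 3 with a
#' 1.5 km buffer, urban built-up level 2 with a 1 km buffer, rural settlements
#' level 1 with a 2 km buffer; the stress level inside a buffer ring is halved.
#'
#' @param levels Named positive numeric vector of stress levels.
#' @param buffer_m Named non-negative buffer distances (metres), same names.
#' @param attenuation Multiplier on the stress level inside the buffer ring
#'   (default 0.5).
#' @return A `stress_spec` object.
#' @export
stress_spec <- function(levels = c(IM = 3, UB = 2, RS = 1),
                        buffer_m = c(IM = 1500, UB = 1000, RS = 2000),
                        attenuation = 0.5) {
  stopifnot(!is.null(names(levels)), !is.null(names(buffer_m)))
  if (any(levels <= 0)) stop("stress levels must be positive", call. = FALSE)
  if (any(buffer_m < 0)) stop("buffer distances must be >= 0", call. = FALSE)
  if (attenuation < 0 || attenuation > 1) {
    stop("attenuation must lie in [0, 1]", call. = FALSE)
  }
  buffer_m <- buffer_m[names(levels)]
  if (anyNA(buffer_m)) stop("levels and buffer_m need matching names", call. = FALSE)
  structure(list(levels = levels, buffer_m = buffer_m,
                 attenuation = attenuation),
            class = "stress_spec")
}

#' Tile a grid's extent into square risk zones (a fishnet)
#'
#' @param grid A `land_grid` giving the extent.
#' @param cell_side Zone side length in metres (default 600); must be at least
#'   one raster cell.
#' @return A `fishnet` object: `$zones` tibble (`zone`, `zrow`, `zcol`,
#'   `n_cells`, `area_ha`, centre `x`/`y`) and `$zone_index`, an integer
#'   matrix aligned with the grid assigning each cell to its zone. Edge zones
#'   are clipped to the extent, so zone areas sum exactly to the grid area.
#' @export
build_fishnet <- function(grid, cell_side = 600) {
  if (cell_side < grid$cell_size) {
    stop("zone side must be at least one raster cell", call. = FALSE)
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  zr <- floor((seq_len(nr) - 0.5) * grid$cell_size / cell_side) + 1L
  zc <- floor((seq_len(nc) - 0.5) * grid$cell_size / cell_side) + 1L
  nzc <- max(zc)
  zone_index <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) zone_index[i, ] <- (zr[i] - 1L) * nzc + zc
  zones <- tibble::as_tibble(as.data.frame(table(zone = as.vector(zone_index))))
  zones$zone <- as.integer(as.character(zones$zone))
  names(zones)[2] <- "n_cells"
  zones$zrow <- (zones$zone - 1L) %/% nzc + 1L
  zones$zcol <- (zones$zone - 1L) %% nzc + 1L
  zones$area_ha <- zones$n_cells * cell_area_ha(grid)
  zones$x <- grid$origin[1] + (zones$zcol - 0.5) * cell_side
  zones$y <- grid$origin[2] - (zones$zrow - 0.5) * cell_side
  structure(
    list(zones = zones[, c("zone", "zrow", "zcol", "n_cells", "area_ha",
                           "x", "y")],
         zone_index = zone_index, cell_side = cell_side,
         n_zone_rows = max(zr), n_zone_cols = nzc,
         geometry = list(cell_size = grid$cell_size, origin = grid$origin)),
    class = "fishnet"
  )
}

#' @export
print.fishnet <- function(x, ...) {
  cat(sprintf("<fishnet> %d zones (%d x %d), %g m side\n",
              nrow(x$zones), x$n_zone_rows, x$n_zone_cols, x$cell_side))
  invisible(x)
}

zone_sum <- function(fishnet, values) {
  out <- rep(0, nrow(fishnet$zones))
  s <- tapply(values, as.vector(fishnet$zone_index), sum, na.rm = TRUE)
  out[match(as.integer(names(s)), fishnet$zones$zone)] <- s
  out
}

#' Per-zone stress occupancy with buffered attenuation
#'
#' For each stress class: core cells are the cells carrying the class; the
#' buffer ring is every other non-nodata cell within the class's buffer
#' distance of a core cell. Core area counts at the full stress level, ring
#' area at the attenuated level.
#'
#' @param map A `categorical_grid` (the scenario land-use map).
#' @param spec A [stress_spec()].
#' @param fishnet A [build_fishnet()] result aligned with `map`.
#' @return Tibble with `zone`, `class`, `core_ha`, `buffer_ha`, `level` and
#'   `weighted_ha` (`core_ha * level + buffer_ha * level * attenuation`).
#' @export
stress_occupancy <- function(map, spec, fishnet) {
  stopifnot(inherits(spec, "stress_spec"), inherits(fishnet, "fishnet"))
  ct <- map$class_table
  ca <- cell_area_ha(map)
  purrr::map_dfr(names(spec$levels), function(cls) {
    code <- ct$code[ct$name == cls]
    core <- !is.na(map$values) & map$values == code
    if (any(core)) {
      dist <- euclidean_distance(map, code)
      ring <- !core & !is.na(map$values) & dist$values <= spec$buffer_m[[cls]]
    } else {
      ring <- core  # all FALSE
    }
    tibble::tibble(
      zone = fishnet$zones$zone,
      class = cls,
      core_ha = zone_sum(fishnet, as.numeric(core)) * ca,
      buffer_ha = zone_sum(fishnet, as.numeric(ring)) * ca,
      level = spec$levels[[cls]]
    ) |>
      dplyr::mutate(weighted_ha = .data$core_ha * .data$level +
                      .data$buffer_ha * .data$level * spec$attenuation)
  })
}

#' Per-zone mean indicator grades over exposed cells
#'
#' Averages each graded indicator (grade rescaled to \[0, 1\] as grade /
#' n_grades) over the zone's exposed cells: cells converted to a construction
#' class between the base and scenario maps where any exist, falling back to
#' buffer-exposed cells, then to all zone cells. The result feeds the
#' bracketed indicator term of the risk index.
#'
#' @param grades Named list of graded `categorical_grid`s (from
#'   [grade_natural_breaks()]), e.g. `WR`, `Spro`, `Sbio`, `SS`, `RS`, `SF`.
#' @param fishnet A [build_fishnet()] result.
#' @param converted Logical matrix marking cells converted to construction
#'   land (may be all `FALSE`).
#' @param exposed Logical matrix marking buffer-exposed cells (fallback mask).
#' @param n_grades Number of grade levels (default 5).
#' @return Tibble with `zone` and one mean column per indicator.
#' @export
zone_indicator_means <- function(grades, fishnet, converted, exposed,
                                 n_grades = 5) {
  zones <- fishnet$zones$zone
  n_conv <- zone_sum(fishnet, as.numeric(converted))
  n_exp <- zone_sum(fishnet, as.numeric(exposed))
  n_all <- fishnet$zones$n_cells
  means <- purrr::map(grades, function(g) {
    v <- as.vector(g$values) / n_grades
    v[is.na(v)] <- 0
    s_conv <- zone_sum(fishnet, v * as.vector(converted))
    s_exp <- zone_sum(fishnet, v * as.vector(exposed))
    s_all <- zone_sum(fishnet, v)
    dplyr::case_when(
      n_conv > 0 ~ s_conv / n_conv,
      n_exp > 0 ~ s_exp / n_exp,
      TRUE ~ s_all / n_all
    )
  })
  dplyr::bind_cols(tibble::tibble(zone = zones), tibble::as_tibble(means))
}

#' Zonal ecological risk index
#'
#' `ERI = sum_i((A_ri / A_r) * w_i) * sum_j(weight_j * mean_j)`: the stress
#' occupancy term (area fraction of each stress factor times its level, buffer
#' rings at the attenuated level) multiplied by the weighted mean of the six
#' indicator values in the zone. Zero stress occupancy gives ERI 0; the index
#' is bilinear in occupancy and indicator means.
#'
#' @param occupancy Output of [stress_occupancy()].
#' @param indicator_means Output of [zone_indicator_means()] (columns beyond
#'   `zone` are the indicators).
#' @param zones The `$zones` tibble of the [build_fishnet()] result.
#' @param weights Indicator weights, one per indicator column, summing to 1;
#'   default equal.
#' @return Tibble with `zone`, `area_ha`, `stress_term`, `indicator_term`,
#'   `eri`.
#' @export
ecological_risk_index <- function(occupancy, indicator_means, zones,
                                  weights = NULL) {
  ind_cols <- setdiff(names(indicator_means), "zone")
  if (is.null(weights)) weights <- rep(1 / length(ind_cols), length(ind_cols))
  if (length(weights) != length(ind_cols)) {
    stop("need one weight per indicator column", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("indicator weights must sum to 1", call. = FALSE)
  }
  stress <- occupancy |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(weighted_ha = sum(.data$weighted_ha), .groups = "drop")
  ind_term <- as.matrix(indicator_means[, ind_cols, drop = FALSE]) %*% weights
  zones |>
    dplyr::select("zone", "area_ha") |>
    dplyr::left_join(stress, by = "zone") |>
    dplyr::left_join(
      tibble::tibble(zone = indicator_means$zone,
                     indicator_term = as.vector(ind_term)),
      by = "zone"
    ) |>
    dplyr::mutate(
      weighted_ha = dplyr::coalesce(.data$weighted_ha, 0),
      stress_term = .data$weighted_ha / .data$area_ha,
      eri = .data$stress_term * .data$indicator_term
    ) |>
    dplyr::select("zone", "area_ha", "stress_term", "indicator_term", "eri")
}

#' Classify zone risk values into five levels by natural breaks
#'
#' @param eri Tibble from [ecological_risk_index()].
#' @param fishnet The matching [build_fishnet()] result.
#' @param n_levels Number of levels (default 5: low, medium-low, medium,
#'   medium-high, high).
#' @return List with `zones` (the input plus `level` and `level_name`),
#'   `areas` (per-level area and percentage table) and `map` (a
#'   `categorical_grid` of levels at zone resolution, one cell per zone).
#'   Degenerate ERI distributions (fewer distinct values than levels) raise an
#'   error.
#' @export
classify_risk_levels <- function(eri, fishnet, n_levels = 5) {
  level_names <- c("low", "medium_low", "medium", "medium_high",
                   "high")[seq_len(n_levels)]
  breaks <- jenks_breaks(eri$eri, n_levels)
  level <- findInterval(eri$eri, breaks, left.open = TRUE) + 1L
  zones <- dplyr::mutate(eri, level = level,
                         level_name = level_names[level])
  areas <- zones |>
    dplyr::group_by(.data$level, .data$level_name) |>
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop") |>
    tidyr::complete(level = seq_len(n_levels),
                    fill = list(area_ha = 0)) |>
    dplyr::mutate(level_name = level_names[.data$level],
                  pct = 100 * .data$area_ha / sum(.data$area_ha))
  m <- matrix(NA_integer_, fishnet$n_zone_rows, fishnet$n_zone_cols)
  idx <- cbind(fishnet$zones$zrow[match(zones$zone, fishnet$zones$zone)],
               fishnet$zones$zcol[match(zones$zone, fishnet$zones$zone)])
  m[idx] <- zones$level
  map <- categorical_grid(
    m, cell_size = fishnet$cell_side,
    origin = fishnet$geometry$origin,
    class_table = tibble::tibble(code = seq_len(n_levels), name = level_names)
  )
  list(zones = zones, areas = areas, map = map)
}

#' End-to-end ecological risk assessment of a scenario map
#'
#' Combines fishnet zoning, buffered stress occupancy of the construction
#' classes, per-zone indicator means over the cells converted to construction
#' land, the ecological risk index and its five-level classification.
#'
#' @param base_map,scenario_map Aligned `categorical_grid`s (e.g. the current
#'   map and a simulated future map).
#' @param grades Named list of graded indicator `categorical_grid`s.
#' @param spec A [stress_spec()].
#' @param cell_side Zone side in metres (default 600).
#' @param weights Indicator weights (default equal).
#' @return A `risk_assessment` object: `$zones`, `$areas`, `$map` (as in
#'   [classify_risk_levels()]) plus `$occupancy` and `$eri`.
#' @export
risk_assessment <- function(base_map, scenario_map, grades, spec = stress_spec(),
                            cell_side = 600, weights = NULL) {
  check_aligned(base_map, scenario_map)
  fn <- build_fishnet(base_map, cell_side)
  occ <- stress_occupancy(scenario_map, spec, fn)
  ct <- scenario_map$class_table
  stress_codes <- ct$code[match(names(spec$levels), ct$name)]
  converted <- !is.na(base_map$values) & !is.na(scenario_map$values) &
    scenario_map$values %in% stress_codes &
    base_map$values != scenario_map$values
  exposed <- matrix(FALSE, nrow(base_map$values), ncol(base_map$values))
  for (cls in names(spec$levels)) {
    code <- ct$code[ct$name == cls]
    if (!any(scenario_map$values == code, na.rm = TRUE)) next
    dist <- euclidean_distance(scenario_map, code)
    exposed <- exposed | (!is.na(scenario_map$values) &
                            dist$values <= spec$buffer_m[[cls]])
  }
  means <- zone_indicator_means(grades, fn, converted, exposed)
  eri <- ecological_risk_index(occ, means, fn$zones, weights)
  cls <- classify_risk_levels(eri, fn)
  structure(c(cls, list(occupancy = occ, eri = eri, fishnet = fn)),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment>\n")
  print(x$areas)
  invisible(x)
}

#' @rdname risk_assessment
#' @param x A `risk_assessment`.
#' @param ... Unused.
#' @return `tidy()`: the per-zone tibble with ERI and level.
#' @export
tidy.risk_assessment <- function(x, ...) x$zones

#' @rdname risk_assessment
#' @return `glance()`: one-row tibble with zone count and per-level area
#'   percentages.
#' @export
glance.risk_assessment <- function(x, ...) {
  pct <- stats::setNames(x$areas$pct, paste0("pct_", x$areas$level_name))
  dplyr::bind_cols(tibble::tibble(n_zones = nrow(x$zones)),
                   tibble::as_tibble_row(pct))
}
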