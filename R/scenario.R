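# Scenario probability surfaces: industry-priority and urban-transformation
# multipliers applied on top of the calibrated development probabilities.

clip01 <- function(g) {
  continuous_grid(pmin(pmax(g$values, 0), 1),
                  cell_size = g$cell_size, origin = g$origin)
}

#' Turn a distance surface into a proximity score
#'
#' Rescales a distance surface to `1 - D / max(D)` so that "near" scores high;
#' the standard transform for letting distance-to-feature drivers enter a
#' priority formula that rewards proximity.
#'
#' @param distance A `continuous_grid` of distances.
#' @return A `continuous_grid` in \[0, 1\].
#' @export
proximity_surface <- function(distance) normalize_minmax(distance, invert = TRUE)

#' Cover fraction of a class within a circular window
#'
#' Per cell, the fraction of cells within `radius_m` (Euclidean, centre to
#' centre) that carry any of `codes` — the aggregation term for industrial
#' land. Window cells beyond the grid edge are excluded from the denominator.
#'
#' @param map A `categorical_grid`.
#' @param codes Integer class codes to aggregate.
#' @param radius_m Window radius in metres (default 1000).
#' @return A `continuous_grid` in \[0, 1\].
#' @export
cover_fraction_surface <- function(map, codes, radius_m = 1000) {
  r_cells <- radius_m / map$cell_size
  half <- floor(r_cells)
  sz <- 2L * half + 1L
  off <- seq(-half, half)
  K <- outer(off, off, function(i, j) as.numeric(i^2 + j^2 <= r_cells^2))
  bin <- matrix(as.numeric(!is.na(map$values) & map$values %in% codes),
                nrow(map$values), ncol(map$values))
  valid <- matrix(as.numeric(!is.na(map$values)),
                  nrow(map$values), ncol(map$values))
  num <- as.matrix(EBImage::filter2(bin, K / sum(K), boundary = 0))
  den <- as.matrix(EBImage::filter2(valid, K / sum(K), boundary = 0))
  frac <- ifelse(den > 0, num / den, 0)
  clip01(continuous_grid(frac, cell_size = map$cell_size, origin = map$origin))
}

#' Slope-based terrain constraint
#'
#' Rescales slope (degrees) to a \[0, 1\] constraint: 0 on flat terrain,
#' saturating at 1 for slopes at or above `cap_deg`.
#'
#' @param slope A `continuous_grid` of slopes in degrees.
#' @param cap_deg Slope at which the constraint saturates (default 25).
#' @return A `continuous_grid` in \[0, 1\].
#' @export
slope_constraint <- function(slope, cap_deg = 25) {
  clip01(continuous_grid(slope$values / cap_deg,
                         cell_size = slope$cell_size, origin = slope$origin))
}

#' Industry-priority scenario probability surface
#'
#' Cellwise evaluation of
#' `Pip = (theta1*Dt + theta2*Dc + theta3*Ai) * (1 - Env) * (theta4*(1-Zi) +
#' theta5*Zi)`: a weighted blend of traffic proximity, urban-centre proximity
#' and industrial aggregation, annihilated on steep terrain and modulated by
#' the planning mask.
#'
#' @param traffic,centre Proximity surfaces in \[0, 1\] (see
#'   [proximity_surface()]).
#' @param aggregation Industrial cover-fraction surface in \[0, 1\] (see
#'   [cover_fraction_surface()]).
#' @param env Terrain constraint in \[0, 1\] (see [slope_constraint()]).
#' @param planned Binary planning mask (1 = inside the industrial plan).
#' @param theta Length-3 weights on traffic/centre/aggregation, summing to 1.
#' @param policy Length-2 weights on (unplanned, planned) areas, summing to 1;
#'   `policy[2] > policy[1]` expresses planning enforcement.
#' @return A `continuous_grid` in \[0, 1\].
#' @export
industry_priority_surface <- function(traffic, centre, aggregation, env,
                                      planned,
                                      theta = c(0.4, 0.3, 0.3),
                                      policy = c(0.3, 0.7)) {
  if (abs(sum(theta) - 1) > 1e-9 || length(theta) != 3) {
    stop("theta (traffic, centre, aggregation) must be 3 weights summing to 1",
         call. = FALSE)
  }
  if (abs(sum(policy) - 1) > 1e-9 || length(policy) != 2) {
    stop("policy (unplanned, planned) must be 2 weights summing to 1",
         call. = FALSE)
  }
  for (g in list(centre, aggregation, env, planned)) check_aligned(traffic, g)
  zi <- planned$values
  pip <- (theta[1] * traffic$values + theta[2] * centre$values +
            theta[3] * aggregation$values) *
    (1 - env$values) *
    (policy[1] * (1 - zi) + policy[2] * zi)
  clip01(continuous_grid(pip, cell_size = traffic$cell_size,
                         origin = traffic$origin))
}

#' Urban-transformation scenario probability surface
#'
#' Cellwise evaluation of `Put = sum_j(upsilon_j * R_j) * El^sigma`: a weighted
#' blend of socio-economic attractiveness factors damped by the land-resource
#' endowment raised to the constraint exponent `sigma` (`sigma = 0` switches
#' the endowment term off).
#'
#' @param factors Named list of socio-economic factor surfaces `R_j` in
#'   \[0, 1\] (income, public budget, education/medical resources, employment
#'   potential, housing prices, ...).
#' @param weights Numeric weights `upsilon_j`, one per factor, summing to 1;
#'   default uniform.
#' @param endowment Land-resource endowment surface `El` in \[0, 1\].
#' @param sigma Constraint exponent in \[0, 1\] (default 0.5).
#' @return A `continuous_grid` in \[0, 1\].
#' @export
urban_transformation_surface <- function(factors, weights = NULL, endowment,
                                         sigma = 0.5) {
  stopifnot(is.list(factors), length(factors) >= 1)
  if (is.null(weights)) weights <- rep(1 / length(factors), length(factors))
  if (length(weights) != length(factors)) {
    stop("need one weight per factor surface", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("factor weights must sum to 1", call. = FALSE)
  }
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]", call. = FALSE)
  ref <- factors[[1]]
  for (g in factors) check_aligned(ref, g)
  check_aligned(ref, endowment)
  blend <- Reduce(`+`, purrr::map2(factors, weights, ~ .x$values * .y))
  put <- blend * endowment$values^sigma
  clip01(continuous_grid(put, cell_size = ref$cell_size, origin = ref$origin))
}

#' Apply a scenario multiplier to a calibrated development probability
#'
#' Cellwise product of the calibrated surface and the scenario surface; the
#' result never exceeds either input, so a scenario can only redistribute or
#' suppress development potential, not invent it.
#'
#' @param p_calibrated,p_scenario Aligned probability surfaces in \[0, 1\].
#' @return A `continuous_grid` in \[0, 1\].
#' @export
apply_scenario <- function(p_calibrated, p_scenario) {
  check_aligned(p_calibrated, p_scenario)
  clip01(continuous_grid(p_calibrated$values * p_scenario$values,
                         cell_size = p_calibrated$cell_size,
                         origin = p_calibrated$origin))
}
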