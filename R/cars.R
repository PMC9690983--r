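# Cellular-automaton allocation with multi-type random patch seeds: organic
# (neighbourhood-driven) and spontaneous (detached-seed) growth compete under
# adaptive inertia and a decreasing acceptance threshold until class areas
# meet demand.

#' Simulation configuration for the patch-seeding cellular automaton
#'
#' @param demand Tibble with `name`, `area_ha`: target class areas. Their sum
#'   must equal the map's non-nodata area (cell rounding is repaired on the
#'   largest class; a discrepancy beyond 0.5% is an error at simulation time).
#' @param pos Percent-of-seeds in \[0, 1\]: per iteration, a cell may found a
#'   new detached patch only if a seeded uniform draw falls below `pos`.
#'   `pos = 0` disables spontaneous growth entirely.
#' @param delta Attenuation factor of the decreasing threshold, in (0, 1)
#'   (default 0.1): the acceptance threshold is `delta^l * r`.
#' @param mu_k Per-class new-patch expansion coefficient in \[0, 1\] (default
#'   0.9); scalar or named vector by class name.
#' @param step Demand-approach step length (cells): the decay counter `l`
#'   increments whenever an iteration reduces the summed absolute residuals by
#'   less than `step`.
#' @param neighborhood_weights Per-class multiplier on the Moore-neighbourhood
#'   cover fraction; scalar or named vector (default 1 for every class).
#' @param cost_matrix M x M 0/1 matrix of permitted transitions (rows = from,
#'   columns = to, class-name dimnames); the diagonal must be 1. Default: all
#'   transitions permitted.
#' @param max_iterations Iteration cap (default 200).
#' @param seed Integer RNG seed for the whole simulation.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(demand, pos = 0.01, delta = 0.1, mu_k = 0.9,
                              step = 50, neighborhood_weights = 1,
                              cost_matrix = NULL, max_iterations = 200,
                              seed = 1) {
  stopifnot(is.data.frame(demand), all(c("name", "area_ha") %in% names(demand)))
  if (pos < 0 || pos > 1) stop("pos must lie in [0, 1]", call. = FALSE)
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)", call. = FALSE)
  if (any(mu_k < 0 | mu_k > 1)) stop("mu_k must lie in [0, 1]", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  classes <- demand$name
  if (!is.null(cost_matrix)) {
    cost_matrix <- as.matrix(cost_matrix)
    stopifnot(identical(dim(cost_matrix), c(length(classes), length(classes))))
    if (any(!cost_matrix %in% c(0, 1))) {
      stop("cost_matrix entries must be 0 or 1", call. = FALSE)
    }
    if (any(diag(cost_matrix) != 1)) {
      stop("cost_matrix diagonal must be 1", call. = FALSE)
    }
  } else {
    cost_matrix <- matrix(1, length(classes), length(classes))
  }
  dimnames(cost_matrix) <- list(classes, classes)
  expand_by_class <- function(x, default) {
    out <- stats::setNames(rep(default, length(classes)), classes)
    if (length(x) == 1 && is.null(names(x))) out[] <- x
    else out[names(x)] <- x
    out
  }
  structure(
    list(demand = tibble::as_tibble(demand), pos = pos, delta = delta,
         mu_k = expand_by_class(mu_k, 0.9),
         step = step,
         neighborhood_weights = expand_by_class(neighborhood_weights, 1),
         cost_matrix = cost_matrix, max_iterations = max_iterations,
         seed = seed),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> PoS %g, delta %g, step %g, %d classes, seed %d\n",
    x$pos, x$delta, x$step, nrow(x$demand), x$seed))
  invisible(x)
}

shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[which(rok), which(cok)] <- m[rs[rok], cs[cok]]
  out
}

moore_offsets <- expand.grid(dr = -1:1, dc = -1:1)
moore_offsets <- moore_offsets[!(moore_offsets$dr == 0 & moore_offsets$dc == 0), ]

#' Moore-neighbourhood cover fraction of a class
#'
#' Per cell, the fraction of its available 3 x 3 Moore neighbours (8 in the
#' interior, fewer on the border) carrying class `k`, multiplied by the
#' class's neighbourhood weight. This is the organic-growth term of the
#' overall probability: it is zero exactly where class `k` has no adjacent
#' presence.
#'
#' @param map A `categorical_grid`.
#' @param k Class code.
#' @param weight Neighbourhood weight multiplier (default 1).
#' @return A `continuous_grid`; values in \[0, weight\].
#' @export
neighborhood_cover_fraction <- function(map, k, weight = 1) {
  isk <- matrix(as.numeric(!is.na(map$values) & map$values == k),
                nrow(map$values), ncol(map$values))
  avail <- matrix(1, nrow(map$values), ncol(map$values))
  cnt <- 0; tot <- 0
  for (i in seq_len(nrow(moore_offsets))) {
    cnt <- cnt + shift_matrix(isk, moore_offsets$dr[i], moore_offsets$dc[i])
    tot <- tot + shift_matrix(avail, moore_offsets$dr[i], moore_offsets$dc[i])
  }
  continuous_grid(weight * cnt / tot, cell_size = map$cell_size,
                  origin = map$origin)
}

#' Adapt the per-class inertia coefficient from the residual history
#'
#' The inertia `I_k` feeds back demand into the competition. With residuals
#' `G = developed - demand` at the two previous iterations: unchanged if
#' `|G1| <= |G2|`; scaled by `G2/G1` if `G1 < G2 < 0`; scaled by `G1/G2` if
#' `G1 > G2 > 0`. Sign changes and zero residuals leave it unchanged.
#'
#' @param inertia Numeric vector of current coefficients.
#' @param g1 Residuals at iteration t-1.
#' @param g2 Residuals at iteration t-2.
#' @return Updated inertia vector.
#' @export
adapt_inertia <- function(inertia, g1, g2) {
  stopifnot(length(inertia) == length(g1), length(g1) == length(g2))
  out <- inertia
  case2 <- g1 < g2 & g2 < 0
  case3 <- g1 > g2 & g2 > 0
  keep <- abs(g1) <= abs(g2)
  out[!keep & case2] <- inertia[!keep & case2] * (g2[!keep & case2] / g1[!keep & case2])
  out[!keep & case3] <- inertia[!keep & case3] * (g1[!keep & case3] / g2[!keep & case3])
  out
}

#' Overall development probability coupling organic and spontaneous growth
#'
#' Where the neighbourhood term is zero, a cell may still develop as a new
#' detached seed: if a fresh uniform draw `r` falls below the development
#' probability and the cell passes the percent-of-seeds gate, the overall
#' probability is `P * (r * mu_k) * I`; everywhere else it is the organic form
#' `P * Omega * I`. Draws come from the current RNG state, so the caller
#' controls reproducibility by seeding.
#'
#' @param p_dev Development-probability surface (`continuous_grid` in
#'   \[0, 1\]).
#' @param omega Weighted neighbourhood cover-fraction surface (see
#'   [neighborhood_cover_fraction()]).
#' @param inertia Scalar inertia coefficient `I_k`.
#' @param mu_k New-patch expansion coefficient in \[0, 1\].
#' @param pos Percent-of-seeds gate in \[0, 1\].
#' @return A `continuous_grid` of overall probabilities.
#' @export
overall_probability <- function(p_dev, omega, inertia = 1, mu_k = 0.9,
                                pos = 1) {
  check_aligned(p_dev, omega)
  n <- length(p_dev$values)
  p <- p_dev$values
  r <- matrix(stats::runif(n), nrow(p), ncol(p))
  gate <- matrix(stats::runif(n), nrow(p), ncol(p)) < pos
  seeded <- omega$values == 0 & r < p & gate
  op <- p * omega$values * inertia
  op[seeded] <- (p * (r * mu_k) * inertia)[seeded]
  continuous_grid(op, cell_size = p_dev$cell_size, origin = p_dev$origin)
}

#' Roulette-wheel candidate selection
#'
#' Draws, for each row of a non-negative weight matrix, one column index with
#' probability proportional to the row's weights. Rows summing to zero return
#' `NA`. Uses the current RNG state (one uniform draw per row).
#'
#' @param weights Numeric matrix, rows = cells, columns = candidate classes.
#' @return Integer vector of column indices, one per row.
#' @export
roulette_draw <- function(weights) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("roulette weights must be non-negative", call. = FALSE)
  rs <- rowSums(weights)
  cum <- weights %*% upper.tri(diag(ncol(weights)), diag = TRUE)
  u <- stats::runif(nrow(weights)) * rs
  out <- rowSums(cum < u) + 1L
  out[rs == 0] <- NA_integer_
  out
}

# Truncated normal on (0, 2), mean 1, sd 1 (vectorised rejection).
rtruncnorm02 <- function(n) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), 1, 1)
    ok <- draw > 0 & draw < 2
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

new_ca_state <- function(map, config) {
  ct <- map$class_table
  classes <- config$demand$name
  stopifnot(identical(classes, ct$name))
  total_cells <- sum(!is.na(map$values))
  dem_cells <- config$demand$area_ha / cell_area_ha(map)
  dem_int <- round(dem_cells)
  drift <- total_cells - sum(dem_int)
  if (abs(drift) > max(1, 0.005 * total_cells)) {
    stop(sprintf(
      "infeasible demand: targets cover %d cells but the map has %d",
      sum(dem_int), total_cells), call. = FALSE)
  }
  dem_int[which.max(dem_int)] <- dem_int[which.max(dem_int)] + drift
  counts <- class_areas(map)$cells
  change <- dem_int - counts
  list(
    classes = classes,
    codes = ct$code,
    demand_cells = dem_int,
    tol_cells = pmax(ceiling(0.01 * abs(change)), 10),
    inertia = rep(1, length(classes)),
    g1 = counts - dem_int,   # residual at t-1
    g2 = counts - dem_int,   # residual at t-2
    l = 0L,
    iteration = 0L
  )
}

#' One allocation iteration of the cellular automaton
#'
#' Every convertible cell roulette-draws a candidate class with probability
#' proportional to the per-class overall probabilities, then the change is
#' committed iff the candidate's development probability exceeds the
#' decreasing threshold `tau = delta^l * r` (`r` truncated-normal, mean 1, on
#' (0, 2)), the cost matrix permits the transition, the candidate class still
#' needs cells, and the donor class can shed them. Cells are visited in a
#' random permutation; classes whose demand is met are frozen.
#'
#' @param map Current `categorical_grid`.
#' @param op_surfaces Named list (by class name) of overall-probability
#'   surfaces for this iteration.
#' @param dev_surfaces Named list of development-probability surfaces (the
#'   threshold test uses these, not the overall probabilities).
#' @param config A [simulation_config()].
#' @param state Internal CA state (from `new_ca_state()` or a previous call).
#' @return List with the updated `map` and `state`.
#' @export
allocate <- function(map, op_surfaces, dev_surfaces, config, state) {
  classes <- state$classes
  M <- length(classes)
  vals <- map$values
  n <- length(vals)
  counts <- class_areas(map)$cells
  g_before <- counts - state$demand_cells

  opm <- matrix(0, n, M)
  for (j in seq_len(M)) {
    s <- op_surfaces[[classes[j]]]
    if (!is.null(s)) opm[, j] <- pmax(as.vector(s$values), 0)
  }
  # freeze classes with no remaining need
  need <- state$demand_cells - counts
  opm[, need <= 0] <- 0

  cur_idx <- match(as.vector(vals), state$codes)
  convertible <- !is.na(cur_idx)
  rs <- rowSums(opm)
  eligible <- which(convertible & rs > 0)
  if (length(eligible)) {
    cand <- roulette_draw(opm[eligible, , drop = FALSE])
    tau <- config$delta^state$l * rtruncnorm02(length(eligible))
    pdev <- vapply(seq_along(eligible), function(i) {
      s <- dev_surfaces[[classes[cand[i]]]]
      if (is.null(s)) 0 else s$values[eligible[i]]
    }, numeric(1))
    cur <- cur_idx[eligible]
    tm_ok <- config$cost_matrix[cbind(cur, cand)] == 1
    accepted <- which(!is.na(pdev) & pdev > tau & tm_ok & cand != cur)
    if (length(accepted)) {
      ord <- accepted[order(stats::runif(length(accepted)))]
      for (i in ord) {
        from <- cur[i]; to <- cand[i]
        if (counts[to] >= state$demand_cells[to]) next
        if (counts[from] <= state$demand_cells[from]) next
        vals[eligible[i]] <- state$codes[to]
        counts[to] <- counts[to] + 1L
        counts[from] <- counts[from] - 1L
      }
    }
  }
  g_after <- counts - state$demand_cells
  progress <- sum(abs(g_before)) - sum(abs(g_after))
  if (progress < config$step) state$l <- state$l + 1L
  state$inertia <- adapt_inertia(state$inertia, g_after, state$g1)
  state$g2 <- state$g1
  state$g1 <- g_after
  state$iteration <- state$iteration + 1L
  map$values <- vals
  list(map = map, state = state)
}

#' Simulate land-use change until class areas meet demand
#'
#' Iterates [allocate()] — recomputing neighbourhood terms and overall
#' probabilities from the start-of-iteration map (synchronous neighbourhoods)
#' — until every class's residual is within tolerance (1% of the demanded
#' change or 10 cells, whichever is larger) or `max_iterations` is reached,
#' in which case the best map so far is returned with a warning and
#' `converged = FALSE`.
#'
#' @param map_t0 Starting `categorical_grid`.
#' @param dev_prob A `development_probability` object, or a named list of
#'   probability surfaces keyed by class name (classes without a surface can
#'   only shed cells).
#' @param config A [simulation_config()].
#' @return A `luc_simulation` object: `$map` (final grid), `$residuals`
#'   (tibble: iteration, class, residual_cells), `$converged`, `$iterations`,
#'   `$config`.
#' @export
simulate_landuse <- function(map_t0, dev_prob, config) {
  stopifnot(inherits(config, "simulation_config"))
  surfaces <- if (inherits(dev_prob, "development_probability")) {
    dev_prob$surfaces
  } else {
    dev_prob
  }
  state <- new_ca_state(map_t0, config)
  map <- map_t0
  log <- list()
  converged <- FALSE
  with_seed(config$seed, {
    for (it in seq_len(config$max_iterations)) {
      counts <- class_areas(map)$cells
      g <- counts - state$demand_cells
      log[[it]] <- tibble::tibble(iteration = it - 1L, class = state$classes,
                                  residual_cells = g)
      if (all(abs(g) <= state$tol_cells)) {
        converged <- TRUE
        break
      }
      ops <- stats::setNames(vector("list", length(state$classes)),
                             state$classes)
      for (j in seq_along(state$classes)) {
        nm <- state$classes[j]
        if (is.null(surfaces[[nm]])) next
        omega <- neighborhood_cover_fraction(
          map, state$codes[j], config$neighborhood_weights[[nm]])
        ops[[nm]] <- overall_probability(
          surfaces[[nm]], omega, inertia = state$inertia[j],
          mu_k = config$mu_k[[nm]], pos = config$pos)
      }
      res <- allocate(map, ops, surfaces, config, state)
      map <- res$map
      state <- res$state
    }
  })
  if (!converged) {
    warning("demand not met within max_iterations; returning best map",
            call. = FALSE)
  }
  structure(
    list(map = map, residuals = purrr::list_rbind(log), converged = converged,
         iterations = state$iteration, config = config,
         demand_cells = stats::setNames(state$demand_cells, state$classes)),
    class = "luc_simulation"
  )
}

#' @export
print.luc_simulation <- function(x, ...) {
  cat(sprintf("<luc_simulation> %d iterations, %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Summarise a simulation run
#'
#' @param x A `luc_simulation`.
#' @param ... Unused.
#' @return One-row tibble: `iterations`, `converged`, `max_abs_residual_cells`,
#'   `total_cells`.
#' @export
glance.luc_simulation <- function(x, ...) {
  last <- dplyr::filter(x$residuals, .data$iteration == max(.data$iteration))
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    max_abs_residual_cells = max(abs(last$residual_cells)),
    total_cells = sum(!is.na(x$map$values))
  )
}

#' Per-class residual trace of a simulation
#'
#' @param x A `luc_simulation`.
#' @param ... Unused.
#' @return The residual log tibble (`iteration`, `class`, `residual_cells`).
#' @export
tidy.luc_simulation <- function(x, ...) x$residuals
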