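# Ecosystem-service and ecological-sensitivity indicators, least-cost
# minimal-cumulative-resistance surfaces and natural-breaks grading.

get_field <- function(inputs, name, op) {
  g <- inputs[[name]]
  if (is.null(g)) {
    stop(sprintf("%s requires input field '%s'", op, name), call. = FALSE)
  }
  g
}

#' Ecosystem-service indicator surfaces
#'
#' Cellwise evaluation of the net-primary-productivity based service formulas
#' on normalised \[0, 1\] factor surfaces:
#' * `WR` (water conservation): `NPP * Fsic * Fpre * (1 - Fslo)`;
#' * `Spro` (soil conservation): `NPP * (1 - k) * (1 - Fslo)`, where `k` is
#'   soil erodibility — protection decreases as erodibility rises;
#' * `Sbio` (biodiversity maintenance): `NPP * Fpre * Ftem * (1 - Falt)`.
#'
#' @param kind One of `"WR"`, `"Spro"`, `"Sbio"`.
#' @param inputs Named list of aligned `continuous_grid`s. Field names used:
#'   `npp`, `fsic` (soil seepage), `fpre` (precipitation), `fslo` (slope),
#'   `ftem` (temperature), `falt` (altitude), `k` (soil erodibility), all
#'   normalised to \[0, 1\] by the caller (see [normalize_minmax()]).
#' @return A non-negative `continuous_grid`.
#' @export
compute_service <- function(kind = c("WR", "Spro", "Sbio"), inputs) {
  kind <- match.arg(kind)
  npp <- get_field(inputs, "npp", kind)
  vals <- switch(kind,
    WR = {
      fsic <- get_field(inputs, "fsic", kind)
      fpre <- get_field(inputs, "fpre", kind)
      fslo <- get_field(inputs, "fslo", kind)
      npp$values * fsic$values * fpre$values * (1 - fslo$values)
    },
    Spro = {
      k <- get_field(inputs, "k", kind)
      fslo <- get_field(inputs, "fslo", kind)
      npp$values * (1 - k$values) * (1 - fslo$values)
    },
    Sbio = {
      fpre <- get_field(inputs, "fpre", kind)
      ftem <- get_field(inputs, "ftem", kind)
      falt <- get_field(inputs, "falt", kind)
      npp$values * fpre$values * ftem$values * (1 - falt$values)
    }
  )
  continuous_grid(vals, cell_size = npp$cell_size, origin = npp$origin)
}

#' Ecological-sensitivity indicator surfaces
#'
#' * `SS` (soil-erosion sensitivity): the geometric mean
#'   `(R * K * LS * C)^(1/4)` of rainfall erosivity, soil erodibility,
#'   slope-length/steepness and vegetation cover; all four factors must be
#'   non-negative.
#' * `SF` (soil fertility): the weighted sum
#'   `0.15 TN + 0.3 TP + 0.4 TK + 0.15 TOM` of the normalised soil
#'   nitrogen/phosphorus/potassium/organic-matter surfaces.
#'
#' @param kind One of `"SS"`, `"SF"`.
#' @param inputs Named list of aligned `continuous_grid`s. Field names used:
#'   `r` (rainfall erosivity), `ki` (soil erodibility), `ls`
#'   (slope-length/steepness), `c` (vegetation cover), `tn`, `tp`, `tk`,
#'   `tom`.
#' @return A non-negative `continuous_grid`.
#' @export
compute_sensitivity <- function(kind = c("SS", "SF"), inputs) {
  kind <- match.arg(kind)
  if (kind == "SS") {
    r <- get_field(inputs, "r", kind)
    ki <- get_field(inputs, "ki", kind)
    ls <- get_field(inputs, "ls", kind)
    cc <- get_field(inputs, "c", kind)
    prod <- r$values * ki$values * ls$values * cc$values
    if (any(prod < 0, na.rm = TRUE)) {
      stop("SS factors must be non-negative (fourth root of the product)",
           call. = FALSE)
    }
    continuous_grid(prod^(1 / 4), cell_size = r$cell_size, origin = r$origin)
  } else {
    tn <- get_field(inputs, "tn", kind)
    tp <- get_field(inputs, "tp", kind)
    tk <- get_field(inputs, "tk", kind)
    tom <- get_field(inputs, "tom", kind)
    continuous_grid(
      0.15 * tn$values + 0.3 * tp$values + 0.4 * tk$values + 0.15 * tom$values,
      cell_size = tn$cell_size, origin = tn$origin
    )
  }
}

#' Minimal cumulative resistance from source cells
#'
#' Least-cost surface over the 8-connected grid: each step from cell a to cell
#' b costs the step length (cell size, times sqrt(2) diagonally) multiplied by
#' the mean resistance of the two cells; a cell's MCR is the minimum total
#' cost over paths from any source. Sources get 0, cells unreachable from
#' every source get `Inf`. Computed with Dijkstra's algorithm via a zero-cost
#' virtual super-source.
#'
#' @param resistance A `continuous_grid` of positive resistance values (`NA` =
#'   impassable/nodata).
#' @param sources Logical matrix the shape of the grid, or integer vector of
#'   linear cell indices, marking source cells.
#' @return A `continuous_grid` of MCR values (metres x resistance units).
#' @export
minimal_cumulative_resistance <- function(resistance, sources) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  if (is.matrix(sources)) sources <- which(sources)
  sources <- sources[!is.na(v[sources])]
  if (length(sources) == 0) stop("no source cells", call. = FALSE)
  if (any(v <= 0, na.rm = TRUE)) {
    stop("resistance must be positive on traversable cells", call. = FALSE)
  }
  passable <- which(!is.na(v))
  id <- matrix(NA_integer_, nr, nc)
  id[passable] <- seq_along(passable)

  edges <- list(); weights <- list(); e <- 0
  for (i in seq_len(nrow(moore_offsets))) {
    dr <- moore_offsets$dr[i]; dc <- moore_offsets$dc[i]
    if (dr < 0 || (dr == 0 && dc < 0)) next  # each undirected pair once
    rows <- seq_len(nr - abs(dr)); cols <- seq_len(nc - abs(dc))
    a <- id[rows + max(0, -dr), cols + max(0, -dc), drop = FALSE]
    b <- id[rows + max(0, dr), cols + max(0, dc), drop = FALSE]
    ra <- v[rows + max(0, -dr), cols + max(0, -dc), drop = FALSE]
    rb <- v[rows + max(0, dr), cols + max(0, dc), drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    step <- resistance$cell_size * if (dr != 0 && dc != 0) sqrt(2) else 1
    e <- e + 1
    edges[[e]] <- rbind(a[ok], b[ok])
    weights[[e]] <- step * (ra[ok] + rb[ok]) / 2
  }
  n_v <- length(passable)
  super <- n_v + 1L
  src_ids <- id[sources]
  edge_vec <- c(unlist(edges), rbind(rep(super, length(src_ids)), src_ids))
  w <- c(unlist(weights), rep(0, length(src_ids)))
  g <- igraph::make_graph(edges = edge_vec, n = super, directed = FALSE)
  d <- igraph::distances(g, v = super, weights = w, algorithm = "dijkstra")
  out <- matrix(NA_real_, nr, nc)
  out[passable] <- as.vector(d)[seq_len(n_v)]
  continuous_grid(ifelse(is.infinite(out), Inf, out),
                  cell_size = resistance$cell_size, origin = resistance$origin)
}

#' Jenks (Fisher) natural-breaks classification
#'
#' `jenks_breaks()` finds the partition of the values into `n_classes`
#' contiguous classes minimising the total within-class sum of squared
#' deviations, by dynamic programming over the sorted unique values (exact
#' Fisher optimality). `grade_natural_breaks()` applies it to a surface and
#' returns the 1-based grade per cell (1 = lowest values).
#'
#' @param x Numeric vector (finite values; `NA` ignored).
#' @param n_classes Number of classes (default 5).
#' @return `jenks_breaks()`: numeric vector of `n_classes - 1` interior break
#'   values (upper bound of each class but the last). `grade_natural_breaks()`:
#'   a `categorical_grid` of grades 1..`n_classes` with the break table in
#'   `attr(, "breaks")`.
#' @export
jenks_breaks <- function(x, n_classes = 5) {
  x <- x[is.finite(x)]
  ux <- sort(unique(x))
  n <- length(ux)
  if (n < n_classes) {
    stop("need at least ", n_classes, " distinct finite values", call. = FALSE)
  }
  wt <- as.numeric(table(factor(x, levels = ux)))
  cw <- cumsum(wt)
  cwx <- cumsum(wt * ux)
  cwx2 <- cumsum(wt * ux^2)
  # ssd of the value range (i..j], 1-based inclusive
  ssd <- function(i, j) {
    w <- cw[j] - if (i > 1) cw[i - 1] else 0
    s <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    s2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    s2 - s^2 / w
  }
  # dp[k, j]: min total ssd splitting first j uniques into k classes
  dp <- matrix(Inf, n_classes, n)
  back <- matrix(0L, n_classes, n)
  for (j in seq_len(n)) dp[1, j] <- ssd(1, j)
  for (k in 2:n_classes) {
    for (j in k:n) {
      best <- Inf; arg <- 0L
      for (m in (k - 1):(j - 1)) {
        val <- dp[k - 1, m] + ssd(m + 1, j)
        if (val < best) { best <- val; arg <- m }
      }
      dp[k, j] <- best
      back[k, j] <- arg
    }
  }
  cuts <- integer(n_classes - 1)
  j <- n
  for (k in n_classes:2) {
    cuts[k - 1] <- back[k, j]
    j <- back[k, j]
  }
  ux[cuts]
}

#' @rdname jenks_breaks
#' @param surface A `continuous_grid`.
#' @export
grade_natural_breaks <- function(surface, n_classes = 5) {
  v <- surface$values
  breaks <- jenks_breaks(as.vector(v), n_classes)
  grades <- matrix(NA_integer_, nrow(v), ncol(v))
  fin <- is.finite(v)
  grades[fin] <- findInterval(v[fin], breaks, left.open = TRUE) + 1L
  grade_table <- tibble::tibble(
    grade = seq_len(n_classes),
    break_low = c(min(v[fin]), breaks),
    break_high = c(breaks, max(v[fin])),
    cells = tabulate(grades[fin], nbins = n_classes)
  )
  out <- categorical_grid(
    grades, cell_size = surface$cell_size, origin = surface$origin,
    class_table = tibble::tibble(
      code = seq_len(n_classes),
      name = c("extremely_low", "low", "medium", "high",
               "extremely_high")[seq_len(n_classes)]
    )
  )
  attr(out, "breaks") <- grade_table
  out
}

#' Compute and grade the full indicator set
#'
#' Convenience wrapper producing the six indicator surfaces (three services,
#' soil-erosion sensitivity, riverside sensitivity as MCR from water cells,
#' soil fertility) and their five-level natural-breaks grades.
#'
#' @param inputs Named list of `continuous_grid`s (see [compute_service()] and
#'   [compute_sensitivity()]), plus `resistance` (landscape resistance) and
#'   `sources` (logical matrix or cell indices of river/water cells) for the
#'   riverside-sensitivity MCR.
#' @param n_classes Grades per indicator (default 5).
#' @return A named list with `surfaces` (list of six `continuous_grid`s: `WR`,
#'   `Spro`, `Sbio`, `SS`, `RS`, `SF`) and `grades` (matching
#'   `categorical_grid`s). Riverside sensitivity is inverted MCR (near rivers
#'   = sensitive), min-max normalised.
#' @export
indicator_set <- function(inputs, n_classes = 5) {
  mcr <- minimal_cumulative_resistance(
    get_field(inputs, "resistance", "RS"),
    get_field(inputs, "sources", "RS")
  )
  finite_mcr <- mcr$values
  finite_mcr[is.infinite(finite_mcr)] <- max(finite_mcr[is.finite(finite_mcr)])
  rs <- normalize_minmax(
    continuous_grid(finite_mcr, cell_size = mcr$cell_size, origin = mcr$origin),
    invert = TRUE
  )
  surfaces <- list(
    WR = compute_service("WR", inputs),
    Spro = compute_service("Spro", inputs),
    Sbio = compute_service("Sbio", inputs),
    SS = compute_sensitivity("SS", inputs),
    RS = rs,
    SF = compute_sensitivity("SF", inputs)
  )
  list(surfaces = surfaces,
       grades = purrr::map(surfaces, grade_natural_breaks, n_classes = n_classes))
}
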