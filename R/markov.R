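#' Construct a land-use transition probability matrix
#'
#' @param P M x M numeric matrix; `P[i, j]` is the probability that class i
#'   converts to class j over the calibration interval. Rows must sum to 1
#'   within `tol`. Published matrices rounded to a few decimals can be loaded
#'   with a looser `tol` and are used as printed, without renormalisation.
#' @param classes Character vector of class names (row/column order).
#' @param interval_years Length of the calibration step in years.
#' @param tol Row-sum tolerance.
#' @return A `transition_matrix` object.
#' @export
transition_matrix <- function(P, classes = land_classes()$name,
                              interval_years = NA_real_, tol = 1e-9) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P), nrow(P) == length(classes))
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    stop(sprintf("rows must sum to 1 within %g (max deviation %.3g)",
                 tol, max(abs(rs - 1))), call. = FALSE)
  }
  dimnames(P) <- list(classes, classes)
  structure(list(P = P, classes = classes, interval_years = interval_years),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes%s\n", length(x$classes),
              if (is.na(x$interval_years)) ""
              else sprintf(", %g-year interval", x$interval_years)))
  print(round(x$P, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transition matrix into long format
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `probability`.
#' @export
tidy.transition_matrix <- function(x, ...) {
  tibble::tibble(
    from = rep(x$classes, times = length(x$classes)),
    to = rep(x$classes, each = length(x$classes)),
    probability = as.vector(x$P)
  )
}

#' Estimate the transition matrix from two land-use maps
#'
#' Row-normalises the cross-tabulation of the calibration start and end maps:
#' a one-step matrix over the full interval, not an annualised chain. A class
#' absent from the start map gets an identity row (it cannot be observed to
#' change) with a warning.
#'
#' @param map_t0,map_t1 Aligned `categorical_grid`s sharing a class table.
#' @param interval_years Optional interval length recorded on the result.
#' @return A `transition_matrix`.
#' @export
estimate_transition_matrix <- function(map_t0, map_t1, interval_years = NA_real_) {
  xt <- cross_tabulate(map_t0, map_t1)
  m <- attr(xt, "matrix")
  rs <- rowSums(m)
  P <- m
  if (any(rs == 0)) {
    warning("classes absent from the start map get identity rows: ",
            paste(rownames(m)[rs == 0], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(m))) {
    P[i, ] <- if (rs[i] > 0) m[i, ] / rs[i] else as.numeric(seq_len(ncol(m)) == i)
  }
  transition_matrix(P, classes = rownames(m), interval_years = interval_years)
}

#' Project land demand one Markov step ahead
#'
#' Right-multiplies the class-area row vector by the transition matrix
#' (`demand_t1 = demand_t0 %*% P`). With a row-stochastic matrix the total
#' area is conserved.
#'
#' @param demand_t0 Tibble with columns `name` and `area_ha` (class order must
#'   match `P`), or a named numeric vector of areas.
#' @param P A `transition_matrix`.
#' @return Tibble with `name` and `area_ha` of the projected demand.
#' @export
project_demand <- function(demand_t0, P) {
  stopifnot(inherits(P, "transition_matrix"))
  if (is.data.frame(demand_t0)) {
    if (!all(c("name", "area_ha") %in% names(demand_t0))) {
      stop("demand needs columns `name` and `area_ha`", call. = FALSE)
    }
    v <- demand_t0$area_ha
    names(v) <- demand_t0$name
  } else {
    v <- demand_t0
  }
  if (length(v) != length(P$classes)) {
    stop("demand vector length does not match the matrix classes", call. = FALSE)
  }
  if (!is.null(names(v)) && !identical(names(v), P$classes)) {
    stop("demand class order does not match the matrix classes", call. = FALSE)
  }
  if (any(v < 0)) stop("demand areas must be non-negative", call. = FALSE)
  out <- as.vector(v %*% P$P)
  tibble::tibble(name = P$classes, area_ha = out)
}

#' Revise a transition matrix toward a planning target
#'
#' Scales the target built-up column j of every non-j row by `mu_j` (the ratio
#' of the planned to the Markov-predicted new area) and rebalances the other
#' entries of each row i by `mu_i = (1 - mu_j * P[i, j]) / (sum(P[i, ]) -
#' P[i, j])` so each row still sums to its original total. The target class's
#' own row — the renewal of built-up land — is left unmodified.
#'
#' @param P A `transition_matrix`.
#' @param target_class Name of the built-up class being planned ("UB", "RS" or
#'   "IM").
#' @param mu_j Positive correction ratio; `mu_j = 1` returns `P` unchanged.
#' @return A revised `transition_matrix` (row sums preserved to 1e-9 of the
#'   originals).
#' @export
revise_transition_probability <- function(P, target_class, mu_j) {
  stopifnot(inherits(P, "transition_matrix"))
  if (!is.numeric(mu_j) || length(mu_j) != 1 || mu_j <= 0) {
    stop("mu_j must be a single positive number", call. = FALSE)
  }
  j <- match(target_class, P$classes)
  if (is.na(j)) stop("unknown target class: ", target_class, call. = FALSE)
  M <- P$P
  out <- M
  for (i in seq_len(nrow(M))) {
    if (i == j) next
    pij <- M[i, j]
    if (mu_j * pij >= 1) {
      stop(sprintf(
        "infeasible revision: mu_j * P[%s, %s] = %.4f >= 1",
        P$classes[i], target_class, mu_j * pij), call. = FALSE)
    }
    row_sum <- sum(M[i, ])
    mu_i <- (row_sum - mu_j * pij) / (row_sum - pij)
    out[i, ] <- M[i, ] * mu_i
    out[i, j] <- mu_j * pij
  }
  transition_matrix(out, classes = P$classes,
                    interval_years = P$interval_years, tol = 1e-3)
}

#' Scale one class's projected demand for a planning scenario
#'
#' Planning scenarios are commonly stated as "x% above the baseline demand"
#' for one construction class. This multiplies the target class's area by
#' `factor`, leaving the others untouched (the spatial allocator resolves the
#' competition; total-area bookkeeping is done at allocation time).
#'
#' @param demand Tibble with `name`, `area_ha`.
#' @param target_class Class name to scale.
#' @param factor Multiplier (1.2 = a 20% increase).
#' @return Tibble with the scaled `area_ha`.
#' @export
scale_demand <- function(demand, target_class, factor) {
  stopifnot(is.data.frame(demand), factor > 0)
  if (!target_class %in% demand$name) {
    stop("unknown target class: ", target_class, call. = FALSE)
  }
  dplyr::mutate(demand, area_ha = ifelse(.data$name == target_class,
                                         .data$area_ha * factor,
                                         .data$area_ha))
}

# ---- serialisation ----------------------------------------------------------

#' Read / write a transition matrix as CSV
#'
#' The CSV has a `from` column of class names and one column per destination
#' class, matching the bundled calibration fixtures.
#'
#' @param path CSV path.
#' @param interval_years Interval recorded on the result.
#' @param tol Row-sum tolerance (published matrices need ~1e-3).
#' @return `read_transition_matrix()`: a `transition_matrix`;
#'   `write_transition_matrix()`: `path` invisibly.
#' @export
read_transition_matrix <- function(path, interval_years = NA_real_, tol = 1e-3) {
  df <- utils::read.csv(path, check.names = FALSE)
  classes <- df[[1]]
  P <- as.matrix(df[, -1, drop = FALSE])
  stopifnot(identical(classes, colnames(P)))
  transition_matrix(P, classes = classes, interval_years = interval_years,
                    tol = tol)
}

#' @rdname read_transition_matrix
#' @param x A `transition_matrix`.
#' @export
write_transition_matrix <- function(x, path) {
  df <- data.frame(from = x$classes, x$P, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- bundled Quanzhou calibration fixtures ----------------------------------

#' Published Quanzhou 2005-2018 calibration matrices and 2031 demands
#'
#' The package bundles the published 13-year transition probability matrices
#' (business-as-usual calibration plus the industry-priority and
#' urban-transformation revisions) and the published land demand table (2018
#' areas and the 2031 demands per scenario) for the Quanzhou case study, as
#' plain-CSV fixtures. They drive the demand-projection examples and the
#' reproducibility checks.
#'
#' @param scenario One of `"bau"`, `"ip"`, `"ut"`.
#' @return `quanzhou_transition_matrix()`: a `transition_matrix` (as printed,
#'   4-decimal entries); `quanzhou_demand()`: a tibble with columns `name`,
#'   `y2018`, `bau_2031`, `ip_2031`, `ut_2031` (hectares).
#' @export
quanzhou_transition_matrix <- function(scenario = c("bau", "ip", "ut")) {
  scenario <- match.arg(scenario)
  path <- system.file("extdata", paste0("quanzhou_", scenario, "_matrix.csv"),
                      package = "sprawlrisk", mustWork = TRUE)
  read_transition_matrix(path, interval_years = 13, tol = 1e-3)
}

#' @rdname quanzhou_transition_matrix
#' @export
quanzhou_demand <- function() {
  path <- system.file("extdata", "quanzhou_demand.csv",
                      package = "sprawlrisk", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}
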