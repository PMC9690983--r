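# Agreement metrics between simulated and observed maps.

#' Confusion counts between observed and simulated maps
#'
#' @param observed,simulated Aligned `categorical_grid`s.
#' @return Tibble with `observed`, `simulated` (class names) and `cells`.
#' @export
confusion_counts <- function(observed, simulated) {
  check_aligned(observed, simulated)
  ct <- observed$class_table
  ok <- !is.na(observed$values) & !is.na(simulated$values)
  if (!any(ok)) stop("no overlapping non-nodata cells", call. = FALSE)
  counts <- table(
    observed = factor(observed$values[ok], levels = ct$code, labels = ct$name),
    simulated = factor(simulated$values[ok], levels = ct$code, labels = ct$name)
  )
  out <- tibble::as_tibble(as.data.frame(counts, responseName = "cells"))
  out$observed <- as.character(out$observed)
  out$simulated <- as.character(out$simulated)
  attr(out, "matrix") <- unclass(counts)
  out
}

#' Overall accuracy and Cohen's Kappa of a simulated map
#'
#' Accuracy is the diagonal share of the observed-vs-simulated confusion
#' matrix; Kappa corrects it for the agreement expected from the marginal
#' class frequencies, `kappa = (po - pe) / (1 - pe)`.
#'
#' @param observed,simulated Aligned `categorical_grid`s.
#' @return One-row tibble with `accuracy` and `kappa`.
#' @export
overall_accuracy_kappa <- function(observed, simulated) {
  cc <- confusion_counts(observed, simulated)
  m <- attr(cc, "matrix")
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (po >= 1) 1 else NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  tibble::tibble(accuracy = po, kappa = kappa)
}

#' Three-map figure of merit
#'
#' Superimposes the initial map, the observed final map and the simulated
#' final map and classifies every cell as a hit (observed change, simulated
#' the same change), miss (observed change, simulated persistence), wrong hit
#' (observed change, simulated a different change) or false alarm (observed
#' persistence, simulated change). `FoM = H / (H + M + WH + FA)`.
#'
#' With `classes` given, a cell enters the bookkeeping only if one of those
#' classes is the destination of the observed or the simulated transition
#' (per-class FoM for construction classes, or their union for an aggregate
#' "urban" FoM).
#'
#' @param initial,observed,simulated Aligned `categorical_grid`s.
#' @param classes Optional character vector of destination class names to
#'   restrict to.
#' @return One-row tibble with `hits`, `misses`, `wrong_hits`, `false_alarms`
#'   (cell counts) and `fom` (fraction; `NaN` if no cell qualifies).
#' @export
figure_of_merit <- function(initial, observed, simulated, classes = NULL) {
  check_aligned(initial, observed)
  check_aligned(initial, simulated)
  ct <- initial$class_table
  v0 <- as.vector(initial$values)
  vo <- as.vector(observed$values)
  vs <- as.vector(simulated$values)
  ok <- !is.na(v0) & !is.na(vo) & !is.na(vs)
  v0 <- v0[ok]; vo <- vo[ok]; vs <- vs[ok]

  obs_change <- vo != v0
  sim_change <- vs != v0
  if (!is.null(classes)) {
    target <- ct$code[match(classes, ct$name)]
    if (anyNA(target)) stop("unknown class names in `classes`", call. = FALSE)
    involved <- (obs_change & vo %in% target) | (sim_change & vs %in% target)
    v0 <- v0[involved]; vo <- vo[involved]; vs <- vs[involved]
    obs_change <- obs_change[involved]; sim_change <- sim_change[involved]
  }
  hits <- sum(obs_change & sim_change & vo == vs)
  misses <- sum(obs_change & !sim_change)
  wrong <- sum(obs_change & sim_change & vo != vs)
  false_alarms <- sum(!obs_change & sim_change)
  denom <- hits + misses + wrong + false_alarms
  tibble::tibble(
    hits = hits, misses = misses, wrong_hits = wrong,
    false_alarms = false_alarms,
    fom = if (denom > 0) hits / denom else NaN
  )
}

#' Standard simulation-accuracy report
#'
#' Bundles overall accuracy, Kappa and the figures of merit for the three
#' construction classes and their union into one tibble, the usual validation
#' summary for a calibration run.
#'
#' @param initial,observed,simulated Aligned `categorical_grid`s.
#' @param construction Character vector of construction-class names (default
#'   `c("UB", "RS", "IM")`).
#' @return One-row tibble: `accuracy`, `kappa`, `fom_<class>` per construction
#'   class and `fom_urban` for the union.
#' @export
validation_report <- function(initial, observed, simulated,
                              construction = c("UB", "RS", "IM")) {
  acc <- overall_accuracy_kappa(observed, simulated)
  per_class <- purrr::map_dbl(construction, function(k) {
    figure_of_merit(initial, observed, simulated, classes = k)$fom
  })
  names(per_class) <- paste0("fom_", tolower(construction))
  urban <- figure_of_merit(initial, observed, simulated,
                           classes = construction)$fom
  dplyr::bind_cols(acc, tibble::as_tibble_row(per_class),
                   tibble::tibble(fom_urban = urban))
}
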