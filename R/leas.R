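# Transition-rule mining: sample newly developed cells per class between two
# dates and fit a probability forest whose positive-class vote fraction is the
# class's development-probability surface.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_driver_stack <- function(drivers, ref) {
  stopifnot(is.list(drivers), length(drivers) >= 1)
  if (is.null(names(drivers)) || any(names(drivers) == "")) {
    stop("drivers must be a named list of continuous grids", call. = FALSE)
  }
  for (nm in names(drivers)) {
    check_aligned(drivers[[nm]], ref, paste0("driver '", nm, "' and map"))
  }
  invisible(TRUE)
}

driver_frame <- function(drivers, idx = NULL) {
  cols <- lapply(drivers, function(g) {
    v <- as.vector(g$values)
    if (is.null(idx)) v else v[idx]
  })
  as.data.frame(cols, check.names = FALSE)
}

#' Extract per-class expansion samples between two land-use maps
#'
#' Converts transition-rule mining into a binary classification problem: for
#' each class k that grew over the interval, positives are cells newly
#' converted to k (`map_t1 == k`, `map_t0 != k`) and negatives are cells that
#' did not change class, each drawn uniformly without replacement at
#' `sampling_rate`. Feature columns are the driver values at the sampled
#' cells.
#'
#' @param map_t0,map_t1 Aligned `categorical_grid`s.
#' @param drivers Named list of aligned `continuous_grid` driver surfaces.
#' @param sampling_rate Fraction of eligible cells sampled per class, in
#'   (0, 1].
#' @param seed Integer RNG seed; results are deterministic given the seed.
#' @return An `expansion_samples` object: tibble `$samples` with columns
#'   `class` (code), `label` (1 = newly converted, 0 = unchanged), `cell`
#'   (linear index), `row`, `col` and one column per driver; the driver stack
#'   and grid geometry are carried along for later prediction. Classes with no
#'   growth are skipped with a warning.
#' @export
extract_expansion_samples <- function(map_t0, map_t1, drivers,
                                      sampling_rate = 0.05, seed = 1) {
  check_aligned(map_t0, map_t1)
  check_driver_stack(drivers, map_t0)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0 || sampling_rate > 1) {
    stop("sampling_rate must lie in (0, 1]", call. = FALSE)
  }
  v0 <- as.vector(map_t0$values)
  v1 <- as.vector(map_t1$values)
  ok <- !is.na(v0) & !is.na(v1)
  dfr <- driver_frame(drivers)
  ok <- ok & stats::complete.cases(dfr)
  unchanged <- which(ok & v0 == v1)
  ct <- map_t0$class_table
  nr <- nrow(map_t0$values)

  samples <- with_seed(seed, {
    purrr::map_dfr(ct$code, function(k) {
      pos_pool <- which(ok & v1 == k & v0 != k)
      if (length(pos_pool) == 0) {
        warning("class ", ct$name[ct$code == k],
                " has no growth; no samples extracted", call. = FALSE)
        return(NULL)
      }
      n_pos <- max(1L, round(length(pos_pool) * sampling_rate))
      n_neg <- max(1L, round(length(unchanged) * sampling_rate))
      pos <- sort(sample(pos_pool, n_pos))
      neg <- sort(sample(unchanged, n_neg))
      idx <- c(pos, neg)
      dplyr::bind_cols(
        tibble::tibble(
          class = k,
          label = rep(c(1L, 0L), c(n_pos, n_neg)),
          cell = idx,
          row = ((idx - 1L) %% nr) + 1L,
          col = ((idx - 1L) %/% nr) + 1L
        ),
        dfr[idx, , drop = FALSE]
      )
    })
  })
  structure(
    list(samples = tibble::as_tibble(samples), drivers = drivers,
         class_table = ct, geometry = map_t0[c("cell_size", "origin")],
         template = map_t0, sampling_rate = sampling_rate, seed = seed),
    class = "expansion_samples"
  )
}

#' @export
print.expansion_samples <- function(x, ...) {
  cat(sprintf("<expansion_samples> %d rows, %d drivers, rate %g\n",
              nrow(x$samples), length(x$drivers), x$sampling_rate))
  print(dplyr::count(x$samples, .data$class, .data$label))
  invisible(x)
}

#' Fit per-class development-probability surfaces with a random forest
#'
#' For each sampled class a probability forest (classification trees with
#' probability averaging — for binary 0/1 targets this equals the regression
#' forest's vote fraction) is fitted on the class's expansion samples. The
#' fitted forest is evaluated at every cell of the grid, giving the class's
#' development-probability surface in \[0, 1\], and the mean impurity decrease
#' per driver, normalised to sum 1, gives the driver contributions.
#'
#' @param samples An `expansion_samples` object.
#' @param n_trees Number of trees (default 20).
#' @param mtry Candidate drivers per split (default 9); clamped to the number
#'   of available drivers.
#' @param seed Integer RNG seed; surfaces are bit-reproducible given the seed.
#' @return A `development_probability` object with `$surfaces` (named list of
#'   `continuous_grid`s keyed by class name), `$importance` (tibble: `class`,
#'   `driver`, `importance`) and `$models` (the ranger fits).
#' @export
fit_development_probability <- function(samples, n_trees = 20, mtry = 9,
                                        seed = 1) {
  stopifnot(inherits(samples, "expansion_samples"))
  drv_names <- names(samples$drivers)
  mtry <- min(mtry, length(drv_names))
  classes <- sort(unique(samples$samples$class))
  ct <- samples$class_table
  tmpl <- samples$template
  all_df <- driver_frame(samples$drivers)
  predictable <- stats::complete.cases(all_df) & !is.na(as.vector(tmpl$values))

  fits <- purrr::map(classes, function(k) {
    df <- dplyr::filter(samples$samples, .data$class == k)
    if (length(unique(df$label)) < 2) {
      stop("class ", ct$name[ct$code == k],
           " has single-class labels; cannot train", call. = FALSE)
    }
    dat <- data.frame(label = factor(df$label, levels = c(0, 1)),
                      df[, drv_names, drop = FALSE], check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "label", data = dat,
      num.trees = n_trees, mtry = mtry, probability = TRUE,
      importance = "impurity", seed = seed + k, num.threads = 1
    )
    pred <- rep(NA_real_, length(predictable))
    pr <- stats::predict(fit, all_df[predictable, , drop = FALSE],
                         num.threads = 1)$predictions
    pred[predictable] <- pr[, "1"]
    surface <- continuous_grid(
      matrix(pred, nrow(tmpl$values), ncol(tmpl$values)),
      cell_size = tmpl$cell_size, origin = tmpl$origin
    )
    imp <- fit$variable.importance
    imp <- pmax(imp, 0)
    imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
    list(model = fit, surface = surface,
         importance = tibble::tibble(class = ct$name[ct$code == k],
                                     driver = names(imp),
                                     importance = unname(imp)))
  })
  names(fits) <- ct$name[match(classes, ct$code)]
  structure(
    list(
      surfaces = purrr::map(fits, "surface"),
      importance = purrr::list_rbind(purrr::map(fits, "importance")),
      models = purrr::map(fits, "model"),
      classes = names(fits),
      class_table = ct,
      n_trees = n_trees, mtry = mtry, seed = seed
    ),
    class = "development_probability"
  )
}

#' @export
print.development_probability <- function(x, ...) {
  cat(sprintf("<development_probability> classes: %s (%d trees, mtry %d)\n",
              paste(x$classes, collapse = ", "), x$n_trees, x$mtry))
  invisible(x)
}

#' @rdname fit_development_probability
#' @param x A `development_probability`.
#' @param ... Unused.
#' @return `tidy()`: the per-class driver-importance tibble.
#' @export
tidy.development_probability <- function(x, ...) x$importance

#' Export expansion samples as a plain tibble / CSV
#'
#' @param x An `expansion_samples` object.
#' @param ... Unused.
#' @return Tibble with `class`, `label`, position and driver columns.
#' @export
as_tibble.expansion_samples <- function(x, ...) x$samples
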