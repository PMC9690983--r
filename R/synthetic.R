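# Seeded synthetic regions: patchy land-use mosaics, driver stacks with known
# monotone effects, correlated ecological fields, and ground-truth growth
# (organic vs spontaneous) so the full pipeline is testable with no download.

smooth_noise <- function(nr, nc, window = 7) {
  w <- 2 * floor(window / 2) + 1  # odd
  K <- matrix(1 / w^2, w, w)
  x <- matrix(stats::runif(nr * nc), nr, nc)
  as.matrix(EBImage::filter2(x, K, boundary = "replicate"))
}

#' Specification of a synthetic study region
#'
#' Defines a seeded, fully reproducible synthetic landscape: an 8-class
#' land-use mosaic grown from random patch seeds, driver surfaces with known
#' monotone effects on the growing classes, correlated ecological fields and a
#' growth recipe (cells to add per class, split between organic edge growth
#' and spontaneous detached seeds).
#'
#' @param n_rows,n_cols Grid size in cells (default 200 x 200).
#' @param cell_size Cell edge in metres (default 30).
#' @param proportions Named class mixture, summing to 1. The default mosaic is
#'   dominated by agriculture and woodland with small construction classes,
#'   the structure the allocator is built for.
#' @param patches_per_class Named integer vector of initial patch seeds per
#'   class; default scales with the mixture (more patches for commoner
#'   classes).
#' @param drivers Named list of driver definitions, each
#'   `list(type = "gradient"|"radial"|"noise", effects = named coefficients)`.
#'   `gradient` rises west to east, `radial` is the Euclidean distance from
#'   the grid centre (metres), `noise` is smoothed white noise. `effects`
#'   gives the monotone effect of the min-max-normalised driver on each
#'   growing class's placement score (negative = attraction to small values).
#' @param growth Tibble with `class`, `cells`, `organic_frac`, `seeds`: the
#'   ground-truth growth recipe per construction class.
#' @param convertible Class names growth may consume (default AG, GL, WL).
#' @param eco_window Smoothing window (cells) of the ecological random fields.
#' @param seed Integer RNG seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_rows = 200, n_cols = 200, cell_size = 30,
                           proportions = c(AG = 0.35, WL = 0.25, GL = 0.15,
                                           WT = 0.06, UB = 0.08, BC = 0.03,
                                           RS = 0.05, IM = 0.03),
                           patches_per_class = NULL,
                           drivers = list(
                             d_centre = list(type = "radial",
                                             effects = c(UB = -1, RS = -0.3)),
                             d_east = list(type = "gradient",
                                           effects = c(IM = 1)),
                             suitability = list(type = "noise",
                                                effects = c(UB = 0.2, IM = 0.2,
                                                            RS = 0.2))
                           ),
                           growth = tibble::tibble(
                             class = c("UB", "IM", "RS"),
                             cells = c(600L, 400L, 200L),
                             organic_frac = c(0.7, 0.5, 0.8),
                             seeds = c(5L, 8L, 3L)
                           ),
                           convertible = c("AG", "GL", "WL"),
                           eco_window = 9, seed = 42) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  stopifnot(all(names(proportions) %in% land_classes()$name))
  if (is.null(patches_per_class)) {
    patches_per_class <- pmax(round(30 * proportions), 1L)
  }
  if (sum(patches_per_class) > n_rows * n_cols) {
    stop("more initial patches than cells", call. = FALSE)
  }
  if (any(growth$organic_frac < 0 | growth$organic_frac > 1)) {
    stop("organic_frac must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         proportions = proportions, patches_per_class = patches_per_class,
         drivers = drivers, growth = growth, convertible = convertible,
         eco_window = eco_window, seed = seed),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d x %d cells at %g m, seed %d\n",
              x$n_rows, x$n_cols, x$cell_size, x$seed))
  invisible(x)
}

neighbor_count <- function(bin) {
  cnt <- 0
  for (i in seq_len(nrow(moore_offsets))) {
    cnt <- cnt + shift_matrix(bin, moore_offsets$dr[i], moore_offsets$dc[i])
  }
  cnt
}

make_driver <- function(def, nr, nc, cell_size, window) {
  m <- switch(def$type,
    gradient = matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc) +
      0.05 * matrix(stats::runif(nr * nc), nr, nc),
    radial = {
      src <- matrix(NA_integer_, nr, nc)
      src[ceiling(nr / 2), ceiling(nc / 2)] <- 5L
      g <- categorical_grid(src, cell_size = cell_size)
      g$values[is.na(g$values)] <- 1L
      euclidean_distance(g, 5L)$values
    },
    noise = smooth_noise(nr, nc, window),
    stop("unknown driver type: ", def$type, call. = FALSE)
  )
  m
}

# Placement score of class `cls`: sum of effect coefficients times the
# min-max-normalised drivers, shifted to be positive.
placement_score <- function(drivers, defs, cls) {
  score <- 0
  for (nm in names(defs)) {
    eff <- defs[[nm]]$effects
    if (!is.null(eff) && cls %in% names(eff)) {
      v <- drivers[[nm]]$values
      rng <- range(v, na.rm = TRUE)
      nv <- if (diff(rng) == 0) v * 0 else (v - rng[1]) / diff(rng)
      score <- score + eff[[cls]] * nv
    }
  }
  if (length(score) == 1) return(NULL)  # class has no active driver
  score - min(score, na.rm = TRUE) + 1e-6
}

#' Generate a synthetic region
#'
#' Builds, reproducibly from the spec's seed: a patchy categorical mosaic
#' (class patches grown by seeded random accretion from random patch seeds, to
#' the spec's mixture proportions), the driver stack, and the ecological input
#' fields (smoothed-noise correlated random fields in \[0, 1\], a positive
#' resistance surface and the water mask as MCR sources).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `map` (a `categorical_grid`), `drivers` (named list of
#'   `continuous_grid`s) and `eco` (named list of inputs for
#'   [indicator_set()]).
#' @export
generate_region <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  n <- nr * nc
  ct <- land_classes()
  with_seed(spec$seed, {
    quota <- round(spec$proportions * n)
    quota[which.max(quota)] <- quota[which.max(quota)] + (n - sum(quota))
    codes <- ct$code[match(names(quota), ct$name)]
    vals <- matrix(0L, nr, nc)
    # initial patch seeds
    seed_cells <- sample(n, sum(spec$patches_per_class))
    seed_class <- rep(codes, spec$patches_per_class[names(quota)])
    vals[seed_cells] <- seed_class
    left <- quota - tabulate(match(seed_class, codes), length(codes))
    # random accretion rounds
    repeat {
      empty <- vals == 0L
      if (!any(empty)) break
      progress <- FALSE
      for (j in sample(seq_along(codes))) {
        if (left[j] <= 0) next
        adj <- neighbor_count(matrix(as.numeric(vals == codes[j]), nr, nc))
        frontier <- which(empty & adj > 0)
        if (!length(frontier)) next
        take <- frontier[sample.int(length(frontier),
                                    min(left[j], length(frontier)))]
        vals[take] <- codes[j]
        empty[take] <- FALSE
        left[j] <- left[j] - length(take)
        progress <- TRUE
      }
      if (!progress) {
        # isolated empties or starved quotas: fill uniformly at random
        empties <- which(empty)
        fill <- rep(codes[left > 0], pmax(left[left > 0], 0))
        vals[empties] <- sample(fill, length(empties))
        break
      }
    }
    map <- categorical_grid(vals, cell_size = spec$cell_size)

    drivers <- purrr::map(spec$drivers, function(def) {
      continuous_grid(make_driver(def, nr, nc, spec$cell_size,
                                  spec$eco_window),
                      cell_size = spec$cell_size)
    })

    field <- function() continuous_grid(
      normalize_minmax(continuous_grid(smooth_noise(nr, nc, spec$eco_window),
                                       cell_size = spec$cell_size))$values,
      cell_size = spec$cell_size)
    eco <- list(
      npp = field(), fsic = field(), fpre = field(), fslo = field(),
      ftem = field(), falt = field(), k = field(),
      r = field(), ki = field(), ls = field(), c = field(),
      tn = field(), tp = field(), tk = field(), tom = field()
    )
    res <- field()
    eco$resistance <- continuous_grid(1 + 9 * res$values,
                                      cell_size = spec$cell_size)
    eco$sources <- !is.na(map$values) & map$values == ct$code[ct$name == "WT"]
    list(map = map, drivers = drivers, eco = eco)
  })
}

#' Evolve ground-truth growth on a synthetic region
#'
#' Adds the growth recipe's cells per class with the dichotomy the allocator
#' must recover: the organic share attaches 8-connected to existing patches at
#' the convertible frontier cells with the highest placement score (the known
#' monotone driver rule); the spontaneous share starts `seeds` new detached
#' patches (sampled among convertible cells not adjacent to the class,
#' probability proportional to the score) and grows them locally. The true
#' per-cell growth mode is recorded.
#'
#' @param map_t0 Starting `categorical_grid` (from [generate_region()]).
#' @param drivers Driver stack from [generate_region()].
#' @param spec The [synthetic_spec()] (growth recipe, effects, seed).
#' @return List with `map` (the evolved `categorical_grid`) and `truth`
#'   (tibble: `cell`, `row`, `col`, `class`, `mode` = "organic"/
#'   "spontaneous").
#' @export
evolve_reference_growth <- function(map_t0, drivers, spec) {
  ct <- map_t0$class_table
  nr <- nrow(map_t0$values); nc <- ncol(map_t0$values)
  conv_codes <- ct$code[match(spec$convertible, ct$name)]
  vals <- map_t0$values
  truth <- list()
  with_seed(spec$seed + 1L, {
    for (gi in seq_len(nrow(spec$growth))) {
      cls <- spec$growth$class[gi]
      code <- ct$code[ct$name == cls]
      n_total <- spec$growth$cells[gi]
      n_org <- round(n_total * spec$growth$organic_frac[gi])
      n_seeds <- spec$growth$seeds[gi]
      score <- placement_score(drivers, spec$drivers, cls)
      if (is.null(score)) score <- matrix(1, nr, nc) + 0 * vals
      score <- score + 1e-9 * matrix(stats::runif(nr * nc), nr, nc)  # tie-break
      convertible <- matrix(vals %in% conv_codes, nr, nc)
      if (sum(convertible) < n_total) {
        stop("insufficient convertible cells for class ", cls, call. = FALSE)
      }
      # organic: highest-score frontier cells, frontier recomputed as it grows
      added_org <- 0L
      while (added_org < n_org) {
        adj <- neighbor_count(matrix(as.numeric(vals == code), nr, nc))
        frontier <- which(convertible & adj > 0 & vals != code)
        if (!length(frontier)) break
        take_n <- min(n_org - added_org, length(frontier))
        take <- frontier[order(score[frontier], decreasing = TRUE)[seq_len(take_n)]]
        vals[take] <- code
        convertible[take] <- FALSE
        truth[[length(truth) + 1]] <- tibble::tibble(
          cell = take, class = cls, mode = "organic")
        added_org <- added_org + take_n
      }
      # spontaneous: detached seeds, then local accretion
      n_spont <- n_total - added_org
      if (n_spont > 0 && n_seeds > 0) {
        adj <- neighbor_count(matrix(as.numeric(vals == code), nr, nc))
        pool <- which(convertible & adj == 0)
        seeds <- integer(0)
        for (s in seq_len(min(n_seeds, n_spont))) {
          if (!length(pool)) break
          pick <- pool[sample.int(length(pool), 1, prob = score[pool])]
          seeds <- c(seeds, pick)
          # keep later seeds detached from this one
          pr <- ((pick - 1L) %% nr) + 1L
          pc <- ((pick - 1L) %/% nr) + 1L
          pool_r <- ((pool - 1L) %% nr) + 1L
          pool_c <- ((pool - 1L) %/% nr) + 1L
          pool <- pool[abs(pool_r - pr) > 1 | abs(pool_c - pc) > 1]
        }
        vals[seeds] <- code
        convertible[seeds] <- FALSE
        truth[[length(truth) + 1]] <- tibble::tibble(
          cell = seeds, class = cls, mode = "spontaneous")
        spont_cells <- seeds
        grown <- length(seeds)
        while (grown < n_spont) {
          # grow only the spontaneous patches, not the pre-existing ones
          bin <- matrix(0, nr, nc); bin[spont_cells] <- 1
          adj <- neighbor_count(bin)
          frontier <- which(convertible & adj > 0 & vals != code)
          if (!length(frontier)) break
          take_n <- min(n_spont - grown, length(frontier))
          take <- frontier[order(score[frontier],
                                 decreasing = TRUE)[seq_len(take_n)]]
          vals[take] <- code
          convertible[take] <- FALSE
          spont_cells <- c(spont_cells, take)
          truth[[length(truth) + 1]] <- tibble::tibble(
            cell = take, class = cls, mode = "spontaneous")
          grown <- grown + take_n
        }
      }
    }
  })
  truth <- purrr::list_rbind(truth)
  truth$row <- ((truth$cell - 1L) %% nr) + 1L
  truth$col <- ((truth$cell - 1L) %/% nr) + 1L
  map <- map_t0
  map$values <- vals
  list(map = map, truth = truth[, c("cell", "row", "col", "class", "mode")])
}
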