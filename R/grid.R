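#' Land-use classes used throughout the package
#'
#' The eight-class coding shared by all categorical grids: agricultural land,
#' woodland, grassland, water, urban built-up, beach, rural settlement, and
#' industrial/mining land. Codes are fixed so transition matrices from
#' different sources are directly comparable.
#'
#' @return A tibble with columns `code` (integer 1..8) and `name` (abbreviated
#'   class label).
#' @export
#' @examples
#' land_classes()
land_classes <- function() {
  tibble::tibble(
    code = 1:8,
    name = c("AG", "WL", "GL", "WT", "UB", "BC", "RS", "IM")
  )
}

#' Construct a categorical (land-use) grid
#'
#' A `categorical_grid` is an integer-coded raster: a matrix of class codes
#' with `NA` marking nodata cells, plus the geometry needed to align it with
#' other grids (cell size in metres, origin at the upper-left corner).
#'
#' @param values Integer matrix of class codes; `NA` = nodata.
#' @param cell_size Cell edge length in metres (default 30).
#' @param origin Numeric length-2, (x, y) of the upper-left corner.
#' @param class_table Tibble with columns `code`, `name`; defaults to
#'   [land_classes()]. Every non-`NA` code in `values` must appear in it.
#' @return A `categorical_grid` object (inherits `land_grid`).
#' @export
categorical_grid <- function(values, cell_size = 30, origin = c(0, 0),
                             class_table = land_classes()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.double(values)) {
    if (any(values != round(values), na.rm = TRUE)) {
      stop("categorical grid values must be integers", call. = FALSE)
    }
    storage.mode(values) <- "integer"
  }
  codes <- sort(unique(values[!is.na(values)]))
  if (length(codes) && !all(codes %in% class_table$code)) {
    stop("codes not in class_table: ",
         paste(setdiff(codes, class_table$code), collapse = ", "),
         call. = FALSE)
  }
  new_land_grid(values, cell_size, origin,
                class = "categorical_grid", class_table = class_table)
}

#' Construct a continuous grid
#'
#' A real-valued raster sharing the geometry model of [categorical_grid()];
#' used for driver surfaces, probabilities and ecological indicators.
#'
#' @inheritParams categorical_grid
#' @param values Numeric matrix; `NA` = nodata. Non-finite values outside the
#'   nodata mask are rejected.
#' @return A `continuous_grid` object (inherits `land_grid`).
#' @export
continuous_grid <- function(values, cell_size = 30, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values) & !is.na(values))) {
    stop("non-finite values outside the nodata mask", call. = FALSE)
  }
  new_land_grid(values, cell_size, origin, class = "continuous_grid")
}

new_land_grid <- function(values, cell_size, origin, class, class_table = NULL) {
  stopifnot(is.matrix(values), length(origin) == 2)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("cell_size must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), class_table = class_table),
    class = c(class, "land_grid")
  )
}

#' @export
dim.land_grid <- function(x) dim(x$values)

#' @export
print.land_grid <- function(x, ...) {
  kind <- if (inherits(x, "categorical_grid")) "categorical" else "continuous"
  cat(sprintf("<%s land_grid> %d x %d cells, %g m, origin (%g, %g)\n",
              kind, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  n_na <- sum(is.na(x$values))
  if (inherits(x, "categorical_grid")) {
    tab <- table(factor(x$values, levels = x$class_table$code,
                        labels = x$class_table$name))
    cat("  cells per class:", paste(names(tab), tab, sep = "=", collapse = " "),
        if (n_na) sprintf(" nodata=%d", n_na) else "", "\n")
  } else {
    rng <- range(x$values, na.rm = TRUE)
    cat(sprintf("  range [%g, %g]%s\n", rng[1], rng[2],
                if (n_na) sprintf(", nodata=%d", n_na) else ""))
  }
  invisible(x)
}

#' Test whether two grids share the same geometry
#'
#' Grids are aligned iff they have identical shape, cell size and origin.
#'
#' @param a,b `land_grid` objects.
#' @param tol Numeric tolerance for cell size and origin comparison.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

check_aligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) {
    stop(what, " are not aligned (shape, cell_size and origin must match)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Area of one cell in hectares
#' @param grid A `land_grid`.
#' @return Numeric scalar, hectares.
#' @export
cell_area_ha <- function(grid) grid$cell_size^2 / 1e4

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long-format view of a grid
#'
#' @param x A `land_grid`.
#' @param ... Unused.
#' @return A tibble with `row`, `col` (1-based), `x`, `y` (cell-centre
#'   coordinates, metres) and `value`; nodata cells included with `NA`.
#' @export
as_tibble.land_grid <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  cx <- x$origin[1] + (col - 0.5) * x$cell_size
  cy <- x$origin[2] - (row - 0.5) * x$cell_size
  val <- as.vector(x$values)
  tibble::tibble(row = row, col = col, x = cx, y = cy, value = val)
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

ASC_NODATA <- -9999

#' Read a raster from an ESRI ASCII grid file
#'
#' The ASCII grid dialect (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by row-major values, north row first) is the
#' package's interchange and fixture format.
#'
#' @param path Path to the `.asc` file.
#' @param kind `"categorical"` or `"continuous"`.
#' @param class_table Class table for categorical grids.
#' @return A [categorical_grid()] or [continuous_grid()].
#' @export
read_grid <- function(path, kind = c("categorical", "continuous"),
                      class_table = land_classes()) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header <- list()
  i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(header))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- if (!is.null(header$nodata_value)) header$nodata_value else ASC_NODATA
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- header$nrows; nc <- header$ncols
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, ": ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  xll <- header$xllcorner %||% 0
  yll <- header$yllcorner %||% 0
  origin <- c(xll, yll + nr * header$cellsize)
  if (kind == "categorical") {
    if (any(m != round(m), na.rm = TRUE)) {
      stop("non-integer values in categorical raster: ", path, call. = FALSE)
    }
    categorical_grid(m, cell_size = header$cellsize, origin = origin,
                     class_table = class_table)
  } else {
    continuous_grid(m, cell_size = header$cellsize, origin = origin)
  }
}

#' Write a grid to an ESRI ASCII grid file
#'
#' @param grid A `land_grid`.
#' @param path Output path.
#' @param digits Significant digits for continuous values.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "land_grid"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  header <- c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(grid$origin[1], digits = 15)),
    paste("yllcorner", format(grid$origin[2] - nr * grid$cell_size, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", ASC_NODATA)
  )
  m <- grid$values
  body <- apply(m, 1, function(r) {
    r[is.na(r)] <- ASC_NODATA
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write raster: ", path, call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

# ---- cross-tabulation -------------------------------------------------------

#' Cross-tabulate two aligned land-use maps into a transition area matrix
#'
#' Entry (i, j) is the area (hectares) of cells that are class i in `a` and
#' class j in `b`. The total equals the common non-nodata area, so the matrix
#' conserves area exactly.
#'
#' @param a,b Aligned `categorical_grid`s with a common class table.
#' @return A tibble with columns `from`, `to` (class names), `from_code`,
#'   `to_code` and `area_ha`, one row per class pair (zeros included). The
#'   full matrix is available via `attr(x, "matrix")`.
#' @export
cross_tabulate <- function(a, b) {
  check_aligned(a, b)
  ct <- a$class_table
  ok <- !is.na(a$values) & !is.na(b$values)
  fa <- factor(a$values[ok], levels = ct$code)
  fb <- factor(b$values[ok], levels = ct$code)
  counts <- table(fa, fb)
  m <- unclass(counts) * cell_area_ha(a)
  dimnames(m) <- list(from = ct$name, to = ct$name)
  out <- tibble::tibble(
    from = rep(ct$name, times = nrow(ct)),
    to = rep(ct$name, each = nrow(ct)),
    from_code = rep(ct$code, times = nrow(ct)),
    to_code = rep(ct$code, each = nrow(ct)),
    area_ha = as.vector(m)
  )
  attr(out, "matrix") <- m
  out
}

#' Class areas of a categorical grid
#'
#' @param grid A `categorical_grid`.
#' @return Tibble with `code`, `name`, `cells`, `area_ha`.
#' @export
class_areas <- function(grid) {
  ct <- grid$class_table
  counts <- tabulate(factor(grid$values[!is.na(grid$values)],
                            levels = ct$code), nbins = nrow(ct))
  tibble::tibble(code = ct$code, name = ct$name, cells = counts,
                 area_ha = counts * cell_area_ha(grid))
}

# ---- distance surfaces ------------------------------------------------------

#' Euclidean distance to the nearest source cell
#'
#' Computes, for every cell, the centre-to-centre Euclidean distance (metres)
#' to the nearest cell whose code is in `target_codes`; source cells get 0.
#' Uses an exact Euclidean distance transform.
#'
#' @param sources A `categorical_grid`.
#' @param target_codes Integer codes defining the source set.
#' @return A `continuous_grid` of distances in metres.
#' @export
euclidean_distance <- function(sources, target_codes) {
  is_src <- !is.na(sources$values) & sources$values %in% target_codes
  if (!any(is_src)) stop("no source cells for the given codes", call. = FALSE)
  # distmap: distance of non-zero pixels to the nearest zero pixel
  x <- matrix(1, nrow(sources$values), ncol(sources$values))
  x[is_src] <- 0
  d <- EBImage::distmap(x, metric = "euclidean")
  continuous_grid(as.matrix(d) * sources$cell_size,
                  cell_size = sources$cell_size, origin = sources$origin)
}

#' Min-max rescale a continuous grid to [0, 1]
#'
#' Helper for normalising driver and indicator surfaces before they enter the
#' probability formulas. Constant surfaces map to 0.
#'
#' @param grid A `continuous_grid`.
#' @param invert If `TRUE`, returns `1 - scaled` (useful for turning distances
#'   into proximity scores).
#' @return A `continuous_grid` with values in \[0, 1\].
#' @export
normalize_minmax <- function(grid, invert = FALSE) {
  v <- grid$values
  rng <- range(v, na.rm = TRUE)
  out <- if (diff(rng) == 0) v * 0 else (v - rng[1]) / diff(rng)
  if (invert) out <- 1 - out
  continuous_grid(out, cell_size = grid$cell_size, origin = grid$origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
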