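# Small in-code fixtures shared across the suite.

cat_grid <- function(values, cell_size = 30, ...) {
  categorical_grid(matrix(as.integer(values), nrow = nrow(values),
                          ncol = ncol(values)), cell_size = cell_size, ...)
}

cont_grid <- function(values, cell_size = 30) {
  continuous_grid(values, cell_size = cell_size)
}

# constant-valued continuous grid
flat <- function(value, nr = 3, nc = 3, cell_size = 30) {
  continuous_grid(matrix(value, nr, nc), cell_size = cell_size)
}

# a small mosaic with all 8 classes present
toy_mosaic <- function(nr = 10, nc = 10, seed = 1) {
  set.seed(seed)
  categorical_grid(matrix(sample(1:8, nr * nc, replace = TRUE), nr, nc))
}

# brute-force minimal cumulative resistance by DFS over all simple paths
brute_mcr <- function(resistance, sources) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  cs <- resistance$cell_size
  idx <- function(r, c) (c - 1L) * nr + r
  best <- rep(Inf, nr * nc)
  neigh <- function(r, c) {
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        out[[length(out) + 1]] <- c(r2, c2, dr, dc)
      }
    }
    out
  }
  dfs <- function(r, c, cost, visited) {
    i <- idx(r, c)
    if (cost >= best[i]) {
      # still may improve other cells through here only if cost < best;
      # pruning at equality is safe for positive weights
      if (cost > best[i]) return(invisible())
    } else {
      best[i] <<- cost
    }
    for (nb in neigh(r, c)) {
      j <- idx(nb[1], nb[2])
      if (visited[j]) next
      step <- cs * if (nb[3] != 0 && nb[4] != 0) sqrt(2) else 1
      w <- step * (v[r, c] + v[nb[1], nb[2]]) / 2
      visited[j] <- TRUE
      dfs(nb[1], nb[2], cost + w, visited)
      visited[j] <- FALSE
    }
  }
  if (is.matrix(sources)) sources <- which(sources)
  for (s in sources) {
    r <- ((s - 1L) %% nr) + 1L
    c <- ((s - 1L) %/% nr) + 1L
    visited <- rep(FALSE, nr * nc)
    visited[s] <- TRUE
    dfs(r, c, 0, visited)
  }
  matrix(best, nr, nc)
}

# brute-force optimal natural breaks: enumerate all contiguous partitions
brute_jenks <- function(x, k) {
  ux <- sort(unique(x))
  n <- length(ux)
  wt <- as.numeric(table(factor(x, levels = ux)))
  ssd <- function(lo, hi) {
    idx <- lo:hi
    w <- wt[idx]
    mu <- sum(w * ux[idx]) / sum(w)
    sum(w * (ux[idx] - mu)^2)
  }
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_cut <- NULL
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(i) ssd(b[i] + 1, b[i + 1]),
                      numeric(1)))
    if (tot < best) { best <- tot; best_cut <- cuts[, j] }
  }
  list(breaks = ux[best_cut], ssd = best)
}

jenks_total_ssd <- function(x, breaks) {
  cls <- findInterval(x, breaks, left.open = TRUE)
  sum(vapply(split(x, cls), function(g) sum((g - mean(g))^2), numeric(1)))
}
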