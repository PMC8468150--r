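# Independent brute-force oracles for the texture matrices, written as
# plain voxel loops so they share no code with the vectorized builders.

# Construct a binned_roi directly from a level array (NA outside the mask).
make_binned <- function(levels, spacing = c(1, 1, 1), bin_width = 25) {
  levels <- array(as.integer(levels), dim = dim(levels))
  structure(list(levels = levels, mask = !is.na(levels),
                 n_bins = max(levels, na.rm = TRUE),
                 bin_width = bin_width, roi_min = 0, spacing = spacing),
            class = "binned_roi")
}

all_offsets_26 <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(d[rowSums(abs(d)) > 0, , drop = FALSE])
}

in_grid <- function(v, dims) all(v >= 1) && all(v <= dims)

oracle_glcm <- function(binned) {
  g <- binned$levels
  dims <- dim(g)
  nb <- binned$n_bins
  M <- matrix(0, nb, nb)
  offs <- all_offsets_26()
  for (i1 in 1:dims[1]) for (j1 in 1:dims[2]) for (k1 in 1:dims[3]) {
    a <- g[i1, j1, k1]
    if (is.na(a)) next
    for (r in seq_len(nrow(offs))) {
      v <- c(i1, j1, k1) + offs[r, ]
      if (!in_grid(v, dims)) next
      b <- g[v[1], v[2], v[3]]
      if (is.na(b)) next
      M[a, b] <- M[a, b] + 1
    }
  }
  M
}

oracle_glrlm <- function(binned) {
  g <- binned$levels
  dims <- dim(g)
  nb <- binned$n_bins
  dirs <- radphase:::unique_directions_3d()
  runs <- list()
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    for (i1 in 1:dims[1]) for (j1 in 1:dims[2]) for (k1 in 1:dims[3]) {
      v <- c(i1, j1, k1)
      a <- g[i1, j1, k1]
      if (is.na(a)) next
      prev <- v - d
      # run starts here iff the previous voxel is not part of a same-level
      # run (outside the grid, outside the mask, or a different level)
      if (in_grid(prev, dims)) {
        pa <- g[prev[1], prev[2], prev[3]]
        if (!is.na(pa) && pa == a) next
      }
      len <- 1L
      nxt <- v + d
      while (in_grid(nxt, dims)) {
        na_ <- g[nxt[1], nxt[2], nxt[3]]
        if (is.na(na_) || na_ != a) break
        len <- len + 1L
        nxt <- nxt + d
      }
      runs[[length(runs) + 1L]] <- c(a, len)
    }
  }
  runs <- do.call(rbind, runs)
  M <- matrix(0, nb, max(runs[, 2]))
  for (i in seq_len(nrow(runs))) {
    M[runs[i, 1], runs[i, 2]] <- M[runs[i, 1], runs[i, 2]] + 1
  }
  M
}

# Flood-fill zones of equal level, 26-connected.  Returns a data frame of
# (level, size, distance) with distance the zone minimum of the brute-force
# Chebyshev distance to the nearest out-of-ROI voxel (out-of-grid counts).
oracle_zones <- function(binned) {
  g <- binned$levels
  dims <- dim(g)
  offs <- all_offsets_26()
  seen <- array(FALSE, dim = dims)
  dist <- oracle_distance_map(binned)
  zones <- list()
  for (i1 in 1:dims[1]) for (j1 in 1:dims[2]) for (k1 in 1:dims[3]) {
    if (seen[i1, j1, k1] || is.na(g[i1, j1, k1])) next
    lev <- g[i1, j1, k1]
    queue <- list(c(i1, j1, k1))
    seen[i1, j1, k1] <- TRUE
    members <- list()
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      members[[length(members) + 1L]] <- v
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (!in_grid(w, dims)) next
        if (seen[w[1], w[2], w[3]]) next
        lw <- g[w[1], w[2], w[3]]
        if (is.na(lw) || lw != lev) next
        seen[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
    dmin <- min(vapply(members, function(v) dist[v[1], v[2], v[3]],
                       numeric(1)))
    zones[[length(zones) + 1L]] <- c(lev, length(members), dmin)
  }
  out <- as.data.frame(do.call(rbind, zones))
  names(out) <- c("level", "size", "distance")
  out
}

zones_to_mat <- function(zones, nb, col) {
  M <- matrix(0, nb, max(zones[[col]]))
  for (i in seq_len(nrow(zones))) {
    M[zones$level[i], zones[[col]][i]] <- M[zones$level[i],
                                            zones[[col]][i]] + 1
  }
  M
}

oracle_glszm <- function(binned) {
  zones_to_mat(oracle_zones(binned), binned$n_bins, "size")
}

oracle_gldzm <- function(binned) {
  zones_to_mat(oracle_zones(binned), binned$n_bins, "distance")
}

# Brute-force Chebyshev distance from each in-mask voxel to the nearest
# out-of-ROI voxel, including the virtual background ring outside the grid.
oracle_distance_map <- function(binned) {
  m <- binned$mask
  dims <- dim(m)
  bg <- which(!m, arr.ind = TRUE)
  out <- array(NA_real_, dim = dims)
  for (i1 in 1:dims[1]) for (j1 in 1:dims[2]) for (k1 in 1:dims[3]) {
    if (!m[i1, j1, k1]) next
    v <- c(i1, j1, k1)
    d_edge <- min(v, dims - v + 1)  # distance to just outside the grid
    d_bg <- Inf
    if (nrow(bg)) {
      d_bg <- min(apply(abs(sweep(bg, 2, v)), 1, max))
    }
    out[i1, j1, k1] <- min(d_edge, d_bg)
  }
  out
}

oracle_ngtdm <- function(binned) {
  g <- binned$levels
  dims <- dim(g)
  nb <- binned$n_bins
  offs <- all_offsets_26()
  n_i <- numeric(nb)
  s_i <- numeric(nb)
  for (i1 in 1:dims[1]) for (j1 in 1:dims[2]) for (k1 in 1:dims[3]) {
    a <- g[i1, j1, k1]
    if (is.na(a)) next
    nbr <- c()
    for (r in seq_len(nrow(offs))) {
      v <- c(i1, j1, k1) + offs[r, ]
      if (!in_grid(v, dims)) next
      b <- g[v[1], v[2], v[3]]
      if (!is.na(b)) nbr <- c(nbr, b)
    }
    if (!length(nbr)) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nbr))
  }
  list(n_i = n_i, s_i = s_i)
}

oracle_ngldm <- function(binned, a_tol = 0L) {
  g <- binned$levels
  dims <- dim(g)
  nb <- binned$n_bins
  offs <- all_offsets_26()
  deps <- list()
  for (i1 in 1:dims[1]) for (j1 in 1:dims[2]) for (k1 in 1:dims[3]) {
    a <- g[i1, j1, k1]
    if (is.na(a)) next
    k <- 0L
    for (r in seq_len(nrow(offs))) {
      v <- c(i1, j1, k1) + offs[r, ]
      if (!in_grid(v, dims)) next
      b <- g[v[1], v[2], v[3]]
      if (!is.na(b) && abs(a - b) <= a_tol) k <- k + 1L
    }
    deps[[length(deps) + 1L]] <- c(a, k)
  }
  deps <- do.call(rbind, deps)
  M <- matrix(0, nb, max(deps[, 2]) + 1L)
  for (i in seq_len(nrow(deps))) {
    M[deps[i, 1], deps[i, 2] + 1L] <- M[deps[i, 1], deps[i, 2] + 1L] + 1
  }
  M
}

# Random small fixtures: dims 2..4 per axis, levels 1..max_levels, random
# mask with at least 2 voxels.
random_fixture <- function(seed, max_levels = 3) {
  set.seed(seed)
  dims <- sample(2:4, 3, replace = TRUE)
  lev <- array(sample.int(max_levels, prod(dims), replace = TRUE),
               dim = dims)
  mask <- array(stats::runif(prod(dims)) < 0.75, dim = dims)
  while (sum(mask) < 2) {
    mask[sample.int(prod(dims), 1)] <- TRUE
  }
  lev[!mask] <- NA_integer_
  # levels present must include 1..n_bins contract? builders use max level
  make_binned(lev)
}

# Pad matrices to a common size before comparison (builders size columns
# by the maximum observed index).
expect_same_counts <- function(a, b) {
  nr <- max(nrow(a), nrow(b))
  nc <- max(ncol(a), ncol(b))
  pad <- function(m) {
    out <- matrix(0, nr, nc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  testthat::expect_equal(pad(a), pad(b))
}

# Independent CCC oracle via the mean-squared-difference identity:
# ccc = 1 - E[(X-Y)^2] / (var x + var y + (mean x - mean y)^2),
# population moments.
oracle_ccc <- function(x, y) {
  n <- length(x)
  vx <- mean((x - mean(x))^2)
  vy <- mean((y - mean(y))^2)
  denom <- vx + vy + (mean(x) - mean(y))^2
  if (denom == 0) return(1)
  1 - mean((x - y)^2) / denom
}
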