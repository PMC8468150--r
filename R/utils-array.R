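# Low-level 3D array helpers shared by the synthetic generator and the
# feature extractor.  All of these operate on plain R arrays; voxel indices
# are 1-based and the axis order is (x, y, z).

# The 13 unique 3D direction vectors at Chebyshev distance 1 (one of each
# +/- pair of the 26-neighbourhood).
unique_directions_3d <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep the lexicographically positive member of each +/- pair
  keep <- d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  unname(d[keep, , drop = FALSE])
}

# Index ranges of the overlap between an array and its copy shifted by `d`:
# returns list(src=, dst=) of 3 ranges each such that arr[src...] and
# arr[dst...] enumerate all voxel pairs (v, v + d) inside the grid.
shift_overlap <- function(dims, d) {
  src <- vector("list", 3)
  dst <- vector("list", 3)
  for (k in 1:3) {
    if (abs(d[k]) >= dims[k]) return(NULL)  # no overlap along this axis
    if (d[k] >= 0) {
      src[[k]] <- seq_len(dims[k] - d[k])
    } else {
      src[[k]] <- (1 - d[k]):dims[k]
    }
    dst[[k]] <- src[[k]] + d[k]
  }
  list(src = src, dst = dst)
}

# Crop an array to the bounding box of a logical mask (same dims), with an
# optional margin clipped at the grid edge.  Returns list(arr=..., ranges=).
crop_to_mask <- function(arr, mask, margin = 0L) {
  stopifnot(identical(dim(arr), dim(mask)))
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  rng <- lapply(1:3, function(k) {
    lo <- max(1L, min(idx[, k]) - margin)
    hi <- min(dims[k], max(idx[, k]) + margin)
    lo:hi
  })
  list(arr = arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE], ranges = rng)
}

# Binary erosion by the 3x3x3 box (Chebyshev ball radius 1), computed as
# three separable 1D erosions.  Voxels outside the grid count as background.
erode_box3 <- function(mask) {
  dims <- dim(mask)
  out <- mask
  for (k in 1:3) {
    n <- dims[k]
    if (n == 1L) {
      out[] <- FALSE  # both out-of-grid neighbours are background
      next
    }
    lo <- slice_shift(out, k, 1L)   # neighbour at index - 1
    hi <- slice_shift(out, k, -1L)  # neighbour at index + 1
    out <- out & lo & hi
  }
  out
}

# Shift a logical/numeric array along axis k by `by` voxels, filling with
# `fill` (background) at the exposed edge.
slice_shift <- function(arr, k, by, fill = FALSE) {
  dims <- dim(arr)
  out <- array(fill, dim = dims)
  n <- dims[k]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- src + by
  idx_src <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  idx_dst <- idx_src
  idx_src[[k]] <- src
  idx_dst[[k]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Chebyshev distance map: for every TRUE voxel, the Chebyshev distance to
# the nearest background voxel, where everything outside the grid is
# background (border voxels get distance 1).  Computed by iterated box
# erosion.
chebyshev_distance_map <- function(mask) {
  dist <- array(0L, dim = dim(mask))
  alive <- mask
  d <- 0L
  while (any(alive)) {
    d <- d + 1L
    eroded <- erode_box3(alive)
    dist[alive & !eroded] <- d
    alive <- eroded
  }
  dist
}

# Separable Gaussian smoothing of a 3D array, kernel truncated at 3 sigma,
# renormalized at the edges (so a constant array stays constant).
# Implemented as sums of shifted arrays, O(kernel length) passes per axis.
gaussian_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  offs <- seq(-half, half)
  kern <- exp(-offs^2 / (2 * sigma^2))
  dims <- dim(arr)
  for (k in 1:3) {
    acc <- array(0, dim = dims)
    for (j in seq_along(offs)) {
      acc <- acc + kern[j] * slice_shift(arr, k, offs[j], fill = 0)
    }
    # edge renormalization: the effective kernel mass along axis k only
    # depends on the index along k, so divide by a recycled 1D profile
    n <- dims[k]
    prof <- vapply(seq_len(n), function(i) {
      sum(kern[i + offs >= 1 & i + offs <= n])
    }, numeric(1))
    rep_each <- if (k == 1) 1L else prod(dims[seq_len(k - 1L)])
    arr <- acc / rep(prof, each = rep_each)
  }
  arr
}

# 3D linear convolution via FFT, returning the "same"-size central part.
# Used for spherical-kernel mean filtering (intensity peaks).
fft_convolve3 <- function(arr, kernel) {
  da <- dim(arr)
  dk <- dim(kernel)
  dpad <- da + dk - 1L
  pa <- array(0, dim = dpad)
  pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- arr
  pk <- array(0, dim = dpad)
  pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(dpad)
  off <- (dk - 1L) %/% 2L
  full[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]),
       off[3] + seq_len(da[3]), drop = FALSE]
}

# Voxel-centre coordinates (mm) for the whole grid, as three arrays.
coord_grids <- function(dims, spacing) {
  list(
    x = array(rep((seq_len(dims[1]) - 1) * spacing[1],
                  times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep((seq_len(dims[2]) - 1) * spacing[2],
                      each = dims[1]), times = dims[3]), dim = dims),
    z = array(rep((seq_len(dims[3]) - 1) * spacing[3],
                  each = dims[1] * dims[2]), dim = dims)
  )
}
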