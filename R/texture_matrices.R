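# Texture-matrix builders.  All six matrices use the full 3D
# 26-neighbourhood at Chebyshev distance 1; directional matrices (GLCM,
# GLRLM) are merged over the 13 unique directions by summation before any
# feature is computed, giving one matrix (and one feature value) per ROI.

#' Gray level co-occurrence matrix (3D, merged directions)
#'
#' Counts ordered pairs of in-mask voxels at Chebyshev distance 1 over all
#' 26 neighbour offsets (equivalently: the 13 unique directions, counted
#' both ways), giving a symmetric `n_bins x n_bins` count matrix.
#'
#' @param binned a `binned_roi` from [discretize()].
#' @param normalize if `TRUE` (default) the matrix is normalized to sum
#'   to 1.
#' @return numeric matrix `n_bins x n_bins`.
#' @export
glcm_matrix <- function(binned, normalize = TRUE) {
  g <- binned$levels
  nb <- binned$n_bins
  dims <- dim(g)
  counts <- matrix(0, nb, nb)
  for (r in seq_len(nrow(unique_directions_3d()))) {
    d <- unique_directions_3d()[r, ]
    ov <- shift_overlap(dims, d)
    if (is.null(ov)) next
    a <- g[ov$src[[1]], ov$src[[2]], ov$src[[3]]]
    b <- g[ov$dst[[1]], ov$dst[[2]], ov$dst[[3]]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate((a[ok] - 1L) * nb + b[ok], nbins = nb * nb)
    counts <- counts + matrix(tab, nb, nb, byrow = TRUE)
  }
  counts <- counts + t(counts)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

#' Gray level run length matrix (3D, merged directions)
#'
#' A run is a maximal set of consecutive in-mask voxels of equal bin index
#' along one of the 13 unique directions; runs of length 1 count.  The
#' matrix entry `(i, l)` is the number of runs of level `i` and length `l`,
#' summed over directions.
#'
#' @inheritParams glcm_matrix
#' @return numeric matrix `n_bins x max_run_length`.
#' @export
glrlm_matrix <- function(binned) {
  g <- binned$levels
  nb <- binned$n_bins
  dims <- dim(g)
  idx <- which(!is.na(g), arr.ind = TRUE)
  lev <- g[!is.na(g)]
  dirs <- unique_directions_3d()
  runs_level <- integer(0)
  runs_len <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    # parameterize each lattice line by the coordinate along the first
    # moving axis: it advances by exactly 1 per step along the direction,
    # and idx - t_par * d is constant on a line (its anchor)
    k0 <- which(d != 0)[1]
    t_par <- idx[, k0] * d[k0]
    line <- idx - outer(t_par, d)
    off <- max(dims) + 1
    span <- 3 * max(dims) + 2
    key <- (line[, 1] + off) + (line[, 2] + off) * span +
      (line[, 3] + off) * span^2
    ord <- order(key, t_par)
    k <- key[ord]
    tt <- t_par[ord]
    lv <- lev[ord]
    n <- length(lv)
    if (n == 0) next
    # a new run starts when the line changes, the step is non-consecutive
    # (an out-of-mask voxel in between), or the level changes
    new_run <- c(TRUE, k[-1] != k[-n] | tt[-1] != tt[-n] + 1 |
                   lv[-1] != lv[-n])
    run_id <- cumsum(new_run)
    runs_level <- c(runs_level, lv[new_run])
    runs_len <- c(runs_len, tabulate(run_id))
  }
  max_len <- max(runs_len)
  mat <- matrix(0, nb, max_len)
  tab <- tabulate((runs_level - 1L) * max_len + runs_len,
                  nbins = nb * max_len)
  mat[] <- matrix(tab, nb, max_len, byrow = TRUE)
  mat
}

# Label 26-connected zones of equal bin index.  Returns a tibble with one
# row per zone: level, size (voxels), and the zone's minimum value of
# `dist` (when a distance map is supplied).
label_zones <- function(binned, dist = NULL) {
  g <- binned$levels
  dims <- dim(g)
  in_mask <- which(!is.na(g))
  vid <- array(NA_integer_, dim = dims)
  vid[in_mask] <- seq_along(in_mask)
  dirs <- unique_directions_3d()
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    ov <- shift_overlap(dims, dirs[r, ])
    if (is.null(ov)) next
    a <- g[ov$src[[1]], ov$src[[2]], ov$src[[3]]]
    b <- g[ov$dst[[1]], ov$dst[[2]], ov$dst[[3]]]
    ia <- vid[ov$src[[1]], ov$src[[2]], ov$src[[3]]]
    ib <- vid[ov$dst[[1]], ov$dst[[2]], ov$dst[[3]]]
    ok <- !is.na(a) & !is.na(b) & a == b
    from <- c(from, ia[ok])
    to <- c(to, ib[ok])
  }
  gr <- igraph::make_empty_graph(n = length(in_mask), directed = FALSE)
  if (length(from)) {
    gr <- igraph::add_edges(gr, rbind(from, to))
  }
  comp <- igraph::components(gr)$membership
  lev <- g[in_mask]
  zl <- tapply(lev, comp, function(v) v[1])
  zs <- tabulate(comp)
  out <- tibble::tibble(level = as.integer(zl), size = zs[as.integer(names(zl))])
  if (!is.null(dist)) {
    dv <- dist[in_mask]
    out$distance <- as.integer(tapply(dv, comp, min)[names(zl)])
  }
  out
}

# Zone tibble -> count matrix with rows = gray level 1..nb.
zones_to_matrix <- function(zones, nb, col) {
  ncol_ <- max(zones[[col]])
  mat <- matrix(0, nb, ncol_)
  for (i in seq_len(nrow(zones))) {
    mat[zones$level[i], zones[[col]][i]] <-
      mat[zones$level[i], zones[[col]][i]] + 1
  }
  mat
}

#' Gray level size zone matrix
#'
#' Zones are maximal 26-connected sets of in-mask voxels sharing a bin
#' index; entry `(i, s)` counts zones of level `i` and size `s` voxels.
#'
#' @inheritParams glcm_matrix
#' @return numeric matrix `n_bins x max_zone_size`.
#' @export
glszm_matrix <- function(binned) {
  zones_to_matrix(label_zones(binned), binned$n_bins, "size")
}

#' Gray level distance zone matrix
#'
#' Zones as in [glszm_matrix()]; the column index is the zone's distance,
#' defined as the minimum over its voxels of the Chebyshev distance to the
#' nearest out-of-ROI voxel (voxels on the ROI border have distance 1;
#' space beyond the image grid counts as out-of-ROI).
#'
#' @inheritParams glcm_matrix
#' @return numeric matrix `n_bins x max_zone_distance`.
#' @export
gldzm_matrix <- function(binned) {
  dist <- chebyshev_distance_map(binned$mask)
  zones_to_matrix(label_zones(binned, dist = dist), binned$n_bins,
                  "distance")
}

#' Neighbourhood gray tone difference matrix components
#'
#' For every in-mask voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its bin index and the mean bin index of its
#' in-mask neighbours is accumulated per gray level.
#'
#' @inheritParams glcm_matrix
#' @return A list with vectors indexed by gray level `1..n_bins`: `n_i`
#'   (voxel counts), `p_i` (probabilities), `s_i` (summed absolute
#'   differences), plus `n_valid` (total voxels contributing).
#' @export
ngtdm_components <- function(binned) {
  g <- binned$levels
  nb <- binned$n_bins
  dims <- dim(g)
  gz <- g
  gz[is.na(gz)] <- 0L
  inm <- !is.na(g)
  nsum <- array(0, dim = dims)
  ncnt <- array(0, dim = dims)
  dirs <- unique_directions_3d()
  for (r in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      d <- sgn * dirs[r, ]
      ov <- shift_overlap(dims, d)
      if (is.null(ov)) next
      add_v <- array(0, dim = dims)
      add_c <- array(0, dim = dims)
      add_v[ov$src[[1]], ov$src[[2]], ov$src[[3]]] <-
        gz[ov$dst[[1]], ov$dst[[2]], ov$dst[[3]]]
      add_c[ov$src[[1]], ov$src[[2]], ov$src[[3]]] <-
        inm[ov$dst[[1]], ov$dst[[2]], ov$dst[[3]]]
      nsum <- nsum + add_v
      ncnt <- ncnt + add_c
    }
  }
  valid <- inm & ncnt > 0
  avg <- nsum[valid] / ncnt[valid]
  lv <- g[valid]
  n_i <- tabulate(lv, nbins = nb)
  s_i <- numeric(nb)
  diffs <- abs(lv - avg)
  agg <- tapply(diffs, lv, sum)
  s_i[as.integer(names(agg))] <- agg
  list(n_i = n_i, p_i = if (sum(n_i) > 0) n_i / sum(n_i) else n_i,
       s_i = s_i, n_valid = sum(n_i))
}

#' Neighbouring gray level dependence matrix
#'
#' The dependence count of an in-mask voxel is the number of its in-mask
#' 26-neighbours whose bin index differs by at most the coarseness
#' parameter `a` (default 0, i.e. exact equality).  Entry `(i, k + 1)`
#' counts voxels of level `i` with dependence `k`.
#'
#' @inheritParams glcm_matrix
#' @param a coarseness tolerance on the level difference (default 0).
#' @return numeric matrix `n_bins x (max_dependence + 1)`.
#' @export
ngldm_matrix <- function(binned, a = 0L) {
  g <- binned$levels
  nb <- binned$n_bins
  dims <- dim(g)
  inm <- !is.na(g)
  dep <- array(0L, dim = dims)
  dirs <- unique_directions_3d()
  for (r in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      d <- sgn * dirs[r, ]
      ov <- shift_overlap(dims, d)
      if (is.null(ov)) next
      a_ <- g[ov$src[[1]], ov$src[[2]], ov$src[[3]]]
      b_ <- g[ov$dst[[1]], ov$dst[[2]], ov$dst[[3]]]
      hit <- !is.na(a_) & !is.na(b_) & abs(a_ - b_) <= a
      add <- array(0L, dim = dims)
      add[ov$src[[1]], ov$src[[2]], ov$src[[3]]] <- hit
      dep <- dep + add
    }
  }
  kmax <- max(dep[inm])
  mat <- matrix(0, nb, kmax + 1L)
  lv <- g[inm]
  kk <- dep[inm]
  tab <- tabulate((lv - 1L) * (kmax + 1L) + kk + 1L,
                  nbins = nb * (kmax + 1L))
  mat[] <- matrix(tab, nb, kmax + 1L, byrow = TRUE)
  mat
}
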