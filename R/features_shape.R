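# Shape and fractal families.  22 of the 23 shape features depend only on
# the mask geometry; the 23rd ("centroid distance") also uses intensities,
# so a mask shared across phases forces the other 22 to be bitwise equal.

#' Morphological shape features (23)
#'
#' 22 purely geometric descriptors of the mask — volume, surface area,
#' sphericity/compactness group, maximum 3D diameter, principal-axis
#' lengths with elongation and flatness, bounding-box measures and radial
#' spread — plus one intensity-dependent feature, `shape_centroid_dist`:
#' the Euclidean distance (mm) between the geometric centroid of the mask
#' and the intensity-weighted centroid of the in-mask HU values (weights
#' shifted to be non-negative by subtracting the ROI minimum; a
#' constant-intensity ROI gives distance 0).
#'
#' Surface area is estimated with a co-area (smoothed-indicator
#' gradient-magnitude integral) estimator: the binary mask is mollified
#' with a Gaussian of 2 voxels and the surface is recovered as the
#' integral of the gradient norm, which converges to the true area for
#' smooth bodies and is accurate to a few percent for digital balls of
#' realistic lesion size.
#'
#' @param mask an [roi_mask()].
#' @param volume the matching [image_volume()] (used only by
#'   `shape_centroid_dist`).
#' @return named numeric vector of 23 features (prefix `shape_`).
#' @export
shape_features <- function(mask, volume) {
  check_same_grid(mask, volume, what = "mask")
  sp <- mask$spacing
  vvol <- prod(sp)
  n <- sum(mask$voxels)
  vol_mm3 <- n * vvol

  idx <- which(mask$voxels, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, `*`)  # voxel centres, mm
  centroid <- colMeans(pts)

  area <- surface_area_coarea(mask)
  r_eq <- (3 * vol_mm3 / (4 * pi))^(1 / 3)
  sphericity <- pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area

  # principal axes from the population covariance of voxel centres
  if (n > 1) {
    cv <- stats::cov(pts) * (n - 1) / n
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  bb <- apply(pts, 2, range)
  bb_edges <- bb[2, ] - bb[1, ] + sp  # voxel extent, mm
  bb_vol <- prod(bb_edges)

  rad <- sqrt(rowSums(sweep(pts, 2, centroid)^2))

  # intensity-weighted centroid (weights shifted non-negative)
  hu <- volume$voxels[mask$voxels]
  w <- hu - min(hu)
  wc <- if (sum(w) > 0) colSums(pts * w) / sum(w) else centroid

  c(shape_vol_mm3 = vol_mm3,
    shape_n_voxels = as.numeric(n),
    shape_surface_area = area,
    shape_surface_volume_ratio = area / vol_mm3,
    shape_sphericity = sphericity,
    shape_compactness1 = vol_mm3 / (sqrt(pi) * area^1.5),
    shape_compactness2 = 36 * pi * vol_mm3^2 / area^3,
    shape_spherical_disproportion = area / (4 * pi * r_eq^2),
    shape_asphericity = (area^3 / (36 * pi * vol_mm3^2))^(1 / 3) - 1,
    shape_equiv_diameter = 2 * r_eq,
    shape_max_diameter_3d = max_diameter_3d(mask, pts),
    shape_major_axis = major,
    shape_minor_axis = 4 * sqrt(ev[2]),
    shape_least_axis = 4 * sqrt(ev[3]),
    shape_elongation = elong,
    shape_flatness = flat,
    shape_bbox_vol = bb_vol,
    shape_extent = vol_mm3 / bb_vol,
    shape_bbox_max_edge = max(bb_edges),
    shape_bbox_min_edge = min(bb_edges),
    shape_radial_dist_mean = mean(rad),
    shape_radial_dist_sd = sqrt(mean((rad - mean(rad))^2)),
    shape_centroid_dist = sqrt(sum((wc - centroid)^2)))
}

# Co-area surface estimate: |grad of the mollified indicator| integrated
# over the grid, with physical-spacing central differences.
surface_area_coarea <- function(mask) {
  sp <- mask$spacing
  cr <- crop_to_mask(mask$voxels * 1, mask$voxels)
  pad <- 8L  # > 3 sigma support of the mollifier
  d0 <- dim(cr$arr)
  u <- array(0, dim = d0 + 2L * pad)
  u[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <-
    cr$arr
  u <- gaussian_smooth3(u, 2)
  gx <- (slice_shift(u, 1, -1, fill = 0) - slice_shift(u, 1, 1, fill = 0)) /
    (2 * sp[1])
  gy <- (slice_shift(u, 2, -1, fill = 0) - slice_shift(u, 2, 1, fill = 0)) /
    (2 * sp[2])
  gz <- (slice_shift(u, 3, -1, fill = 0) - slice_shift(u, 3, 1, fill = 0)) /
    (2 * sp[3])
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(sp)
}

# Maximum pairwise distance between boundary-voxel centres (boundary =
# in-mask voxels with at least one out-of-mask 6-neighbour), computed in
# chunks to bound memory.
max_diameter_3d <- function(mask, pts = NULL) {
  m <- mask$voxels
  inner <- m &
    slice_shift(m, 1, 1) & slice_shift(m, 1, -1) &
    slice_shift(m, 2, 1) & slice_shift(m, 2, -1) &
    slice_shift(m, 3, 1) & slice_shift(m, 3, -1)
  bnd <- m & !inner
  idx <- which(bnd, arr.ind = TRUE)
  # exact pruning: a voxel strictly between two others on the same (y, z)
  # line is a convex combination of them, so it cannot attain the diameter
  key <- idx[, 2] + max(idx[, 2]) * idx[, 3]
  keep <- logical(nrow(idx))
  for (side in list(which.min, which.max)) {
    sel <- tapply(seq_len(nrow(idx)), key, function(r) r[side(idx[r, 1])])
    keep[unlist(sel)] <- TRUE
  }
  idx <- idx[keep, , drop = FALSE]
  bp <- sweep(idx - 1, 2, mask$spacing, `*`)
  nb <- nrow(bp)
  if (nb == 1) return(0)
  s2 <- rowSums(bp^2)
  best <- 0
  step <- 2048L
  for (s in seq(1L, nb, by = step)) {
    rows <- s:min(nb, s + step - 1L)
    d2 <- outer(s2[rows], s2, `+`) -
      2 * tcrossprod(bp[rows, , drop = FALSE], bp)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Fractal features of the mask (3)
#'
#' Box-counting over dyadic box sizes: the box-counting dimension of the
#' mask, of its boundary surface, and the log2 intercept of the mask's
#' box-count regression (a scale-prefactor heterogeneity summary).  A solid
#' body has mask dimension near 3 and boundary dimension near 2.
#'
#' @param mask an [roi_mask()].
#' @return named numeric vector of 3 features (prefix `fractal_`).
#' @export
fractal_features <- function(mask) {
  m <- mask$voxels
  cr <- crop_to_mask(m, m)
  sub <- cr$arr
  inner <- sub &
    slice_shift(sub, 1, 1) & slice_shift(sub, 1, -1) &
    slice_shift(sub, 2, 1) & slice_shift(sub, 2, -1) &
    slice_shift(sub, 3, 1) & slice_shift(sub, 3, -1)
  bnd <- sub & !inner
  fit_mask <- box_count_fit(sub)
  fit_bnd <- box_count_fit(bnd)
  c(fractal_dim_mask = unname(fit_mask["dim"]),
    fractal_dim_boundary = unname(fit_bnd["dim"]),
    fractal_intercept = unname(fit_mask["intercept"]))
}

# Least-squares fit of log2 N(s) against log2 s for dyadic box sizes.
box_count_fit <- function(arr) {
  idx <- which(arr, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(dim = 0, intercept = 0))
  side <- max(dim(arr))
  sizes <- 2^(0:max(1, floor(log2(side))))
  counts <- vapply(sizes, function(s) {
    box <- (idx - 1L) %/% s
    nbx <- max(box[, 1]) + 2
    nby <- max(box[, 2]) + 2
    length(unique(box[, 1] + box[, 2] * nbx + box[, 3] * nbx * nby))
  }, numeric(1))
  keep <- counts > 0
  if (sum(keep) < 2) return(c(dim = 0, intercept = log2(max(counts, 1))))
  xs <- log2(sizes[keep])
  ys <- log2(counts[keep])
  fit <- stats::lm.fit(cbind(1, xs), ys)
  c(dim = -unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]))
}
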