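# Intensity-based feature families: first-order statistics on raw HU
# values, intensity-histogram features on the discretized levels, and the
# local/global intensity peaks.

# Population (1/n) moments; skewness and excess kurtosis return the
# convention value 0 for constant input.
pop_var <- function(x) mean((x - mean(x))^2)
pop_skew <- function(x) {
  m2 <- pop_var(x)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}
pop_kurt_excess <- function(x) {
  m2 <- pop_var(x)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' First-order intensity statistics (19)
#'
#' Computed on the raw in-mask HU values (no discretization): moments,
#' order statistics, dispersion measures, energy and root-mean-square.
#' Variance and standard deviation use the population (1/n) estimator;
#' kurtosis is excess kurtosis.  The coefficient of variation and quartile
#' coefficient of dispersion return 0 when their denominator is 0 (possible
#' for HU data whose mean crosses zero); this convention keeps every value
#' finite.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @return named numeric vector of 19 features (prefix `stats_`).
#' @export
stats_features <- function(volume, mask) {
  check_same_grid(mask, volume, what = "mask")
  x <- volume$voxels[mask$voxels]
  q <- stats::quantile(x, c(.10, .25, .5, .75, .90), names = FALSE)
  v <- pop_var(x)
  m <- mean(x)
  inner <- x[x >= q[1] & x <= q[5]]
  c(stats_mean = m,
    stats_var = v,
    stats_sd = sqrt(v),
    stats_skewness = pop_skew(x),
    stats_kurtosis = pop_kurt_excess(x),
    stats_median = q[3],
    stats_min = min(x),
    stats_p10 = q[1],
    stats_p90 = q[5],
    stats_max = max(x),
    stats_iqr = q[4] - q[2],
    stats_range = max(x) - min(x),
    stats_mad = mean(abs(x - m)),
    stats_rmad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    stats_medad = mean(abs(x - q[3])),
    stats_cov = if (abs(m) > 0) sqrt(v) / m else 0,
    stats_qcd = if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0,
    stats_energy = sum(x^2),
    stats_rms = sqrt(mean(x^2)))
}

#' Intensity histogram features (25)
#'
#' Computed on the discretized bin indices: the standard histogram feature
#' set (moments, order statistics, mode, dispersion, entropy, uniformity,
#' histogram gradients) plus the 25th and 75th percentiles.  Entropy uses
#' log base 2; a single-bin ROI has entropy 0 and uniformity 1, and all
#' gradient features fall back to 0 / level 1.
#'
#' @param binned a `binned_roi` from [discretize()].
#' @return named numeric vector of 25 features (prefix `ih_`).
#' @export
ih_features <- function(binned) {
  b <- as.numeric(binned$levels[binned$mask])
  nb <- binned$n_bins
  cnt <- tabulate(binned$levels[binned$mask], nbins = nb)
  p <- cnt / sum(cnt)
  q <- stats::quantile(b, c(.10, .25, .5, .75, .90), names = FALSE)
  m <- mean(b)
  v <- pop_var(b)
  inner <- b[b >= q[1] & b <= q[5]]
  if (nb >= 2) {
    grad <- c(cnt[2] - cnt[1],
              if (nb > 2) (cnt[3:nb] - cnt[1:(nb - 2)]) / 2 else NULL,
              cnt[nb] - cnt[nb - 1])
  } else {
    grad <- 0
  }
  c(ih_mean = m,
    ih_var = v,
    ih_skewness = pop_skew(b),
    ih_kurtosis = pop_kurt_excess(b),
    ih_median = q[3],
    ih_min = min(b),
    ih_p10 = q[1],
    ih_p25 = q[2],
    ih_p75 = q[4],
    ih_p90 = q[5],
    ih_max = max(b),
    ih_mode = which.max(cnt),
    ih_iqr = q[4] - q[2],
    ih_range = max(b) - min(b),
    ih_mad = mean(abs(b - m)),
    ih_rmad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    ih_medad = mean(abs(b - q[3])),
    ih_cov = if (m > 0) sqrt(v) / m else 0,
    ih_qcd = (q[4] - q[2]) / (q[4] + q[2]),
    ih_entropy = -sum(p * log2p(p)),
    ih_uniformity = sum(p^2),
    ih_max_gradient = max(grad),
    ih_max_gradient_level = which.max(grad),
    ih_min_gradient = min(grad),
    ih_min_gradient_level = which.min(grad))
}

#' Local and global intensity peaks (2)
#'
#' Mean HU in a 1 cm^3 sphere (radius ~6.2 mm) centred on a voxel.  The
#' local peak is that mean at the highest-intensity in-mask voxel (if tied,
#' the largest mean among the tied voxels); the global peak is the maximum
#' of the spherical mean over all in-mask voxels.  The spherical mean uses
#' only voxels inside the image grid; if the sphere is clipped at the grid
#' boundary a warning is raised.
#'
#' @inheritParams stats_features
#' @return named numeric vector of 2 features (prefix `locint_`).
#' @export
local_intensity_features <- function(volume, mask) {
  check_same_grid(mask, volume, what = "mask")
  sp <- volume$spacing
  r_mm <- (3 / (4 * pi) * 1000)^(1 / 3)  # radius of a 1 cm^3 sphere
  half <- ceiling(r_mm / sp)
  kd <- 2L * as.integer(half) + 1L
  ax <- lapply(1:3, function(k) ((-half[k]):half[k]) * sp[k])
  KX <- array(rep(ax[[1]], times = kd[2] * kd[3]), dim = kd)
  KY <- array(rep(rep(ax[[2]], each = kd[1]), times = kd[3]), dim = kd)
  KZ <- array(rep(ax[[3]], each = kd[1] * kd[2]), dim = kd)
  kern <- array(as.numeric(KX^2 + KY^2 + KZ^2 <= r_mm^2), dim = kd)

  dims <- dim(volume$voxels)
  cr <- crop_to_mask(volume$voxels, mask$voxels, margin = max(half))
  sub <- cr$arr
  msub <- mask$voxels[cr$ranges[[1]], cr$ranges[[2]], cr$ranges[[3]],
                      drop = FALSE]
  # clipped if the sphere around any in-mask voxel would leave the grid
  idx <- which(msub, arr.ind = TRUE)
  grid_lo <- vapply(cr$ranges, min, numeric(1))
  clip <- FALSE
  for (k in 1:3) {
    lo_full <- grid_lo[k] + min(idx[, k]) - 1 - half[k]
    hi_full <- grid_lo[k] + max(idx[, k]) - 1 + half[k]
    if (lo_full < 1 || hi_full > dims[k]) clip <- TRUE
  }
  if (clip) {
    warning("intensity-peak sphere clipped at the image boundary",
            call. = FALSE)
  }
  num <- fft_convolve3(sub, kern)
  den <- fft_convolve3(array(1, dim = dim(sub)), kern)
  sph_mean <- num / den
  peak_map <- sph_mean[msub]
  vals <- sub[msub]
  top <- which(vals == max(vals))
  c(locint_peak_local = max(peak_map[top]),
    locint_peak_global = max(peak_map))
}
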