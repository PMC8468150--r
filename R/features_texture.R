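# Texture features computed from the matrices in texture_matrices.R.
# Degenerate single-bin ROIs yield documented convention values (0 for
# correlation-type quantities whose defining ratio is 0/0) instead of NaN,
# so extract_all() is total on any non-empty mask.

log2p <- function(p) ifelse(p > 0, log2(p), 0)

#' Gray level co-occurrence features (26)
#'
#' The 25 standard co-occurrence features (joint, difference and sum
#' statistics, homogeneity/contrast group, correlation group, information
#' correlations, cluster moments) plus the maximal correlation coefficient
#' as the 26th, computed from the merged-direction 3D matrix.
#'
#' @param binned a `binned_roi` from [discretize()].
#' @return named numeric vector of 26 features (prefix `glcm_`).
#' @export
glcm_features <- function(binned) {
  P <- glcm_matrix(binned, normalize = TRUE)
  nb <- nrow(P)
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  px <- rowSums(P)  # == colSums: P symmetric
  mu <- sum(seq_len(nb) * px)
  jvar <- sum((i - mu)^2 * P)
  # difference |i-j| = k (k = 0..nb-1) and sum i+j = k (k = 2..2nb)
  pdiff <- numeric(nb)
  psum <- numeric(2 * nb - 1)
  dd <- abs(i - j) + 1L
  ss <- i + j - 1L
  for (k in seq_len(nb)) pdiff[k] <- sum(P[dd == k])
  for (k in seq_len(2 * nb - 1)) psum[k] <- sum(P[ss == k])
  kd <- 0:(nb - 1)
  ks <- 2:(2 * nb)
  diff_avg <- sum(kd * pdiff)
  sum_avg <- sum(ks * psum)
  hx <- -sum(px * log2p(px))
  hxy <- -sum(P * log2p(P))
  pxpy <- px[row(P)] * px[col(P)]
  hxy1 <- -sum(P * log2p(matrix(pxpy, nb, nb)))
  hxy2 <- -sum(pxpy * log2p(pxpy))
  corr <- if (jvar > 0) sum((i - mu) * (j - mu) * P) / jvar else 0
  icorr1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  icorr2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  mcc <- glcm_mcc(P, px)
  c(glcm_joint_max = max(P),
    glcm_joint_avg = mu,
    glcm_joint_var = jvar,
    glcm_joint_entropy = hxy,
    glcm_diff_avg = diff_avg,
    glcm_diff_var = sum((kd - diff_avg)^2 * pdiff),
    glcm_diff_entropy = -sum(pdiff * log2p(pdiff)),
    glcm_sum_avg = sum_avg,
    glcm_sum_var = sum((ks - sum_avg)^2 * psum),
    glcm_sum_entropy = -sum(psum * log2p(psum)),
    glcm_energy = sum(P^2),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_inv_diff = sum(P / (1 + abs(i - j))),
    glcm_inv_diff_norm = sum(P / (1 + abs(i - j) / nb)),
    glcm_inv_diff_mom = sum(P / (1 + (i - j)^2)),
    glcm_inv_diff_mom_norm = sum(P / (1 + ((i - j) / nb)^2)),
    glcm_inv_var = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    glcm_correlation = corr,
    glcm_autocorrelation = sum(i * j * P),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    glcm_info_corr_1 = icorr1,
    glcm_info_corr_2 = icorr2,
    glcm_mcc = mcc)
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q[i,j] = sum_k P(i,k) P(j,k) / (px_i px_k), restricted to occurring
# levels.  Convention 0 for single-level ROIs.
glcm_mcc <- function(P, px) {
  keep <- px > 0
  if (sum(keep) < 2) return(0)
  Pk <- P[keep, keep, drop = FALSE]
  pk <- px[keep]
  Q <- (Pk / pk) %*% t(Pk / matrix(pk, nrow(Pk), ncol(Pk), byrow = TRUE))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmin(1, pmax(0, ev[2])))
}

#' Gray level run length features (15)
#'
#' Run emphasis, gray-level/run-length non-uniformity, run percentage,
#' variance and entropy features from the merged-direction run length
#' matrix.  Run percentage is normalized by voxels times the 13 directions
#' so it lies in (0, 1].
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 15 features (prefix `glrlm_`).
#' @export
glrlm_features <- function(binned) {
  R <- glrlm_matrix(binned)
  n_vox <- sum(binned$mask)
  rl_features(R, n_vox * 13, prefix = "glrlm_",
              names15 = c("sre", "lre", "lglre", "hglre", "srlgle",
                          "srhgle", "lrlgle", "lrhgle", "gln", "rln",
                          "rlnn", "run_pct", "glv", "rlv", "run_entropy"))
}

# Shared run-length-style feature kernel for GLRLM (lengths), GLSZM
# (sizes) and GLDZM (distances): matrix rows are gray levels, columns the
# second index.
rl_features <- function(M, denom_pct, prefix, names15) {
  Ns <- sum(M)
  i <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  l <- matrix(seq_len(ncol(M)), nrow(M), ncol(M), byrow = TRUE)
  p <- M / Ns
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  vals <- c(
    sum(M / l^2) / Ns,
    sum(M * l^2) / Ns,
    sum(M / i^2) / Ns,
    sum(M * i^2) / Ns,
    sum(M / (i^2 * l^2)) / Ns,
    sum(M * i^2 / l^2) / Ns,
    sum(M * l^2 / i^2) / Ns,
    sum(M * i^2 * l^2) / Ns,
    sum(rowSums(M)^2) / Ns,
    sum(colSums(M)^2) / Ns,
    sum(colSums(M)^2) / Ns^2,
    Ns / denom_pct,
    sum((i - mu_i)^2 * p),
    sum((l - mu_l)^2 * p),
    -sum(p * log2p(p))
  )
  stats::setNames(vals, paste0(prefix, names15))
}

#' Gray level size zone features (16)
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features (prefix `glszm_`).
#' @export
glszm_features <- function(binned) {
  S <- glszm_matrix(binned)
  n_vox <- sum(binned$mask)
  base <- rl_features(S, n_vox, prefix = "glszm_",
                      names15 = c("sze", "lze", "lglze", "hglze", "szlgle",
                                  "szhgle", "lzlgle", "lzhgle", "gln",
                                  "szn", "sznn", "zone_pct", "glv", "zsv",
                                  "zone_entropy"))
  c(base, glszm_glnn = sum(rowSums(S)^2) / sum(S)^2)
}

#' Gray level distance zone features (16)
#'
#' Same zone set as [glszm_features()] but indexed by the zone's Chebyshev
#' distance to the ROI border; includes the high-intensity large-distance
#' emphasis (`gldzm_ldhgle`).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features (prefix `gldzm_`).
#' @export
gldzm_features <- function(binned) {
  D <- gldzm_matrix(binned)
  n_vox <- sum(binned$mask)
  base <- rl_features(D, n_vox, prefix = "gldzm_",
                      names15 = c("sde", "lde", "lgle", "hgle", "sdlgle",
                                  "sdhgle", "ldlgle", "ldhgle", "gln",
                                  "zdn", "zdnn", "zone_pct", "glv", "zdv",
                                  "zd_entropy"))
  c(base, gldzm_glnn = sum(rowSums(D)^2) / sum(D)^2)
}

#' Neighbourhood gray tone difference features (5)
#'
#' Coarseness, contrast, busyness, complexity and strength.  Conventions
#' for degenerate ROIs: coarseness is capped at 1e6 when every voxel equals
#' its neighbourhood average; contrast, busyness, complexity and strength
#' are 0 when fewer than two gray levels occur.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features (prefix `ngtdm_`).
#' @export
ngtdm_features <- function(binned) {
  cmp <- ngtdm_components(binned)
  p <- cmp$p_i
  s <- cmp$s_i
  nv <- cmp$n_valid
  occ <- which(p > 0)
  ngp <- length(occ)
  ps_dot <- sum(p * s)
  coarseness <- if (ps_dot > 0) 1 / ps_dot else 1e6
  contrast <- 0
  busyness <- 0
  complexity <- 0
  strength <- 0
  if (ngp >= 2 && nv > 0) {
    ii <- occ[rep(seq_len(ngp), ngp)]
    jj <- occ[rep(seq_len(ngp), each = ngp)]
    pij2 <- p[ii] * p[jj] * (ii - jj)^2
    contrast <- sum(pij2) / (ngp * (ngp - 1)) * sum(s) / nv
    bden <- sum(abs(ii * p[ii] - jj * p[jj]))
    busyness <- if (bden > 0) ps_dot / bden else 0
    complexity <- sum(abs(ii - jj) *
                        (p[ii] * s[ii] + p[jj] * s[jj]) /
                        (p[ii] + p[jj])) / nv
    strength <- if (sum(s) > 0) sum((p[ii] + p[jj]) * (ii - jj)^2) /
      sum(s) else 0
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Neighbouring gray level dependence features (17)
#'
#' Dependence emphasis, gray-level and dependence-count non-uniformity,
#' variance, entropy and energy features from the dependence matrix with
#' coarseness parameter `a = 0`.  The column index used in the emphasis
#' weights is `dependence count + 1` so weights stay finite.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 17 features (prefix `ngldm_`).
#' @export
ngldm_features <- function(binned) {
  N <- ngldm_matrix(binned, a = 0L)
  Ns <- sum(N)
  i <- matrix(seq_len(nrow(N)), nrow(N), ncol(N))
  j <- matrix(seq_len(ncol(N)), nrow(N), ncol(N), byrow = TRUE)
  p <- N / Ns
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(ngldm_lde = sum(N / j^2) / Ns,
    ngldm_hde = sum(N * j^2) / Ns,
    ngldm_lglce = sum(N / i^2) / Ns,
    ngldm_hglce = sum(N * i^2) / Ns,
    ngldm_ldlgle = sum(N / (i^2 * j^2)) / Ns,
    ngldm_ldhgle = sum(N * i^2 / j^2) / Ns,
    ngldm_hdlgle = sum(N * j^2 / i^2) / Ns,
    ngldm_hdhgle = sum(N * i^2 * j^2) / Ns,
    ngldm_gln = sum(rowSums(N)^2) / Ns,
    ngldm_glnn = sum(rowSums(N)^2) / Ns^2,
    ngldm_dcn = sum(colSums(N)^2) / Ns,
    ngldm_dcnn = sum(colSums(N)^2) / Ns^2,
    ngldm_dc_pct = Ns / sum(binned$mask),
    ngldm_glv = sum((i - mu_i)^2 * p),
    ngldm_dcv = sum((j - mu_j)^2 * p),
    ngldm_dc_entropy = -sum(p * log2p(p)),
    ngldm_dc_energy = sum(p^2))
}
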