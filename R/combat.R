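#' Fit a location-scale ComBat batch model
#'
#' Implements empirical-Bayes ComBat (Johnson, Li & Rabinovic 2007) on a
#' feature table.  The generative model for feature value `Y_ij` of ROI `j`
#' in batch `i` is `Y_ij = alpha + beta X_ij + gamma_i + delta_i eps_ij`
#' with `eps ~ N(0, sigma^2)`: `alpha` the grand feature effect, `X` an
#' optional design of biological covariates, `gamma_i` an additive and
#' `delta_i` a multiplicative batch effect.
#'
#' Estimation: `alpha` and `beta` by least squares with batch indicators
#' constrained to a batch-size-weighted zero sum; each feature standardized
#' to zero mean and unit pooled variance; per-batch location
#' (`gamma_hat`) and scale (`delta_hat^2`) estimated on the standardized
#' data; normal (gamma) and inverse-gamma (delta^2) hyperpriors fitted
#' across features by method of moments; and posterior (shrunk) `gamma*`,
#' `delta*^2` obtained by the standard iterative conditional update
#' (tolerance 1e-4, max 500 iterations).  With `eb = FALSE` shrinkage is
#' skipped (the infinite-prior-variance limit), so the starred estimates
#' equal the raw per-batch estimates.
#'
#' @param table a feature table; every feature must have nonzero pooled
#'   variance (remove shape and near-zero-variance features first).
#' @param batch name of the batch column (default `"meta_batch"`); at
#'   least 2 batches with at least 2 rows each.
#' @param covariates optional character vector of covariate column names
#'   (numeric columns of `table`); default none.
#' @param eb apply empirical-Bayes shrinkage (default `TRUE`).
#' @return An object of class `combat_model`.
#' @references Johnson WE, Li C, Rabinovic A (2007). Adjusting batch
#'   effects in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @export
combat_fit <- function(table, batch = "meta_batch", covariates = NULL,
                       eb = TRUE) {
  table <- as_feature_table(table)
  if (!batch %in% names(table)) {
    stop("batch column `", batch, "` not found", call. = FALSE)
  }
  b <- factor(table[[batch]])
  if (nlevels(b) < 2) {
    stop("need at least 2 batches, got ", nlevels(b), call. = FALSE)
  }
  n_i <- table(b)
  if (any(n_i < 2)) {
    stop("batch(es) with fewer than 2 rows: ",
         paste(names(n_i)[n_i < 2], collapse = ", "), call. = FALSE)
  }
  feats <- setdiff(feature_columns(table), covariates)
  if (length(feats) < 2) {
    stop("need at least 2 features for empirical-Bayes estimation",
         call. = FALSE)
  }
  Y <- feature_matrix(table, feats)
  n <- nrow(Y)

  Xb <- stats::model.matrix(~ 0 + b)
  Xc <- NULL
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(table))
    if (length(miss)) {
      stop("covariate column(s) not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    Xc <- as.matrix(table[covariates])
  }
  X <- cbind(Xb, Xc)
  B <- solve(crossprod(X), crossprod(X, Y))
  nb <- nlevels(b)
  grand <- as.numeric(n_i / n) %*% B[seq_len(nb), , drop = FALSE]  # alpha
  stand_mean <- matrix(grand, n, length(feats), byrow = TRUE)
  if (!is.null(Xc)) {
    stand_mean <- stand_mean +
      Xc %*% B[-seq_len(nb), , drop = FALSE]
  }
  resid <- Y - X %*% B
  var_pooled <- colMeans(resid^2)
  zero_var <- feats[var_pooled <= .Machine$double.eps * 100]
  if (length(zero_var)) {
    stop("zero pooled variance feature(s): ",
         paste(zero_var, collapse = ", "),
         " (remove near-zero-variance features before harmonization)",
         call. = FALSE)
  }
  Z <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, length(feats),
                                 byrow = TRUE)

  gamma_hat <- rowsum(Z, b) / as.numeric(n_i)
  delta_hat2 <- matrix(NA_real_, nb, length(feats),
                       dimnames = list(levels(b), feats))
  for (k in seq_len(nb)) {
    Zi <- Z[b == levels(b)[k], , drop = FALSE]
    delta_hat2[k, ] <- apply(Zi, 2, stats::var)
  }
  if (any(delta_hat2 < 1e-8)) {
    warning("within-batch variance floored at 1e-8 x pooled variance for ",
            sum(delta_hat2 < 1e-8), " batch-feature cell(s)",
            call. = FALSE)
    delta_hat2 <- pmax(delta_hat2, 1e-8)
  }

  gamma_star <- gamma_hat
  delta_star2 <- delta_hat2
  hyper <- NULL
  iters <- integer(nb)
  if (eb) {
    gamma_bar <- rowMeans(gamma_hat)
    t2 <- apply(gamma_hat, 1, stats::var)
    a_prior <- apply(delta_hat2, 1, function(d) {
      m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
    })
    b_prior <- apply(delta_hat2, 1, function(d) {
      m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
    })
    for (k in seq_len(nb)) {
      Zi <- Z[b == levels(b)[k], , drop = FALSE]
      sol <- eb_iterate(Zi, gamma_hat[k, ], delta_hat2[k, ],
                        gamma_bar[k], t2[k], a_prior[k], b_prior[k])
      gamma_star[k, ] <- sol$gamma
      delta_star2[k, ] <- sol$delta2
      iters[k] <- sol$iterations
    }
    hyper <- tibble::tibble(batch = levels(b), gamma_bar = gamma_bar,
                            tau2 = t2, lambda = a_prior, theta = b_prior)
  }

  structure(list(
    batch_column = batch,
    batch_levels = levels(b),
    batch_sizes = as.integer(n_i),
    features = feats,
    covariates = covariates,
    alpha = stats::setNames(as.numeric(grand), feats),
    beta = if (!is.null(Xc)) B[-seq_len(nb), , drop = FALSE] else NULL,
    batch_coef = B[seq_len(nb), , drop = FALSE],
    var_pooled = var_pooled,
    gamma_hat = gamma_hat,
    delta_hat2 = delta_hat2,
    gamma_star = gamma_star,
    delta_star2 = delta_star2,
    hyperparameters = hyper,
    eb = eb,
    iterations = iters
  ), class = "combat_model")
}

# Iterative conditional EB update for one batch: posterior mean of gamma
# given delta2 and posterior mode-scale update of delta2 given gamma,
# until max relative change < 1e-4.
eb_iterate <- function(Zi, g_hat, d_hat2, g_bar, t2, a, b,
                       tol = 1e-4, max_iter = 500L) {
  n <- nrow(Zi)
  # degenerate hyperpriors (zero spread of the raw estimates across
  # features, e.g. duplicated batches): no information to shrink with, so
  # keep the raw scale estimates and the closed-form location posterior
  if (!is.finite(a) || !is.finite(b) || !is.finite(t2)) {
    g <- (t2 * n * g_hat + d_hat2 * g_bar) / (t2 * n + d_hat2)
    if (!is.finite(t2)) g <- g_hat
    return(list(gamma = g, delta2 = d_hat2, iterations = 0L))
  }
  g_old <- g_hat
  d_old <- d_hat2
  it <- 0L
  repeat {
    it <- it + 1L
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums((Zi - matrix(g_new, n, ncol(Zi), byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < tol || it >= max_iter) break
  }
  list(gamma = g_new, delta2 = d_new, iterations = it)
}

#' Apply a fitted ComBat model to a feature table
#'
#' Transforms every feature value as
#' `(Y - alpha - beta X - gamma*_i) / delta*_i + alpha + beta X` (working
#' on the pooled-variance-standardized scale), which removes the batch
#' location and scale effects while preserving the grand mean and any
#' covariate-predicted component.  Metadata columns pass through untouched.
#'
#' @param table a feature table containing the model's features and batch
#'   labels the model has seen.
#' @param model a `combat_model` from [combat_fit()].
#' @return the harmonized feature table (same shape and column order).
#' @export
combat_transform <- function(table, model) {
  table <- as_feature_table(table)
  stopifnot(inherits(model, "combat_model"))
  miss <- setdiff(model$features, names(table))
  if (length(miss)) {
    stop("feature mismatch; missing from table: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ...", call. = FALSE)
  }
  b <- as.character(table[[model$batch_column]])
  unseen <- setdiff(unique(b), model$batch_levels)
  if (length(unseen)) {
    stop("unseen batch label(s): ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  Y <- feature_matrix(table, model$features)
  n <- nrow(Y)
  p <- length(model$features)
  stand_mean <- matrix(model$alpha, n, p, byrow = TRUE)
  if (!is.null(model$covariates)) {
    Xc <- as.matrix(table[model$covariates])
    stand_mean <- stand_mean + Xc %*% model$beta
  }
  sd_pool <- matrix(sqrt(model$var_pooled), n, p, byrow = TRUE)
  Z <- (Y - stand_mean) / sd_pool
  bi <- match(b, model$batch_levels)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star2[bi, , drop = FALSE])
  out <- table
  out[model$features] <- tibble::as_tibble(Zadj * sd_pool + stand_mean)
  out
}

#' Fit and apply ComBat in one step
#'
#' The reference contrast-phase workflow: phase as batch, no covariates.
#'
#' @inheritParams combat_fit
#' @return list with elements `table` (harmonized feature table) and
#'   `model` (the fitted `combat_model`).
#' @export
combat_fit_transform <- function(table, batch = "meta_batch",
                                 covariates = NULL, eb = TRUE) {
  model <- combat_fit(table, batch = batch, covariates = covariates,
                      eb = eb)
  list(table = combat_transform(table, model), model = model)
}

#' @export
print.combat_model <- function(x, ...) {
  cat("<combat_model> ", length(x$features), " features, ",
      length(x$batch_levels), " batches (",
      paste(paste0(x$batch_levels, ": n=", x$batch_sizes),
            collapse = ", "), ")\n", sep = "")
  cat(if (x$eb) paste0("  empirical-Bayes shrinkage, ",
                       paste(x$iterations, collapse = "/"),
                       " iterations per batch\n")
      else "  no shrinkage (raw batch estimates)\n")
  invisible(x)
}

#' Tidy a ComBat model: one row per batch-feature pair
#'
#' @param x a `combat_model`.
#' @param ... unused.
#' @return tibble with the raw and shrunk location/scale estimates (on the
#'   standardized scale) and their data-scale additive counterpart
#'   `gamma_star_data = gamma_star * pooled sd`.
#' @export
tidy.combat_model <- function(x, ...) {
  nb <- length(x$batch_levels)
  p <- length(x$features)
  tibble::tibble(
    batch = rep(x$batch_levels, each = p),
    feature = rep(x$features, times = nb),
    gamma_hat = as.numeric(t(x$gamma_hat)),
    gamma_star = as.numeric(t(x$gamma_star)),
    delta_hat2 = as.numeric(t(x$delta_hat2)),
    delta_star2 = as.numeric(t(x$delta_star2)),
    gamma_star_data = as.numeric(t(x$gamma_star)) *
      rep(sqrt(x$var_pooled), times = nb)
  )
}

#' One-row summary of a ComBat model
#' @param x a `combat_model`.
#' @param ... unused.
#' @return tibble with feature/batch counts, shrinkage setting and the
#'   mean absolute shrunk batch shift.
#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    n_batches = length(x$batch_levels),
    n_rows = sum(x$batch_sizes),
    eb = x$eb,
    max_iterations = max(x$iterations),
    mean_abs_gamma_star = mean(abs(x$gamma_star))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
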