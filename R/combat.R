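#' Step 1: global location/scale parameters
#'
#' Fits, per CpG site, the additive model
#' `Y = alpha_g + X_cov' beta_g + gamma_ig + eps` by ordinary least squares
#' on the batch-indicator design (no intercept), then re-centres the batch
#' coefficients under the identifiability constraint
#' `sum_i n_i gamma_ig = 0`, which defines the global site mean `alpha_g`.
#' The site variance `sigma_g^2` is the mean squared residual with divisor
#' `N` (maximum-likelihood form).
#'
#' @param Y a `meth_matrix` of M-values (G sites x N samples).
#' @param design output of [build_design()] for the matching sample sheet.
#' @return a list with `global` (class `global_params`: `alpha`, `beta_cov`
#'   G x p, `sigma`, `sigma2`, `n_total`, `coding`) and `gamma_hat`
#'   (G x m batch offsets on the original M-value scale).
#' @export
estimate_global_params <- function(Y, design) {
  X <- design$X
  m <- length(design$batch_levels)
  p <- ncol(X) - m
  N <- nrow(X)
  G <- nrow(Y)
  if (ncol(Y) != N) stop("Y and design have mismatched sample counts")
  if (N <= m + p)
    stop("need more samples than model columns (N > m + p)")
  vals <- unclass(Y)
  # theta-hat = (X'X)^{-1} X'Y_g for all sites at once: (m+p) x G
  Bt <- solve(crossprod(X), crossprod(X, t(vals)))
  gamma_prime <- t(Bt[seq_len(m), , drop = FALSE])          # G x m
  beta_cov <- if (p > 0) t(Bt[m + seq_len(p), , drop = FALSE])
              else matrix(0, G, 0)
  w <- design$n_per_batch / N
  alpha <- as.vector(gamma_prime %*% w)
  gamma_hat <- gamma_prime - alpha                          # sums to 0 with weights n_i
  fitted <- t(X %*% Bt)                                     # alpha + gamma + X'beta
  sigma2 <- rowMeans((vals - fitted)^2)
  if (any(sigma2 <= 0))
    stop("site(s) with zero residual variance: ",
         paste(utils::head(rownames(Y)[sigma2 <= 0], 10L), collapse = ", "))
  rownames(beta_cov) <- rownames(Y)
  colnames(beta_cov) <- colnames(X)[m + seq_len(p)]
  colnames(gamma_hat) <- design$batch_levels
  rownames(gamma_hat) <- rownames(Y)
  global <- structure(list(alpha = stats::setNames(alpha, rownames(Y)),
                           beta_cov = beta_cov,
                           sigma = sqrt(sigma2), sigma2 = sigma2,
                           n_total = N, coding = design$coding),
                      class = "global_params")
  list(global = global, gamma_hat = gamma_hat)
}

# Covariate contribution X_cov' beta_g for every (site, sample) cell; zero
# matrix when there are no covariates.
covariate_term <- function(global, X_cov, n_samples) {
  if (ncol(global$beta_cov) == 0L)
    return(matrix(0, length(global$alpha), n_samples))
  global$beta_cov %*% t(X_cov)
}

#' Step 2 (first half): standardize data with the global parameters
#'
#' `Z = (Y - alpha_g - X_cov' beta_g) / sigma_g` elementwise by site.  Note
#' that the estimated batch offsets are deliberately not subtracted: the
#' batch structure remaining in `Z` is what the empirical-Bayes step
#' shrinks and removes.
#'
#' @inheritParams estimate_global_params
#' @param global a `global_params` object from [estimate_global_params()].
#' @param X_cov coded covariate matrix (N x p) for the samples of `Y`.
#' @return numeric matrix `Z` of the same dimension as `Y`.
#' @export
standardize_mvalues <- function(Y, global, X_cov) {
  vals <- unclass(Y)
  if (length(global$alpha) != nrow(vals))
    stop("site count of Y does not match the global parameters")
  if (!is.null(rownames(vals)) &&
      !identical(rownames(vals), names(global$alpha)))
    stop("site IDs of Y do not match the global parameters")
  (vals - global$alpha - covariate_term(global, X_cov, ncol(vals))) / global$sigma
}

#' Step 2 (second half): method-of-moments hyperpriors for one batch
#'
#' Moment-matches the hierarchical priors `gamma_ig ~ N(gamma_bar, tau2)`
#' and `delta_ig^2 ~ InvGamma(zeta_bar, theta_bar)` to the per-site batch
#' estimates: `zeta_bar = a^2/s^2 + 2` and `theta_bar = a (a^2/s^2 + 1)`
#' where `a` and `s^2` are the mean and variance of the `delta2_hat`
#' values across sites.
#'
#' @param gamma_hat per-site batch mean offsets (standardized scale).
#' @param delta2_hat per-site batch variances (standardized scale, divisor
#'   `n_i - 1`), or `NULL` in mean-only mode.
#' @return a `hyperpriors` object: `gamma_bar`, `tau2_bar`, `zeta_bar`,
#'   `theta_bar`, plus the audit quantities `a` and `s2`.
#' @export
estimate_hyperpriors <- function(gamma_hat, delta2_hat = NULL) {
  G <- length(gamma_hat)
  if (G < 2L) stop("need at least two sites to moment-match hyperpriors")
  gamma_bar <- mean(gamma_hat)
  tau2_bar <- stats::var(gamma_hat)
  if (is.null(delta2_hat)) {
    hp <- list(gamma_bar = gamma_bar, tau2_bar = tau2_bar,
               zeta_bar = NA_real_, theta_bar = NA_real_,
               a = NA_real_, s2 = NA_real_)
    return(structure(hp, class = "hyperpriors"))
  }
  if (any(delta2_hat <= 0)) stop("delta2_hat must be strictly positive")
  a <- mean(delta2_hat)
  s2 <- stats::var(delta2_hat)
  if (s2 == 0)
    stop("all per-site batch variances identical (s2 = 0): the ",
         "inverse-gamma prior is degenerate; use mean_only or jitter")
  structure(list(gamma_bar = gamma_bar, tau2_bar = tau2_bar,
                 zeta_bar = a^2 / s2 + 2, theta_bar = a * (a^2 / s2 + 1),
                 a = a, s2 = s2),
            class = "hyperpriors")
}

#' Step 2 (second half): empirical-Bayes batch-effect estimates
#'
#' Solves, per site, the coupled fixed-point equations
#' \deqn{\gamma^* = (n \bar\tau^2 \hat\gamma + \delta^{2*} \bar\gamma) /
#'       (n \bar\tau^2 + \delta^{2*})}
#' \deqn{\delta^{2*} = (\bar\theta + \sum_j (Z_j - \gamma^*)^2 / 2) /
#'       (n/2 + \bar\zeta - 1)}
#' by alternating updates, initialised at the raw per-site estimates, until
#' the maximum relative change of both vectors falls below `tol`.  In
#' mean-only mode the variance is not modelled: `gamma_star` is computed in
#' one pass with `delta2_hat` held fixed in its update and `delta2_star` is
#' identically 1.
#'
#' @param Z_i standardized-data slice for the batch (G sites x n_i samples).
#' @param hyperpriors a `hyperpriors` object for this batch.
#' @param gamma_hat,delta2_hat per-site raw batch estimates on the
#'   standardized scale (`delta2_hat` may be `NULL` in mean-only mode and
#'   is then treated as 1 in the `gamma_star` update).
#' @param mean_only logical; skip the variance fixed point.
#' @param tol convergence tolerance on the maximum relative change.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   worst-site residual.
#' @return list with `gamma_star`, `delta2_star`, `iterations`.
#' @export
eb_batch_estimates <- function(Z_i, hyperpriors, gamma_hat, delta2_hat = NULL,
                               mean_only = FALSE, tol = 1e-4, max_iter = 500L) {
  stopifnot(tol > 0)
  n <- ncol(Z_i)
  t2 <- hyperpriors$tau2_bar
  g_bar <- hyperpriors$gamma_bar
  if (mean_only) {
    d2 <- if (is.null(delta2_hat)) rep(1, length(gamma_hat)) else delta2_hat
    gamma_star <- (n * t2 * gamma_hat + d2 * g_bar) / (n * t2 + d2)
    return(list(gamma_star = gamma_star,
                delta2_star = rep(1, length(gamma_hat)),
                iterations = 0L))
  }
  if (n < 2L) stop("empirical-Bayes variance estimation needs n_i >= 2")
  zeta <- hyperpriors$zeta_bar
  theta <- hyperpriors$theta_bar
  sZ <- rowSums(Z_i)
  sZ2 <- rowSums(Z_i^2)
  g_old <- gamma_hat
  d_old <- delta2_hat
  for (iter in seq_len(max_iter)) {
    g_new <- (n * t2 * gamma_hat + d_old * g_bar) / (n * t2 + d_old)
    sum2 <- pmax(sZ2 - 2 * g_new * sZ + n * g_new^2, 0)
    d_new <- (theta + sum2 / 2) / (n / 2 + zeta - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    g_old <- g_new
    d_old <- d_new
    if (change < tol)
      return(list(gamma_star = g_new, delta2_star = d_new,
                  iterations = iter))
  }
  resid <- max(abs(g_new - (n * t2 * gamma_hat + d_new * g_bar) /
                     (n * t2 + d_new)))
  stop(sprintf(paste0("empirical-Bayes updates did not converge in %d ",
                      "iterations (worst-site residual %.3g)"),
               max_iter, resid))
}

#' Step 3: correct standardized data back to the M-value scale
#'
#' `Y* = sigma_g / delta*_ig * (Z - gamma*_ig) + alpha_g + X_cov' beta_g`,
#' where `delta* = sqrt(delta2_star)` (1 in mean-only mode).
#'
#' @param Z standardized matrix (G x N).
#' @param batch factor of batch labels per sample (column of `Z`).
#' @param batches named list of per-batch parameter sets, each containing
#'   `gamma_star` and `delta2_star` per site.
#' @param global a `global_params` object.
#' @param X_cov coded covariate matrix for the samples.
#' @param site_ids,sample_ids identifiers for the output matrix.
#' @return a `meth_matrix` of corrected M-values.
#' @export
apply_correction <- function(Z, batch, batches, global, X_cov,
                             site_ids = rownames(Z),
                             sample_ids = colnames(Z)) {
  batch <- as.factor(batch)
  unknown <- setdiff(levels(droplevels(batch)), names(batches))
  if (length(unknown))
    stop("no batch parameters for batch label(s): ",
         paste(unknown, collapse = ", "))
  out <- matrix(NA_real_, nrow(Z), ncol(Z))
  for (lab in levels(droplevels(batch))) {
    idx <- which(batch == lab)
    bp <- batches[[lab]]
    delta_star <- sqrt(bp$delta2_star)
    out[, idx] <- (Z[, idx, drop = FALSE] - bp$gamma_star) *
      (global$sigma / delta_star)
  }
  out <- out + global$alpha + covariate_term(global, X_cov, ncol(Z))
  meth_matrix(out, scale = "M", site_ids = site_ids, sample_ids = sample_ids)
}

#' Fit the location/scale batch-correction model and correct the data
#'
#' Runs the full three-step procedure on a matrix of M-values: (1) per-site
#' OLS of the data on batch indicators and biological covariates under the
#' constraint `sum_i n_i gamma_ig = 0`, giving the global site mean,
#' covariate coefficients and pooled standard deviation; (2)
#' standardization, method-of-moments hyperpriors per batch, and the
#' empirical-Bayes fixed point for the per-site batch location
#' (`gamma_star`) and scale (`delta2_star`); (3) correction of every sample
#' back to the M-value scale with its batch's shrunken parameters.
#'
#' The returned model object freezes everything a later incremental run
#' needs (global parameters, covariate coding, per-batch estimates) and can
#' be serialized losslessly with [write_icombat_model()].
#'
#' @param Y a `meth_matrix` of M-values (G sites x N samples).  Columns
#'   must correspond to the samples of `sheet` (any order; they are matched
#'   by ID).
#' @param sheet a [sample_sheet()] with batch labels and the biological
#'   covariates to protect.
#' @param mean_only correct only batch means (`delta* = 1`); use when
#'   within-batch variance estimation is unstable (very small batches).
#' @param tol,max_iter empirical-Bayes convergence controls.
#' @param drop_zero_variance drop sites whose values are constant instead
#'   of erroring.
#' @return a list with `corrected` (a `meth_matrix`, same sample order as
#'   `Y`) and `model` (an `icombat_model`).
#' @export
combat_fit <- function(Y, sheet, mean_only = FALSE, tol = 1e-4,
                       max_iter = 500L, drop_zero_variance = FALSE) {
  if (!is_meth_matrix(Y)) Y <- meth_matrix(as.matrix(Y), scale = "M")
  if (meth_scale(Y) != "M")
    stop("correction operates on M-values; convert with mvalue_from_beta()")
  if (!setequal(colnames(Y), sheet$sample_ids))
    stop("sample IDs of the matrix and the sample sheet differ")
  ord <- match(colnames(Y), sheet$sample_ids)
  sheet <- sample_sheet(sheet$sample_ids[ord], sheet$batch[ord],
                        if (is.null(sheet$covariates)) NULL
                        else sheet$covariates[ord, , drop = FALSE],
                        coding = sheet$coding)
  const <- apply(unclass(Y), 1L, function(x) max(x) == min(x))
  if (any(const)) {
    if (!drop_zero_variance)
      stop(sum(const), " zero-variance site(s): ",
           paste(utils::head(rownames(Y)[const], 10L), collapse = ", "),
           " (set drop_zero_variance = TRUE to drop them)")
    message("dropping ", sum(const), " zero-variance site(s)")
    Y <- Y[!const, ]
  }
  n_per <- table(sheet$batch)
  min_n <- if (mean_only) 1L else 2L
  if (any(n_per < min_n))
    stop("batch(es) with fewer than ", min_n, " samples: ",
         paste(names(n_per)[n_per < min_n], collapse = ", "),
         if (!mean_only) " (mean_only = TRUE accepts single-sample batches)")
  design <- build_design(sheet)
  step1 <- estimate_global_params(Y, design)
  global <- step1$global
  Z <- standardize_mvalues(Y, global, design$X_cov)
  batches <- list()
  for (k in seq_along(design$batch_levels)) {
    lab <- design$batch_levels[k]
    idx <- which(sheet$batch == lab)
    n_i <- length(idx)
    Z_i <- Z[, idx, drop = FALSE]
    gamma_hat_i <- rowMeans(Z_i)  # equals step-1 gamma_hat / sigma
    delta2_hat_i <- if (n_i >= 2L)
      rowSums((Z_i - gamma_hat_i)^2) / (n_i - 1) else NULL
    hp <- estimate_hyperpriors(gamma_hat_i,
                               if (mean_only) NULL else delta2_hat_i)
    eb <- eb_batch_estimates(Z_i, hp, gamma_hat_i, delta2_hat_i,
                             mean_only = mean_only, tol = tol,
                             max_iter = max_iter)
    batches[[lab]] <- list(label = lab, n = n_i, hyperpriors = hp,
                           gamma_hat = gamma_hat_i,
                           delta2_hat = delta2_hat_i,
                           gamma_star = eb$gamma_star,
                           delta2_star = eb$delta2_star,
                           eb_iterations = eb$iterations)
  }
  corrected <- apply_correction(Z, sheet$batch, batches, global,
                                design$X_cov, site_ids = rownames(Y),
                                sample_ids = colnames(Y))
  model <- structure(list(version = "1.0",
                          site_ids = rownames(Y),
                          covariate_coding = sheet$coding,
                          mean_only = mean_only,
                          options = list(tol = tol,
                                         max_iter = as.integer(max_iter)),
                          global = global,
                          batches = batches),
                     class = "icombat_model")
  list(corrected = corrected, model = model)
}

#' @export
print.icombat_model <- function(x, ...) {
  cat(sprintf(paste0("icombat_model: %d sites, %d batch(es) [%s], ",
                     "%d covariate column(s)%s\n"),
              length(x$site_ids), length(x$batches),
              paste(names(x$batches), collapse = ", "),
              ncol(x$global$beta_cov),
              if (isTRUE(x$mean_only)) ", mean-only" else ""))
  invisible(x)
}
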