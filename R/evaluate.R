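#' Per-site group association test with age adjustment
#'
#' For every site, ordinary least squares of the methylation values on
#' `(intercept, group, age)` and a two-sided t-test of the group
#' coefficient on `N - 3` degrees of freedom.  Vectorised across sites via
#' the shared design.
#'
#' @param Y a `meth_matrix` (or numeric matrix), sites x samples.
#' @param group 0/1 vector per sample.
#' @param age numeric vector per sample.
#' @return a list (`site_test`): `p_values`, `t_stats`, `coef` (group
#'   coefficient per site), `df`, `target_coef = "group"`.
#' @export
site_regression <- function(Y, group, age) {
  vals <- unclass(as.matrix(Y))
  N <- ncol(vals)
  if (length(group) != N || length(age) != N)
    stop("group/age length must match the number of samples")
  if (N <= 3L) stop("need more than 3 samples for the 3-parameter model")
  if (length(unique(group)) < 2L) stop("group is constant")
  if (length(unique(age)) < 2L) stop("age is constant")
  D <- cbind(intercept = 1, group = as.numeric(group), age = as.numeric(age))
  DtD_inv <- solve(crossprod(D))
  coefs <- vals %*% D %*% DtD_inv            # G x 3
  resid <- vals - coefs %*% t(D)
  df <- N - 3L
  s2 <- rowSums(resid^2) / df
  se <- sqrt(s2 * DtD_inv["group", "group"])
  t_stats <- coefs[, "group"] / se
  p <- 2 * stats::pt(abs(t_stats), df = df, lower.tail = FALSE)
  list(p_values = p, t_stats = t_stats, coef = coefs[, "group"],
       df = df, target_coef = "group")
}

#' True- and false-positive rates at a significance level
#'
#' @param result a `site_test` from [site_regression()] (or a bare p-value
#'   vector).
#' @param truth_signal logical per site; `TRUE` marks true positives.
#' @param alpha significance level.
#' @return list with `tpr` and `fpr`.
#' @export
tpr_fpr <- function(result, truth_signal, alpha = 0.05) {
  p <- if (is.list(result)) result$p_values else result
  if (length(p) != length(truth_signal))
    stop("p-values and truth vector have different lengths")
  if (!any(truth_signal) || all(truth_signal))
    stop("both truth strata must be non-empty")
  sig <- p < alpha
  list(tpr = mean(sig[truth_signal]), fpr = mean(sig[!truth_signal]))
}

#' Genomic-control inflation factor
#'
#' Converts each p-value to the matching chi-square(1) quantile and
#' divides the median by the chi-square(1) median (~0.4549); lambda of 1
#' indicates a well-calibrated null, values above 1 indicate inflation
#' from unmodelled structure such as batch.
#'
#' @param p_values vector of p-values in (0, 1]; exact zeros are mapped to
#'   the largest finite quantile with a warning.
#' @return lambda (positive scalar).
#' @export
gc_lambda <- function(p_values) {
  p <- if (is.list(p_values)) p_values$p_values else p_values
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-values of exactly 0 mapped to the largest finite quantile")
    p[p == 0] <- 1e-300
  }
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Pearson correlation between two matrices, cell by cell
#'
#' @param Y1,Y2 matrices of identical dimension (and IDs, when present).
#' @param max_cells optional cap: when the matrices hold more cells, a
#'   seeded random subsample of this size is used.
#' @param seed seed for the subsample.
#' @return Pearson correlation of the paired cells.
#' @export
pairwise_correlation <- function(Y1, Y2, max_cells = NULL, seed = 1L) {
  v1 <- unclass(as.matrix(Y1)); v2 <- unclass(as.matrix(Y2))
  if (!identical(dim(v1), dim(v2))) stop("matrices have different dimensions")
  if (!is.null(rownames(v1)) && !is.null(rownames(v2)) &&
      !identical(dimnames(v1), dimnames(v2)))
    stop("matrix IDs differ")
  x <- as.vector(v1); y <- as.vector(v2)
  if (!is.null(max_cells) && length(x) > max_cells) {
    set.seed(as.integer(seed))
    idx <- sample.int(length(x), max_cells)
    x <- x[idx]; y <- y[idx]
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  stats::cor(x, y)
}

#' PCA embedding of samples
#'
#' Site-centred singular value decomposition; returns the sample scores on
#' the leading components with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param Y a `meth_matrix` (or matrix), sites x samples.
#' @param k number of components.
#' @param n_top_sites optionally restrict to the most variable sites.
#' @return N x k matrix of scores; proportion of variance explained in
#'   attribute `"var_explained"`.
#' @export
pca_embed <- function(Y, k = 3L, n_top_sites = NULL) {
  vals <- unclass(as.matrix(Y))
  if (!is.null(n_top_sites) && n_top_sites < nrow(vals)) {
    v <- apply(vals, 1L, stats::var)
    vals <- vals[order(v, decreasing = TRUE)[seq_len(n_top_sites)], ,
                 drop = FALSE]
  }
  if (k > min(dim(vals))) stop("k exceeds matrix rank bound")
  Xc <- vals - rowMeans(vals)
  sv <- svd(Xc)
  pos <- sum(sv$d > sv$d[1L] * 1e-12)
  if (pos < k) {
    warning("rank ", pos, " < k; returning ", pos, " component(s)")
    k <- pos
  }
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(u[, j]))
    if (u[i0, j] < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  scores <- sweep(v, 2L, sv$d[seq_len(k)], `*`)
  dimnames(scores) <- list(colnames(vals), paste0("PC", seq_len(k)))
  attr(scores, "var_explained") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  scores
}

#' Count surrogate variables by permutation parallel analysis
#'
#' Residualises the data on the biological design, then compares the
#' ordered eigenvalue proportions of the residual matrix with those of
#' matrices whose rows are independently permuted (which destroys
#' cross-site structure while keeping each site's marginal distribution).
#' The count is the number of leading components whose proportion exceeds
#' the permutation distribution at level `alpha` (with the component-wise
#' p-values made monotone).
#'
#' @param Y a `meth_matrix` (or matrix), sites x samples.
#' @param design_bio N x q design of known biological covariates
#'   (including an intercept column).
#' @param n_perm number of permutations.
#' @param alpha significance level per component.
#' @param seed seed for the permutations.
#' @return integer count of surrogate variables.
#' @export
num_sv <- function(Y, design_bio, n_perm = 20L, alpha = 0.10, seed = 1L) {
  vals <- unclass(as.matrix(Y))
  D <- as.matrix(design_bio)
  N <- ncol(vals)
  if (nrow(D) != N) stop("design rows must match sample count")
  if (N <= ncol(D) + 2L) stop("too few samples for surrogate estimation")
  H <- D %*% solve(crossprod(D), t(D))
  R <- vals - vals %*% H
  n_comp <- N - ncol(D)
  dstat <- function(M) {
    d2 <- svd(M, nu = 0, nv = 0)$d^2
    (d2 / sum(d2))[seq_len(n_comp)]
  }
  obs <- dstat(R)
  set.seed(as.integer(seed))
  exceed <- numeric(n_comp)
  for (b in seq_len(n_perm)) {
    Rp <- t(apply(R, 1L, sample))
    Rp <- Rp - Rp %*% H
    exceed <- exceed + (dstat(Rp) >= obs)
  }
  psv <- cummax((exceed + 1) / (n_perm + 1))
  sum(psv <= alpha)
}

#' Run the simulation benchmark for one scenario
#'
#' For each replicate: draw a dataset, correct the existing batches
#' jointly, correct each new batch incrementally against the frozen model,
#' and separately correct all batches jointly; then run the per-site group
#' test (age-adjusted) on the raw, jointly corrected, and incrementally
#' corrected data and summarise TPR, FPR and the genomic-control factor.
#' Also records the per-replicate correlation between the two corrected
#' matrices and verifies that re-deriving the existing batches' corrected
#' values from the grown model reproduces them exactly (maximum absolute
#' change, expected 0).
#'
#' Replicates whose random draw yields a degenerate design (e.g. a
#' constant group) are resampled with a fresh child seed and counted.
#'
#' @param scenario_id scenario identifier in [scenario_registry()].
#' @param n_reps number of replicates.
#' @param master_seed master seed; replicate r uses a deterministic child
#'   seed derived from `(master_seed, scenario, r)`.
#' @param alpha significance level of the site test.
#' @param compute_nsv also compute the surrogate-variable count per method
#'   (slower).
#' @return a data.frame with one row per method (`raw`, `combat`,
#'   `icombat`) and columns `tpr`, `fpr`, `gc_lambda` (and `n_sv` when
#'   requested), plus attributes `corr_combat_icombat`,
#'   `zero_change_max`, `n_resampled`, `n_reps`, `scenario`.
#' @export
run_experiment <- function(scenario_id, n_reps = 20L, master_seed = 1L,
                           alpha = 0.05, compute_nsv = FALSE) {
  reg <- scenario_registry()
  if (!scenario_id %in% names(reg)) stop("unknown scenario: ", scenario_id)
  scenario <- reg[[scenario_id]]
  s_idx <- match(scenario_id, names(reg))
  methods <- c("raw", "combat", "icombat")
  acc <- array(NA_real_, dim = c(n_reps, 3L, 4L),
               dimnames = list(NULL, methods,
                               c("tpr", "fpr", "gc_lambda", "n_sv")))
  corr <- numeric(n_reps)
  zero_change <- numeric(n_reps)
  n_resampled <- 0L
  for (r in seq_len(n_reps)) {
    rep_res <- NULL
    for (attempt in 0:49) {
      seed_r <- child_seed(master_seed, s_idx, r, attempt)
      rep_res <- tryCatch(
        run_replicate(scenario, seed_r, alpha, compute_nsv),
        error = function(e) {
          message("replicate ", r, " resampled (", conditionMessage(e), ")")
          NULL
        })
      if (!is.null(rep_res)) break
      n_resampled <- n_resampled + 1L
    }
    if (is.null(rep_res))
      stop("replicate ", r, " failed after repeated resampling")
    acc[r, , ] <- rep_res$metrics
    corr[r] <- rep_res$corr
    zero_change[r] <- rep_res$zero_change
  }
  means <- apply(acc, c(2L, 3L), mean)
  out <- data.frame(method = methods,
                    tpr = means[, "tpr"], fpr = means[, "fpr"],
                    gc_lambda = means[, "gc_lambda"],
                    row.names = NULL)
  if (compute_nsv) out$n_sv <- means[, "n_sv"]
  attr(out, "corr_combat_icombat") <- mean(corr)
  attr(out, "zero_change_max") <- max(zero_change)
  attr(out, "n_resampled") <- n_resampled
  attr(out, "n_reps") <- as.integer(n_reps)
  attr(out, "scenario") <- scenario_id
  out
}

run_replicate <- function(scenario, seed, alpha = 0.05,
                          compute_nsv = FALSE) {
  ds <- simulate_methylation(scenario, seed)
  parts <- split_existing_new(ds)
  fit_existing <- combat_fit(parts$existing$Y, parts$existing$sheet)
  inc <- icombat_correct_many(parts$new, fit_existing$model)
  icombat_mat <- cbind(unclass(fit_existing$corrected),
                       do.call(cbind, lapply(inc$corrected, unclass)))
  icombat_mat <- icombat_mat[, colnames(ds$Y)]
  fit_all <- combat_fit(ds$Y, ds$sheet)
  combat_mat <- unclass(fit_all$corrected)[, colnames(ds$Y)]

  # immutability check: re-derive the existing batches' corrected values
  # from the grown model (stored globals + stored batch parameters)
  model_out <- inc$model
  ex <- parts$existing
  X_cov_ex <- code_covariates(ex$sheet$covariates, model_out$covariate_coding)
  Z_ex <- standardize_mvalues(ex$Y, model_out$global, X_cov_ex)
  redone <- apply_correction(Z_ex, ex$sheet$batch, model_out$batches,
                             model_out$global, X_cov_ex)
  zero_change <- max(abs(unclass(redone) - unclass(fit_existing$corrected)))

  group <- ds$sheet$covariates$group
  age <- ds$sheet$covariates$age
  mats <- list(raw = unclass(ds$Y), combat = combat_mat,
               icombat = icombat_mat)
  metrics <- matrix(NA_real_, 3L, 4L,
                    dimnames = list(names(mats),
                                    c("tpr", "fpr", "gc_lambda", "n_sv")))
  for (meth in names(mats)) {
    st <- site_regression(mats[[meth]], group, age)
    rates <- tpr_fpr(st, ds$truth_signal, alpha = alpha)
    metrics[meth, "tpr"] <- rates$tpr
    metrics[meth, "fpr"] <- rates$fpr
    metrics[meth, "gc_lambda"] <- gc_lambda(st)
    if (compute_nsv)
      metrics[meth, "n_sv"] <- num_sv(mats[[meth]],
                                      cbind(1, group, age), seed = seed)
  }
  list(metrics = metrics,
       corr = pairwise_correlation(combat_mat, icombat_mat),
       zero_change = zero_change)
}
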