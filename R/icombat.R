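#' Correct a newly measured batch against a frozen model
#'
#' Incremental correction: the new batch is standardized with the stored
#' global parameters (`alpha`, `beta_cov`, `sigma` — never re-estimated),
#' its own per-site location/scale estimates and method-of-moments
#' hyperpriors are computed from the new samples alone, the empirical-Bayes
#' fixed point is solved exactly as in [combat_fit()], and the corrected
#' values are mapped back onto the scale of the existing corrected data.
#' Because no stored parameter is touched, data corrected in earlier runs
#' are bit-identical before and after the addition; the model grows by one
#' appended batch-parameter block.
#'
#' The per-site batch location for the new batch is the within-batch mean
#' of the standardized values — the exact analogue of the constrained OLS
#' offset in the original fit (the two coincide for batches present at fit
#' time).
#'
#' @param Y_new a `meth_matrix` of M-values for the new batch.  Rows are
#'   matched to the model's sites by ID (any order).
#' @param sheet_new a [sample_sheet()] for the new samples: a single batch
#'   label not already in the model, with covariates expressible in the
#'   model's stored coding (unseen factor levels are an error).
#' @param model an `icombat_model` from [combat_fit()] or a previous
#'   incremental run.
#' @param intersect_sites if `TRUE`, sites present in `Y_new` but unknown
#'   to the model are dropped with a warning; sites required by the model
#'   must always be present.
#' @return a list with `corrected` (a `meth_matrix` for the new samples)
#'   and `model` (the input model with one appended batch).
#' @export
icombat_correct <- function(Y_new, sheet_new, model, intersect_sites = FALSE) {
  stopifnot(inherits(model, "icombat_model"))
  if (!is_meth_matrix(Y_new)) Y_new <- meth_matrix(as.matrix(Y_new), scale = "M")
  if (meth_scale(Y_new) != "M")
    stop("incremental correction operates on M-values")
  if (nlevels(droplevels(sheet_new$batch)) != 1L)
    stop("a new batch must carry exactly one batch label")
  label <- as.character(droplevels(sheet_new$batch)[1L])
  if (label %in% names(model$batches))
    stop("batch label '", label, "' already present in the model")
  if (!setequal(colnames(Y_new), sheet_new$sample_ids))
    stop("sample IDs of the new matrix and sample sheet differ")

  missing_sites <- setdiff(model$site_ids, rownames(Y_new))
  if (length(missing_sites))
    stop(length(missing_sites), " model site(s) absent from the new batch, ",
         "e.g. ", paste(utils::head(missing_sites, 5L), collapse = ", "))
  extra <- setdiff(rownames(Y_new), model$site_ids)
  if (length(extra)) {
    if (!intersect_sites)
      stop(length(extra), " site(s) in the new batch are unknown to the ",
           "model (set intersect_sites = TRUE to drop them)")
    warning("dropping ", length(extra), " site(s) unknown to the model")
  }
  Y_new <- Y_new[model$site_ids, ]

  ord <- match(colnames(Y_new), sheet_new$sample_ids)
  covs <- if (is.null(sheet_new$covariates)) NULL
          else sheet_new$covariates[ord, , drop = FALSE]
  X_cov <- code_covariates(covs, model$covariate_coding)
  n_i <- ncol(Y_new)
  min_n <- if (isTRUE(model$mean_only)) 1L else 2L
  if (n_i < min_n)
    stop("new batch needs at least ", min_n, " sample(s)",
         if (!isTRUE(model$mean_only)) " (or a mean_only model)")

  Z <- standardize_mvalues(Y_new, model$global, X_cov)
  gamma_hat <- rowMeans(Z)
  delta2_hat <- if (n_i >= 2L) rowSums((Z - gamma_hat)^2) / (n_i - 1) else NULL
  hp <- estimate_hyperpriors(gamma_hat,
                             if (isTRUE(model$mean_only)) NULL else delta2_hat)
  eb <- eb_batch_estimates(Z, hp, gamma_hat, delta2_hat,
                           mean_only = isTRUE(model$mean_only),
                           tol = model$options$tol,
                           max_iter = model$options$max_iter)
  new_bp <- list(label = label, n = n_i, hyperpriors = hp,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 gamma_star = eb$gamma_star, delta2_star = eb$delta2_star,
                 eb_iterations = eb$iterations)
  corrected <- apply_correction(Z, factor(rep(label, n_i)),
                                stats::setNames(list(new_bp), label),
                                model$global, X_cov,
                                site_ids = model$site_ids,
                                sample_ids = colnames(Y_new))
  model$batches[[label]] <- new_bp
  list(corrected = corrected, model = model)
}

#' Correct several new batches sequentially
#'
#' Folds [icombat_correct()] over an ordered list of new batches.  Each
#' batch's empirical-Bayes estimation uses only its own samples plus the
#' frozen global parameters, so batches already added are never revisited
#' and each corrected matrix is independent of later additions (and of the
#' addition order).
#'
#' @param new_batches list of new batches, each a list with elements `Y`
#'   (a `meth_matrix`) and `sheet` (a [sample_sheet()]).
#' @inheritParams icombat_correct
#' @return a list with `corrected` (named list of corrected matrices, one
#'   per batch) and `model` (with all batches appended).
#' @export
icombat_correct_many <- function(new_batches, model, intersect_sites = FALSE) {
  labels <- vapply(new_batches,
                   function(b) as.character(droplevels(b$sheet$batch)[1L]),
                   character(1))
  if (anyDuplicated(labels))
    stop("duplicate batch labels among the new batches")
  corrected <- list()
  for (k in seq_along(new_batches)) {
    res <- icombat_correct(new_batches[[k]]$Y, new_batches[[k]]$sheet, model,
                           intersect_sites = intersect_sites)
    corrected[[labels[k]]] <- res$corrected
    model <- res$model
  }
  list(corrected = corrected, model = model)
}

fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

model_table <- function(cols) {
  dt <- data.table::as.data.table(lapply(cols, function(col) {
    if (is.numeric(col)) fmt_full(col) else col
  }))
  dt
}

#' Write a fitted model to disk
#'
#' The store is a directory containing a JSON manifest (version, options,
#' covariate coding, batch metadata and hyperpriors, content hash of the
#' global block) plus flat numeric tables: `global.csv` with the per-site
#' global parameters and one `batch_*.csv` per batch with the raw and
#' shrunken batch estimates.  Numbers are written with 17 significant
#' digits, so the round trip through [read_icombat_model()] reproduces
#' every double exactly and corrections re-run bit-identically.
#'
#' @param model an `icombat_model`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_icombat_model <- function(model, path) {
  stopifnot(inherits(model, "icombat_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- model$global
  gdt <- model_table(c(list(site_id = model$site_ids,
                            alpha = g$alpha, sigma = g$sigma),
                       stats::setNames(lapply(seq_len(ncol(g$beta_cov)),
                                              function(j) g$beta_cov[, j]),
                                       paste0("beta.", colnames(g$beta_cov)))))
  global_file <- file.path(path, "global.csv")
  data.table::fwrite(gdt, global_file)
  batch_meta <- list()
  for (k in seq_along(model$batches)) {
    bp <- model$batches[[k]]
    fname <- sprintf("batch_%03d.csv", k)
    bdt <- model_table(list(
      site_id = model$site_ids,
      gamma_hat = bp$gamma_hat,
      delta2_hat = bp$delta2_hat %||% rep(NA_real_, length(bp$gamma_hat)),
      gamma_star = bp$gamma_star,
      delta2_star = bp$delta2_star))
    data.table::fwrite(bdt, file.path(path, fname))
    batch_meta[[k]] <- list(label = bp$label, n = bp$n, file = fname,
                            eb_iterations = bp$eb_iterations,
                            hyperpriors = lapply(unclass(bp$hyperpriors),
                                                 fmt_full))
  }
  manifest <- list(format = "icombat-model",
                   version = model$version,
                   n_sites = length(model$site_ids),
                   mean_only = isTRUE(model$mean_only),
                   options = model$options,
                   n_total = g$n_total,
                   beta_columns = as.list(colnames(g$beta_cov)),
                   covariate_coding = model$covariate_coding,
                   batches = batch_meta,
                   global_hash = unname(tools::md5sum(global_file)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted model from disk
#'
#' Validates the manifest (site counts, batch files) and verifies the
#' content hash of the global-parameter block before returning; a model
#' whose global block was altered after writing is refused, since every
#' incremental correction depends on those frozen values.
#'
#' @param path directory written by [write_icombat_model()].
#' @return an `icombat_model`.
#' @export
read_icombat_model <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json under ", path)
  mf <- jsonlite::read_json(mf_path)
  if (!identical(mf$format, "icombat-model"))
    stop("not an icombat model store: ", path)
  global_file <- file.path(path, "global.csv")
  hash <- unname(tools::md5sum(global_file))
  if (!identical(hash, mf$global_hash))
    stop("global parameter block failed its checksum; the model store ",
         "was modified after writing")
  gdt <- data.table::fread(global_file, colClasses = list(character = "site_id"))
  if (nrow(gdt) != mf$n_sites)
    stop("manifest reports ", mf$n_sites, " sites but global.csv has ",
         nrow(gdt))
  site_ids <- gdt$site_id
  beta_cols <- unlist(mf$beta_columns)
  beta_cov <- if (length(beta_cols))
    as.matrix(gdt[, paste0("beta.", beta_cols), with = FALSE])
  else matrix(0, nrow(gdt), 0)
  colnames(beta_cov) <- beta_cols
  rownames(beta_cov) <- site_ids
  sigma <- stats::setNames(gdt$sigma, site_ids)
  global <- structure(list(alpha = stats::setNames(gdt$alpha, site_ids),
                           beta_cov = beta_cov, sigma = sigma,
                           sigma2 = unname(sigma)^2, n_total = mf$n_total,
                           coding = coding_from_json(mf$covariate_coding)),
                      class = "global_params")
  batches <- list()
  for (bm in mf$batches) {
    bdt <- data.table::fread(file.path(path, bm$file),
                             colClasses = list(character = "site_id"))
    if (!identical(bdt$site_id, site_ids))
      stop("site IDs of ", bm$file, " do not match global.csv")
    hp <- structure(lapply(bm$hyperpriors, function(v)
      if (is.null(v)) NA_real_ else as.numeric(v)), class = "hyperpriors")
    d2h <- stats::setNames(bdt$delta2_hat, site_ids)
    batches[[bm$label]] <- list(
      label = bm$label, n = bm$n, hyperpriors = hp,
      gamma_hat = stats::setNames(bdt$gamma_hat, site_ids),
      delta2_hat = if (all(is.na(d2h))) NULL else d2h,
      gamma_star = stats::setNames(bdt$gamma_star, site_ids),
      delta2_star = stats::setNames(bdt$delta2_star, site_ids),
      eb_iterations = bm$eb_iterations)
  }
  structure(list(version = mf$version, site_ids = site_ids,
                 covariate_coding = coding_from_json(mf$covariate_coding),
                 mean_only = isTRUE(mf$mean_only),
                 options = list(tol = as.numeric(mf$options$tol),
                                max_iter = as.integer(mf$options$max_iter)),
                 global = global, batches = batches),
            class = "icombat_model")
}

coding_from_json <- function(cd) {
  lapply(cd, function(x) {
    out <- list(type = x$type)
    if (!is.null(x$levels)) out$levels <- unlist(x$levels)
    out
  })
}
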