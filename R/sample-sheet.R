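#' Sample sheet: batch labels and biological covariates
#'
#' Holds, for each sample, its batch assignment and the biological
#' covariates that the correction must preserve (e.g. group, age).  The
#' dummy coding of categorical covariates is computed once, stored on the
#' object, and serialized with fitted models so that later (incremental)
#' batches are coded identically.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param batch vector of batch labels, one per sample; coerced to factor
#'   in order of first appearance.
#' @param covariates data.frame of per-sample biological covariates
#'   (numeric or factor/character columns), or `NULL` for none.
#' @param coding an existing covariate coding to freeze (as stored in a
#'   fitted model); by default the coding is derived from `covariates`.
#'
#' @return a `sample_sheet` object (list with `sample_ids`, `batch`,
#'   `covariates`, `coding`).
#' @export
sample_sheet <- function(sample_ids, batch, covariates = NULL, coding = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids in sample sheet")
  n <- length(sample_ids)
  if (length(batch) != n) stop("`batch` must have one entry per sample")
  batch <- factor(as.character(batch), levels = unique(as.character(batch)))
  if (any(table(batch) < 1L)) stop("every batch level needs >= 1 sample")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != n)
      stop("`covariates` must have one row per sample")
  }
  if (is.null(coding)) coding <- derive_coding(covariates)
  structure(list(sample_ids = sample_ids, batch = batch,
                 covariates = covariates, coding = coding),
            class = "sample_sheet")
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("sample_sheet: %d samples, %d batches (%s), covariates: %s\n",
              length(x$sample_ids), nlevels(x$batch),
              paste(levels(x$batch), collapse = ", "),
              if (is.null(x$covariates)) "none"
              else paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

# Deterministic covariate coding: numeric columns pass through; factor or
# character columns are dummy coded dropping the first observed level (no
# intercept exists anywhere in the design, so one level per factor must go).
derive_coding <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0L) return(list())
  coding <- list()
  for (nm in names(covariates)) {
    col <- covariates[[nm]]
    if (is.numeric(col)) {
      coding[[nm]] <- list(type = "numeric")
    } else {
      lev <- if (is.factor(col)) levels(droplevels(col)) else unique(as.character(col))
      if (length(lev) < 2L)
        stop("covariate '", nm, "' is constant; drop it from the sheet")
      coding[[nm]] <- list(type = "factor", levels = as.character(lev))
    }
  }
  coding
}

# Expand covariates to the numeric matrix implied by a coding.  Unseen
# factor levels are an error: absorbing them silently would alias biology
# into the batch term.
code_covariates <- function(covariates, coding) {
  if (length(coding) == 0L)
    return(matrix(0, nrow = if (is.null(covariates)) 0L else nrow(covariates),
                  ncol = 0L))
  missing_cols <- setdiff(names(coding), names(covariates))
  if (length(missing_cols))
    stop("sample sheet lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  cols <- list()
  for (nm in names(coding)) {
    cd <- coding[[nm]]
    col <- covariates[[nm]]
    if (cd$type == "numeric") {
      if (!is.numeric(col)) stop("covariate '", nm, "' must be numeric")
      cols[[nm]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      unseen <- setdiff(unique(col), cd$levels)
      if (length(unseen))
        stop("covariate '", nm, "' has level(s) absent from the stored ",
             "coding: ", paste(unseen, collapse = ", "))
      for (lv in cd$levels[-1L])
        cols[[paste0(nm, "=", lv)]] <- as.numeric(col == lv)
    }
  }
  do.call(cbind, cols)
}

#' Build the batch/covariate design matrix
#'
#' Constructs `X = (X_batch, X_cov)`: one 0/1 indicator column per batch
#' (no intercept column anywhere) followed by the coded biological
#' covariates.  The matrix is checked for full column rank; rank deficiency
#' means a covariate is confounded with batch (or with another covariate)
#' and is reported as an error naming the offending columns.
#'
#' @param sheet a [sample_sheet()].
#' @return a list with `X` (N x (m+p)), `X_batch`, `X_cov`,
#'   `batch_levels`, `n_per_batch`, and `coding`.
#' @export
build_design <- function(sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  n <- length(sheet$sample_ids)
  m <- nlevels(sheet$batch)
  X_batch <- matrix(0, n, m, dimnames = list(sheet$sample_ids,
                                             paste0("batch:", levels(sheet$batch))))
  X_batch[cbind(seq_len(n), as.integer(sheet$batch))] <- 1
  X_cov <- code_covariates(sheet$covariates, sheet$coding)
  if (ncol(X_cov) == 0L) X_cov <- matrix(0, n, 0)
  if (ncol(X_cov) > 0L) {
    if (any(apply(X_cov, 2L, function(x) length(unique(x)) == 1L)))
      stop("constant covariate column in design; drop it from the sheet")
    rownames(X_cov) <- sheet$sample_ids
  }
  X <- cbind(X_batch, X_cov)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; column(s) confounded: ",
         paste(dropped, collapse = ", "),
         " (a covariate constant within every batch cannot be separated ",
         "from the batch effect)")
  }
  list(X = X, X_batch = X_batch, X_cov = X_cov,
       batch_levels = levels(sheet$batch),
       n_per_batch = as.integer(table(sheet$batch)),
       coding = sheet$coding)
}

#' Read a sample sheet from CSV/TSV
#'
#' The file must contain a `sample_id` column and a `batch` column;
#' remaining columns are available as covariates.
#'
#' @param path file path.
#' @param covariates character vector naming the covariate columns to keep
#'   (default: all columns other than `sample_id` and `batch`).
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path, covariates = NULL) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("sample_id", "batch")
  if (!all(need %in% names(df)))
    stop("sample sheet must contain columns: ", paste(need, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(df), need)
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov))
    stop("covariate column(s) not in sheet: ", paste(missing_cov, collapse = ", "))
  cov_df <- if (length(covariates)) df[, covariates, drop = FALSE] else NULL
  sample_sheet(df$sample_id, df$batch, cov_df)
}

#' Write a sample sheet to TSV
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  df <- data.frame(sample_id = sheet$sample_ids,
                   batch = as.character(sheet$batch),
                   stringsAsFactors = FALSE)
  if (!is.null(sheet$covariates)) df <- cbind(df, sheet$covariates)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
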