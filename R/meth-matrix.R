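#' Methylation matrix container
#'
#' A `meth_matrix` is a numeric matrix of methylation measurements with CpG
#' sites as rows and samples as columns, tagged with the measurement scale:
#' `"M"` for M-values (log2 ratio of methylated to unmethylated intensity,
#' unbounded) or `"beta"` for beta-values (methylated proportion in (0,1)).
#'
#' @param values numeric matrix, sites x samples.
#' @param scale `"M"` or `"beta"`.
#' @param site_ids optional character vector of row (site) identifiers;
#'   defaults to `rownames(values)` or `site_1..site_G`.
#' @param sample_ids optional character vector of column (sample)
#'   identifiers; defaults to `colnames(values)` or `sample_1..sample_N`.
#'
#' @return a `meth_matrix`: the matrix with row/column names set and a
#'   `meth_scale` attribute.
#' @export
meth_matrix <- function(values, scale = c("M", "beta"),
                        site_ids = NULL, sample_ids = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (sites x samples)")
  if (is.null(site_ids))
    site_ids <- rownames(values) %||% paste0("site_", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- colnames(values) %||% paste0("sample_", seq_len(ncol(values)))
  site_ids <- as.character(site_ids)
  sample_ids <- as.character(sample_ids)
  if (length(site_ids) != nrow(values))
    stop("length of `site_ids` does not match nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length of `sample_ids` does not match ncol(values)")
  if (anyDuplicated(site_ids))
    stop("duplicate site_ids: ", paste(unique(site_ids[duplicated(site_ids)]),
                                       collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (scale == "beta" && (any(!is.finite(values)) ||
                          any(values <= 0) || any(values >= 1)))
    stop("beta-values must lie strictly in (0, 1)")
  dimnames(values) <- list(site_ids, sample_ids)
  structure(values, meth_scale = scale, class = c("meth_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d sites x %d samples, scale = %s\n",
              nrow(x), ncol(x), meth_scale(x)))
  invisible(x)
}

#' Measurement scale of a methylation matrix
#' @param x a `meth_matrix`.
#' @return `"M"` or `"beta"`.
#' @export
meth_scale <- function(x) attr(x, "meth_scale") %||% "M"

is_meth_matrix <- function(x) inherits(x, "meth_matrix")

#' Subset a meth_matrix, keeping the scale tag
#' @param x a `meth_matrix`.
#' @param i,j row/column indices.
#' @param drop ignored; always `FALSE`.
#' @param ... unused.
#' @export
`[.meth_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  meth_matrix(out, scale = meth_scale(x))
}

#' M-values from probe intensities
#'
#' Computes `log2((M + eta) / (U + eta))` elementwise, where `M` and `U` are
#' the methylated and unmethylated signal intensities and `eta` is a small
#' positive offset that keeps the ratio finite at zero intensity.
#'
#' @param methylated,unmethylated non-negative numeric matrices of equal
#'   dimension (sites x samples).
#' @param eta positive stabilising offset; defaults to 1.
#' @inheritParams meth_matrix
#' @return a `meth_matrix` on the M scale.
#' @export
mvalue_from_intensities <- function(methylated, unmethylated, eta = 1,
                                    site_ids = NULL, sample_ids = NULL) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("`eta` must be a single positive number")
  methylated <- as.matrix(methylated)
  unmethylated <- as.matrix(unmethylated)
  if (!identical(dim(methylated), dim(unmethylated)))
    stop("intensity matrices have mismatched dimensions")
  if (any(methylated < 0) || any(unmethylated < 0))
    stop("intensities must be non-negative")
  y <- log2((methylated + eta) / (unmethylated + eta))
  meth_matrix(y, scale = "M",
              site_ids = site_ids %||% rownames(methylated),
              sample_ids = sample_ids %||% colnames(methylated))
}

#' Beta-values from M-values
#'
#' The logistic-type map `B = 2^Y / (2^Y + 1)`, the standard approximate
#' conversion from the M scale to the proportion scale.
#'
#' @param Y a `meth_matrix` on the M scale.
#' @return a `meth_matrix` on the beta scale, all values strictly in (0,1).
#' @export
beta_from_mvalue <- function(Y) {
  if (!is_meth_matrix(Y)) Y <- meth_matrix(as.matrix(Y), scale = "M")
  if (meth_scale(Y) != "M")
    stop("input is on the ", meth_scale(Y), " scale; expected M-values")
  b <- stats::plogis(log(2) * unclass(Y))  # 2^Y/(2^Y+1), overflow-safe
  meth_matrix(b, scale = "beta", site_ids = rownames(Y),
              sample_ids = colnames(Y))
}

#' M-values from beta-values
#'
#' The inverse of [beta_from_mvalue()]: `Y = log2(B / (1 - B))` (the logit
#' on base 2).  Undefined at 0 and 1; such values are rejected unless
#' `clip = TRUE`, in which case they are first clipped into
#' `[eps, 1 - eps]`.
#'
#' @param B a `meth_matrix` on the beta scale (or plain matrix in (0,1)).
#' @param clip clip values at/outside the open unit interval instead of
#'   erroring.
#' @param eps clipping margin when `clip = TRUE`.
#' @return a `meth_matrix` on the M scale.
#' @export
mvalue_from_beta <- function(B, clip = FALSE, eps = 1e-6) {
  vals <- unclass(as.matrix(B))
  if (any(!is.finite(vals)))
    stop("beta-values must be finite")
  bad <- vals <= 0 | vals >= 1
  if (any(bad)) {
    if (!clip)
      stop(sum(bad), " beta-value(s) at or outside (0, 1); ",
           "the M transform is undefined there (set clip = TRUE to clip)")
    vals <- pmin(pmax(vals, eps), 1 - eps)
  }
  y <- log2(vals / (1 - vals))
  meth_matrix(y, scale = "M", site_ids = rownames(vals),
              sample_ids = colnames(vals))
}

#' Read a methylation matrix from CSV/TSV
#'
#' Expects a header row of sample IDs and a first column of site IDs.
#' Gzipped files are read transparently.
#'
#' @param path file path.
#' @param scale the scale tag to attach (`"M"` or `"beta"`).
#' @param impute_missing impute missing cells with the per-site median
#'   (otherwise any `NA` is an error).
#' @return a `meth_matrix`.
#' @export
read_meth_matrix <- function(path, scale = c("M", "beta"),
                             impute_missing = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  site_ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    if (!impute_missing)
      stop(sum(is.na(vals)), " missing value(s) in ", path,
           "; set impute_missing = TRUE to impute per-site medians")
    n_missing <- sum(is.na(vals))
    med <- apply(vals, 1L, stats::median, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- med[idx[, 1L]]
    message("imputed ", n_missing, " missing value(s) with per-site medians")
  }
  meth_matrix(vals, scale = scale, site_ids = site_ids,
              sample_ids = colnames(vals))
}

#' Write a methylation matrix to TSV
#'
#' @param Y a `meth_matrix`.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_meth_matrix <- function(Y, path) {
  dt <- data.table::data.table(site_id = rownames(Y))
  vals <- unclass(Y)
  for (j in seq_len(ncol(vals))) data.table::set(dt, j = colnames(vals)[j],
                                                 value = vals[, j])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
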