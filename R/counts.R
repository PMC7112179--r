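# Feature-by-sample containers. Counts may be fractional (multi-mapped
# reads are weighted); rounding to integers happens at the entry of the
# differential-expression step, not here.

#' Feature-by-sample count matrix with sample metadata
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns.
#' @param samples data.frame with columns `sample_id`, `tissue`,
#'   `replicate`, and optionally `library_size` (defaults to the column
#'   sum, i.e. every fragment assigned).
#'
#' @return An object of class `"count_matrix"`.
#' @export
count_matrix <- function(values, samples) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), all(values >= 0),
            nrow(samples) == ncol(values),
            all(c("sample_id", "tissue", "replicate") %in% names(samples)))
  colnames(values) <- samples$sample_id
  if (is.null(samples$library_size))
    samples$library_size <- colSums(values)
  if (any(samples$library_size < colSums(values) - 1e-6))
    stop("library_size smaller than the assigned counts of a sample")
  structure(list(values = values, samples = as.data.frame(samples)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples (", paste(unique(x$samples$tissue), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Subset a count matrix by sample
#'
#' @param cm a [count_matrix].
#' @param sample_ids sample ids to keep.
#' @return A [count_matrix] restricted to those samples.
#' @export
subset_samples <- function(cm, sample_ids) {
  keep <- cm$samples$sample_id %in% sample_ids
  count_matrix(cm$values[, keep, drop = FALSE],
               cm$samples[keep, , drop = FALSE])
}

#' FPKM expression matrix with sample metadata
#'
#' @param fpkm_values non-negative numeric matrix, features in rows.
#' @param samples data.frame with `sample_id`, `tissue`, `replicate`.
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(fpkm_values, samples) {
  fpkm_values <- as.matrix(fpkm_values)
  stopifnot(!is.null(rownames(fpkm_values)), all(fpkm_values >= 0),
            nrow(samples) == ncol(fpkm_values))
  colnames(fpkm_values) <- samples$sample_id
  structure(list(values = fpkm_values, samples = as.data.frame(samples)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (FPKM):", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  invisible(x)
}

#' Per-tissue arithmetic mean of a feature-by-sample matrix
#'
#' @param x a [count_matrix] or [expression_matrix].
#' @return Matrix features x tissues of replicate means.
#' @export
tissue_means <- function(x) {
  tis <- unique(x$samples$tissue)
  out <- vapply(tis, function(t) {
    cols <- x$samples$tissue == t
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  colnames(out) <- tis
  out
}

#' Read / write a feature-by-sample table with a sample-metadata sidecar
#'
#' The table is TSV with a `feature_id` column followed by one column per
#' sample; the sidecar TSV holds `sample_id`, `tissue`, `replicate`,
#' `library_size`.
#'
#' @param path table path; the sidecar is `<path>.samples.tsv` unless given.
#' @param sidecar optional explicit sidecar path.
#' @return A [count_matrix].
#' @export
read_counts_tsv <- function(path, sidecar = paste0(path, ".samples.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  samples <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  count_matrix(m[, samples$sample_id, drop = FALSE], samples)
}

#' @rdname read_counts_tsv
#' @param cm a [count_matrix] to write.
#' @export
write_counts_tsv <- function(cm, path,
                             sidecar = paste0(path, ".samples.tsv")) {
  df <- data.frame(feature_id = rownames(cm$values), cm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$samples, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
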