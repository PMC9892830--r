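#' Upper-quartile normalization
#'
#' Scales each sample so that its 75th percentile of present intensities
#' equals the geometric mean of all samples' 75th percentiles. Division by
#' the per-sample quantile removes sample-loading differences; the common
#' rescaling keeps the output on the input's intensity scale. Within-sample
#' ratios are preserved exactly.
#'
#' The quantile uses linear interpolation (R type 7) over present values
#' only.
#'
#' @param qm a [quant_matrix()].
#' @return A normalized [quant_matrix()] tagged `"uq_normalized"`, with the
#'   per-sample quantiles in attribute `"sample_quantiles"`.
#' @export
upper_quantile_normalize <- function(qm) {
  v <- qm$values
  q75 <- apply(v, 2, stats::quantile, probs = 0.75, na.rm = TRUE, names = FALSE)
  empty <- colnames(v)[!is.finite(q75)]
  if (length(empty)) stop_value("sample(s) with no present values: ",
                                paste(empty, collapse = ", "))
  ref <- exp(mean(log(q75)))
  out <- sweep(v, 2, q75 / ref, "/")
  res <- qm_tag(quant_matrix(out, qm$level, qm$provenance), "uq_normalized")
  attr(res, "sample_quantiles") <- stats::setNames(q75, colnames(v))
  res
}

#' Internal-standard batch correction
#'
#' Divides every feature's intensity by the value of the pooled
#' internal-standard (IS) channel of the same TMT batch, cancelling the
#' multiplicative batch effect the IS carries. Output values are
#' ratios-to-reference, comparable across batches. IS columns are dropped
#' from the result; where the IS value of a feature is missing in a batch,
#' that feature becomes missing for the whole batch (no reference, no
#' ratio).
#'
#' The correction is single-application: the result is tagged
#' `"is_corrected"` and re-application is refused.
#'
#' @param qm a [quant_matrix()].
#' @param ann sample annotation tibble (see [read_annotations()]).
#' @return A corrected [quant_matrix()] without IS columns.
#' @export
is_batch_correct <- function(qm, ann) {
  if (qm_has_tag(qm, "is_corrected")) {
    stop_design("matrix already internal-standard corrected (IS channels dropped)")
  }
  ann <- validate_annotations(ann)
  v <- qm$values
  ann <- ann[ann$sample_id %in% colnames(v), ]
  batches <- unique(ann$batch_id[!ann$is_internal_standard])
  out_cols <- list()
  for (b in batches) {
    in_b <- ann$batch_id == b
    is_id <- ann$sample_id[in_b & ann$is_internal_standard]
    if (length(is_id) != 1L) {
      stop_design("batch '", b, "' has no internal-standard column in the matrix")
    }
    member_ids <- ann$sample_id[in_b & !ann$is_internal_standard]
    ref <- v[, is_id]
    block <- v[, member_ids, drop = FALSE] / ref   # NA ref propagates to NA
    out_cols[[b]] <- block
  }
  out <- do.call(cbind, out_cols)
  colnames(out) <- unlist(lapply(out_cols, colnames), use.names = FALSE)
  qm_tag(quant_matrix(out, qm$level, qm$provenance), "is_corrected")
}

#' Missing-value filter
#'
#' Removes features whose missing fraction across samples is strictly
#' greater than `max_missing_frac` ("more than 50% missing" at the default).
#' A feature missing in exactly half of the samples is retained. The filter
#' is idempotent. The missing fraction is denominated over all columns of
#' the matrix (run after IS correction, so IS channels are not counted).
#'
#' @param qm a [quant_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction in `[0, 1]`.
#' @return Filtered [quant_matrix()]; removed feature ids in attribute
#'   `"removed_features"` and their count in `"n_removed"`.
#' @export
filter_missing <- function(qm, max_missing_frac = 0.5) {
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop_value("max_missing_frac must be in [0, 1]")
  }
  v <- qm$values
  frac <- rowMeans(is.na(v))
  drop <- frac > max_missing_frac
  res <- qm_tag(quant_matrix(v[!drop, , drop = FALSE], qm$level, qm$provenance),
                "missing_filtered")
  attr(res, "removed_features") <- rownames(v)[drop]
  attr(res, "n_removed") <- sum(drop)
  res
}

#' PCA projection of samples
#'
#' Projects samples onto principal components of the log2 intensity matrix.
#' Features are centered; remaining missing values are mean-imputed per
#' feature for the projection only (run after [filter_missing()] so no
#' feature is mostly imputed). Scores come from the singular value
#' decomposition of the centered matrix.
#'
#' @param qm a [quant_matrix()].
#' @param n_components number of components to keep.
#' @return Object of class `qm_pca`: list with `scores` (tibble, one row per
#'   sample) and `var_explained` (fractions, summing to at most 1).
#' @export
pca_project <- function(qm, n_components = 2) {
  v <- log2(qm$values)
  if (n_components > min(dim(v))) {
    stop_value("n_components exceeds matrix rank bound min(", nrow(v), ", ", ncol(v), ")")
  }
  imp <- t(apply(v, 1, function(r) { r[is.na(r)] <- mean(r, na.rm = TRUE); r }))
  ctr <- imp - rowMeans(imp)
  sv <- svd(t(ctr), nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  var_all <- sv$d^2 / sum(sv$d^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = colnames(v)),
                              tibble::as_tibble(scores)),
    var_explained = var_all[seq_len(n_components)]
  ), class = "qm_pca")
}

#' @export
print.qm_pca <- function(x, ...) {
  cat("<qm_pca> ", nrow(x$scores), " samples, ",
      length(x$var_explained), " components (",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qm_pca <- function(x, ...) x$scores

#' Run the full preprocessing chain
#'
#' Applies, in order: upper-quartile normalization, internal-standard batch
#' correction, missing-value filtering. The order matches the measurement
#' model — loading differences are removed before ratios to the batch
#' reference are formed, and the missing filter sees the final sample set.
#'
#' @inheritParams is_batch_correct
#' @inheritParams filter_missing
#' @return Preprocessed [quant_matrix()].
#' @export
preprocess <- function(qm, ann, max_missing_frac = 0.5) {
  qm |>
    upper_quantile_normalize() |>
    is_batch_correct(ann) |>
    filter_missing(max_missing_frac)
}
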