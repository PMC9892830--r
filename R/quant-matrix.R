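#' Quantification matrix container
#'
#' A `quant_matrix` holds nonnegative feature-by-sample reporter intensities
#' at one of three levels (`protein`, `phosphosite`, `abpp_site`), with `NA`
#' as the explicit missing marker. Zero or negative intensities are invalid:
#' TMT reporter intensities are strictly positive, so a zero indicates an
#' upstream processing fault rather than a missing measurement.
#'
#' A character vector of provenance tags records which pipeline stages have
#' been applied (e.g. `"uq_normalized"`, `"is_corrected"`); stages that must
#' not be applied twice check it.
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimensions must carry unique names. `NA` marks a missing value.
#' @param level one of `"protein"`, `"phosphosite"`, `"abpp_site"`.
#' @param provenance character vector of stage tags already applied.
#'
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, level = c("protein", "phosphosite", "abpp_site"),
                         provenance = character()) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_format("`values` must have feature (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(values))) {
    stop_format("duplicate feature ids: ",
                paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop_format("duplicate sample ids: ",
                paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stop_value("nonpositive intensity at feature '", rownames(values)[rc[1]],
               "', sample '", colnames(values)[rc[2]],
               "' (zero is invalid, use NA for missing)")
  }
  structure(list(values = values, level = level, provenance = provenance),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<quant_matrix> level=%s  %d features x %d samples  (%.1f%% missing)\n",
              x$level, nrow(v), ncol(v), 100 * mean(is.na(v))))
  if (length(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Feature and sample ids of a quant_matrix
#' @param qm a [quant_matrix()].
#' @return character vector of ids.
#' @export
qm_features <- function(qm) rownames(qm$values)

#' @rdname qm_features
#' @export
qm_samples <- function(qm) colnames(qm$values)

qm_tag <- function(qm, tag) {
  qm$provenance <- c(qm$provenance, tag)
  qm
}

qm_has_tag <- function(qm, tag) tag %in% qm$provenance

#' Convert a quant_matrix to a long tibble
#'
#' @param x a [quant_matrix()].
#' @param ... unused.
#' @return Tibble with columns `feature_id`, `sample_id`, `intensity`
#'   (missing values kept as `NA`), plus a `level` column.
#' @exportS3Method generics::tidy
tidy.quant_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    feature_id = rep(rownames(v), times = ncol(v)),
    sample_id = rep(colnames(v), each = nrow(v)),
    intensity = as.vector(v),
    level = x$level
  )
}

# typed error helpers -------------------------------------------------------

stop_format <- function(...) stop(errorCondition(paste0(...), class = c("gaclnm_format_error", "gaclnm_error")))
stop_value  <- function(...) stop(errorCondition(paste0(...), class = c("gaclnm_value_error",  "gaclnm_error")))
stop_design <- function(...) stop(errorCondition(paste0(...), class = c("gaclnm_design_error", "gaclnm_error")))

#' Parse phosphosite feature ids
#'
#' Site ids use the `PROTEIN_S123` syntax: parent protein id, an underscore,
#' a residue letter (serine, threonine or tyrosine) and a 1-based position.
#'
#' @param ids character vector of site ids.
#' @return Tibble with columns `site_id`, `protein_id`, `residue`, `position`.
#' @examples
#' parse_site_id("GSK3B_S9")
#' @export
parse_site_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)_([STY])([0-9]+)$", ids))
  bad <- ids[vapply(m, length, 1L) != 4L]
  if (length(bad)) {
    stop_format("invalid phosphosite id(s): ", paste(utils::head(bad, 5), collapse = ", "),
                " (expected PROTEIN_[STY]<position>)")
  }
  pos <- as.integer(vapply(m, `[`, "", 4L))
  if (any(pos < 1L)) stop_value("phosphosite position must be >= 1")
  tibble::tibble(
    site_id = ids,
    protein_id = vapply(m, `[`, "", 2L),
    residue = vapply(m, `[`, "", 3L),
    position = pos
  )
}

#' @rdname parse_site_id
#' @param protein_id,residue,position components to render into site ids.
#' @export
make_site_id <- function(protein_id, residue, position) {
  stopifnot(all(residue %in% c("S", "T", "Y")), all(position >= 1))
  paste0(protein_id, "_", residue, position)
}
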