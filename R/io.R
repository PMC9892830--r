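#' Read and write quantification matrices
#'
#' Matrices are tab-separated UTF-8 with a header row: first column the
#' feature id, remaining columns one per sample. Empty cells and the literal
#' `NA` are missing; zero or negative intensities are rejected.
#'
#' @param path TSV file path.
#' @param level quantification level, see [quant_matrix()].
#' @return `read_quant_matrix()`: a [quant_matrix()].
#' @export
read_quant_matrix <- function(path, level = c("protein", "phosphosite", "abpp_site")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop_value("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    stop_format("duplicate sample column name(s): ",
                paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "))
  }
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                          colClasses = c("character", rep("numeric", length(header) - 1L)))
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  quant_matrix(v, level = level)
}

#' @rdname read_quant_matrix
#' @param qm a [quant_matrix()] to serialize.
#' @param digits significant digits for on-disk floats.
#' @export
write_quant_matrix <- function(qm, path, digits = 6) {
  v <- qm$values
  out <- data.frame(feature_id = rownames(v),
                    signif(v, digits), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

ANNOTATION_COLS <- c("sample_id", "subject_id", "tissue", "group", "batch_id",
                     "channel_id", "is_internal_standard")

#' Read the sample annotation table
#'
#' CSV with one row per TMT channel. Required columns: `sample_id`,
#' `subject_id`, `tissue` (tumor / para_tumor), `group` (LNM / noLNM),
#' `batch_id`, `channel_id`, `is_internal_standard`. Optional: `stage`
#' (I--IV), `t_stage`, `n_stage`, `m_stage`, `age`, `sex`.
#'
#' Each batch must contain exactly one internal-standard (IS) channel — the
#' pooled reference mixture labeled alongside the biological samples.
#' IS rows carry no group or stage.
#'
#' @param path CSV file path.
#' @return Tibble of sample annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                        colClasses = "character")
  validate_annotations(tibble::as_tibble(df))
}

#' @rdname read_annotations
#' @param ann a data frame of annotations to validate in memory.
#' @export
validate_annotations <- function(ann) {
  missing_cols <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing_cols)) stop_format("annotation missing column(s): ",
                                        paste(missing_cols, collapse = ", "))
  ann <- tibble::as_tibble(ann)
  if (is.character(ann$is_internal_standard)) {
    ann$is_internal_standard <- toupper(ann$is_internal_standard) %in% c("TRUE", "T", "1", "YES")
  }
  for (col in intersect(c("t_stage", "n_stage", "m_stage", "age"), names(ann))) {
    ann[[col]] <- as.integer(ann[[col]])
  }
  if (anyDuplicated(ann$sample_id)) {
    stop_format("duplicate sample_id: ",
                paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  }
  bad_tissue <- setdiff(stats::na.omit(unique(ann$tissue)), c("tumor", "para_tumor"))
  if (length(bad_tissue)) stop_format("unknown tissue value(s): ", paste(bad_tissue, collapse = ", "))
  bad_group <- setdiff(stats::na.omit(unique(ann$group)), c("LNM", "noLNM"))
  if (length(bad_group)) stop_format("unknown group value(s): ", paste(bad_group, collapse = ", "))
  if ("stage" %in% names(ann)) {
    bad_stage <- setdiff(stats::na.omit(unique(ann$stage)), c("I", "II", "III", "IV"))
    if (length(bad_stage)) stop_format("unknown stage value(s): ", paste(bad_stage, collapse = ", "))
  }
  n_is <- tapply(ann$is_internal_standard, ann$batch_id, sum)
  off <- names(n_is)[n_is != 1L]
  if (length(off)) {
    stop_design("each batch needs exactly one internal-standard channel; offending batch(es): ",
                paste(off, collapse = ", "))
  }
  is_rows <- ann$is_internal_standard
  if (any(!is.na(ann$group[is_rows]))) {
    stop_design("internal-standard channels must not carry a group label")
  }
  ann
}

#' Read a scored protein--protein interaction edge list
#'
#' Rows of `(protein_a, protein_b, score)`, tab-separated with a header.
#' Scores are either already on the unit interval (`score_scale = "unit"`)
#' or on the STRING 0--1000 integer dialect (`"string_1000"`, divided by
#' 1000). The dialect is an explicit flag — no auto-detection, since a
#' silently misread scale corrupts the confidence threshold downstream.
#' Duplicate edges keep the maximum confidence; self-loops are dropped with
#' a warning.
#'
#' @param path TSV path.
#' @param score_scale `"unit"` or `"string_1000"`.
#' @return An [igraph::graph][igraph] with edge attribute `confidence`.
#' @export
read_edge_list <- function(path, score_scale = c("unit", "string_1000")) {
  score_scale <- match.arg(score_scale)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = c("character", "character", "numeric"))
  edges_to_graph(df[[1]], df[[2]], df[[3]], score_scale)
}

#' @rdname read_edge_list
#' @param a,b,score parallel vectors defining edges in memory (same
#'   validation and deduplication rules as the file reader).
#' @export
edges_to_graph <- function(a, b, score, score_scale = "unit") {
  hi <- if (score_scale == "string_1000") 1000 else 1
  if (any(score < 0 | score > hi)) {
    stop_value("edge score outside [0, ", hi, "] for scale '", score_scale, "'")
  }
  conf <- if (score_scale == "string_1000") score / 1000 else score
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    a <- a[!self]; b <- b[!self]; conf <- conf[!self]
  }
  # undirected: canonical order, keep max confidence among duplicates
  lo_id <- pmin(a, b); hi_id <- pmax(a, b)
  df <- tibble::tibble(from = lo_id, to = hi_id, confidence = conf) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop")
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. Lines with fewer than three fields are a format error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; each element carries its
#'   description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) stop_format("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop_format("GMT set '", f[1], "' has no members")
    attr(members, "description") <- f[2]
    members
  })
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop_format("duplicate GMT set name(s)")
  sets
}

#' @rdname read_gmt
#' @param sets named list of member vectors to serialize.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description") %||% ""
    paste(c(names(sets)[i], desc, as.character(sets[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector mapping protein id (first word of the
#'   header) to its amino-acid sequence, uppercase.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, set.attributes = FALSE)
  out <- toupper(unlist(recs))
  names(out) <- names(recs)
  out
}

#' Read a kinase--substrate link table
#'
#' TSV with columns `kinase_id`, `site_id` (PROTEIN_S123 syntax), `source`
#' (`curated` or `predicted`) and `networkin_score` (confidence of a
#' computational kinase-substrate prediction; empty for curated links).
#'
#' @param path TSV path.
#' @return Tibble with one row per link; site id components parsed out.
#' @export
read_ks_map <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                            na.strings = c("", "NA")))
  validate_ks_map(df)
}

#' @rdname read_ks_map
#' @param links in-memory link table to validate.
#' @export
validate_ks_map <- function(links) {
  need <- c("kinase_id", "site_id", "source")
  missing_cols <- setdiff(need, names(links))
  if (length(missing_cols)) stop_format("ks map missing column(s): ",
                                        paste(missing_cols, collapse = ", "))
  if (!"networkin_score" %in% names(links)) links$networkin_score <- NA_real_
  bad_src <- setdiff(unique(links$source), c("curated", "predicted"))
  if (length(bad_src)) stop_format("unknown link source(s): ", paste(bad_src, collapse = ", "))
  if (any(!is.na(links$networkin_score) & links$networkin_score < 0)) {
    stop_value("negative networkin_score")
  }
  if (anyDuplicated(links[c("kinase_id", "site_id", "source")])) {
    stop_format("duplicate (kinase, site, source) link(s)")
  }
  key <- parse_site_id(links$site_id)
  dplyr::bind_cols(tibble::as_tibble(links),
                   key[c("protein_id", "residue", "position")])
}

#' Write a result table as TSV
#'
#' Tab-separated UTF-8, header row, stable column order, `NA` for missing.
#' Refuses to overwrite an existing file unless `force = TRUE`.
#'
#' @param x data frame.
#' @param path output path.
#' @param force overwrite an existing file?
#' @export
write_table <- function(x, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop_value("output exists (use force = TRUE to overwrite): ", path)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
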