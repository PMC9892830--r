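#' Kinase-substrate enrichment analysis (KSEA)
#'
#' Scores each kinase by how far the mean log2 fold change of its annotated
#' substrate sites departs from the mean over all quantified sites:
#'
#'   z = (s_bar - p_bar) * sqrt(m) / delta
#'
#' where `s_bar` is the kinase's mean substrate log2FC, `p_bar` and `delta`
#' the mean and standard deviation of all site log2FCs, and `m` the number
#' of distinct substrate sites used. Predicted links are kept only when
#' their NetworKIN score reaches `networkin_cutoff`; curated links are
#' always kept. Kinases with fewer than `min_substrates` usable sites are
#' excluded. Two-sided normal p-values and a Benjamini-Hochberg FDR across
#' scored kinases are reported.
#'
#' @param site_fc tibble with columns `site_id` and `log2fc` (typically the
#'   protein-adjusted phosphosite fold changes from
#'   [differential_expression()] after [phospho_adjust()]).
#' @param links kinase-substrate link tibble (see [read_ks_map()]).
#' @param networkin_cutoff minimum NetworKIN score for predicted links.
#' @param min_substrates substrate count cutoff.
#' @param alpha significance level on the raw p-value.
#' @return Tibble of class `ksea_result`: `kinase_id`, `m`,
#'   `mean_substrate_log2fc`, `mean_all_log2fc`, `sd_all_log2fc`, `z`,
#'   `p_value`, `fdr`, `direction`, `significant`, ordered by decreasing
#'   `|z|`.
#' @export
ksea <- function(site_fc, links, networkin_cutoff = 2.5, min_substrates = 5,
                 alpha = 0.05) {
  stopifnot(all(c("site_id", "log2fc") %in% names(site_fc)))
  fc <- site_fc$log2fc[!is.na(site_fc$log2fc)]
  names(fc) <- site_fc$site_id[!is.na(site_fc$log2fc)]
  if (!all(is.finite(fc))) stop_value("non-finite site log2 fold changes")
  p_bar <- mean(fc)
  delta <- stats::sd(fc)
  if (!is.finite(delta) || delta == 0) {
    stop_value("degenerate FC distribution (zero spread across sites)")
  }
  links <- validate_ks_map(links)
  keep <- links$source == "curated" |
    (!is.na(links$networkin_score) & links$networkin_score >= networkin_cutoff)
  links <- links[keep & links$site_id %in% names(fc), ]
  res <- links |>
    dplyr::distinct(.data$kinase_id, .data$site_id) |>
    dplyr::group_by(.data$kinase_id) |>
    dplyr::summarise(m = dplyr::n(),
                     mean_substrate_log2fc = mean(fc[.data$site_id]),
                     .groups = "drop") |>
    dplyr::filter(.data$m >= min_substrates) |>
    dplyr::mutate(
      mean_all_log2fc = p_bar,
      sd_all_log2fc = delta,
      z = (.data$mean_substrate_log2fc - p_bar) * sqrt(.data$m) / delta,
      p_value = 2 * stats::pnorm(abs(.data$z), lower.tail = FALSE),
      fdr = stats::p.adjust(.data$p_value, method = "BH"),
      direction = ifelse(.data$z >= 0, "up", "down"),
      significant = .data$p_value < alpha) |>
    dplyr::arrange(dplyr::desc(abs(.data$z)))
  class(res) <- c("ksea_result", class(res))
  res
}

#' Aggregate ABPP technical replicates
#'
#' Desthiobiotin-ATP probe site intensities are measured in two technical
#' replicate runs per biological sample. Each replicate column is
#' upper-quartile normalized (reusing [upper_quantile_normalize()]), then
#' replicate pairs are averaged per site: mean of the present values, so one
#' missing replicate leaves the other as the estimate, and both missing
#' stays missing.
#'
#' @param qm ABPP-level [quant_matrix()] whose columns are replicate runs.
#' @param replicate_of named character vector mapping each replicate column
#'   to its biological sample id; every biological sample must map exactly
#'   two replicate columns.
#' @param normalize apply upper-quartile normalization to the replicate
#'   columns first (disable when the input is already normalized).
#' @return [quant_matrix()] with one column per biological sample.
#' @export
abpp_aggregate <- function(qm, replicate_of, normalize = TRUE) {
  cols <- qm_samples(qm)
  unmapped <- setdiff(cols, names(replicate_of))
  if (length(unmapped)) stop_design("replicate column(s) without pairing: ",
                                    paste(unmapped, collapse = ", "))
  tab <- table(replicate_of[cols])
  off <- names(tab)[tab != 2L]
  if (length(off)) stop_design("sample(s) without exactly two replicates: ",
                               paste(off, collapse = ", "))
  v <- if (normalize) upper_quantile_normalize(qm)$values else qm$values
  samples <- unique(unname(replicate_of[cols]))
  out <- vapply(samples, function(s) {
    rowMeans(v[, cols[replicate_of[cols] == s], drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(v)))
  out[is.nan(out)] <- NA
  qm_tag(quant_matrix(out, "abpp_site", qm$provenance), "abpp_aggregated")
}

#' Differential ABPP site analysis with group-exclusive calls
#'
#' Compares per-sample probe-site intensities between the LNM and no-LNM
#' groups. Sites quantified in at least `min_detected` samples of one group
#' and in none of the other are called *exclusive* to the detected group —
#' evidence of an activity present only there — and are exempted from
#' testing. Remaining sites with at least `min_n` present values per group
#' get a two-sided t-test on log2 intensities plus the linear fold-change
#' gates.
#'
#' @param site_means aggregated ABPP [quant_matrix()] (see
#'   [abpp_aggregate()]).
#' @param groups named character vector mapping sample id to `"LNM"` /
#'   `"noLNM"`.
#' @param fc_up,fc_down linear fold-change gates.
#' @param alpha significance level.
#' @param min_detected detections required for an exclusivity call.
#' @param min_n minimum present values per group for testing.
#' @return Tibble: `site_id`, `n_lnm`, `n_nolnm`, `fold_change`, `log2fc`,
#'   `p_value`, `significant`, `exclusive_group` (`NA`, `"LNM"` or
#'   `"noLNM"`).
#' @export
abpp_differential <- function(site_means, groups, fc_up = 1.5, fc_down = 0.67,
                              alpha = 0.05, min_detected = 2, min_n = 2) {
  v <- site_means$values
  ids_a <- intersect(colnames(v), names(groups)[groups == "LNM"])
  ids_b <- intersect(colnames(v), names(groups)[groups == "noLNM"])
  if (!length(ids_a) || !length(ids_b)) stop_design("both groups must have samples")
  purrr::map(rownames(v), function(f) {
    a <- v[f, ids_a][!is.na(v[f, ids_a])]
    b <- v[f, ids_b][!is.na(v[f, ids_b])]
    excl <- if (length(a) >= min_detected && length(b) == 0) "LNM"
            else if (length(b) >= min_detected && length(a) == 0) "noLNM"
            else NA_character_
    fc <- if (length(a) && length(b)) mean(a) / mean(b) else NA_real_
    p <- NA_real_
    if (is.na(excl) && length(a) >= min_n && length(b) >= min_n) {
      p <- if (stats::sd(c(log2(a), log2(b))) == 0) 1
           else tryCatch(stats::t.test(log2(a), log2(b))$p.value,
                         error = function(e) 1)
    }
    tibble::tibble(
      site_id = f, n_lnm = length(a), n_nolnm = length(b),
      fold_change = fc, log2fc = log2(fc), p_value = p,
      significant = !is.na(p) & p < alpha & (fc >= fc_up | fc <= fc_down),
      exclusive_group = excl)
  }) |> dplyr::bind_rows()
}

#' Position frequency matrix around probe-modified lysines
#'
#' Builds, per site class (e.g. the ATP-binding-site lysine "Lys1" vs the
#' active-site lysine "Lys2"), an amino-acid frequency matrix over the
#' positions `-flank .. +flank` centered on the modified lysine. Sequence
#' termini contribute nothing at out-of-range positions, so each column sums
#' to its own contributing-site count. Sites whose stated position is not a
#' lysine in the provided sequence are reported and skipped.
#'
#' @param sites tibble with columns `protein_id`, `position` (1-based
#'   lysine position) and `site_class`.
#' @param sequences named character vector of protein sequences (see
#'   [read_fasta()]).
#' @param flank window half-width.
#' @return List, one element per site class: list with `counts` (20 x
#'   (2*flank+1) matrix), `freq` (columns normalized to their contributing
#'   counts), `n_sites`, `consensus` (argmax residue per position), and
#'   `skipped` (tibble of skipped sites with reasons).
#' @export
motif_matrix <- function(sites, sequences, flank = 7) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  positions <- -flank:flank
  classes <- unique(sites$site_class)
  out <- lapply(classes, function(cl) {
    sub <- sites[sites$site_class == cl, ]
    counts <- matrix(0L, nrow = length(aa), ncol = length(positions),
                     dimnames = list(aa, as.character(positions)))
    skipped <- list()
    n_used <- 0L
    for (i in seq_len(nrow(sub))) {
      pid <- sub$protein_id[i]; pos <- sub$position[i]
      if (!pid %in% names(sequences)) {
        warning("sequence absent for ", pid, "; site skipped")
        skipped[[length(skipped) + 1L]] <-
          tibble::tibble(protein_id = pid, position = pos, reason = "no_sequence")
        next
      }
      seq_chars <- strsplit(sequences[[pid]], "")[[1]]
      if (pos < 1 || pos > length(seq_chars) || seq_chars[pos] != "K") {
        warning(pid, " position ", pos, " is not a lysine; site skipped")
        skipped[[length(skipped) + 1L]] <-
          tibble::tibble(protein_id = pid, position = pos, reason = "not_lysine")
        next
      }
      n_used <- n_used + 1L
      for (j in seq_along(positions)) {
        p <- pos + positions[j]
        if (p >= 1 && p <= length(seq_chars) && seq_chars[p] %in% aa) {
          counts[seq_chars[p], j] <- counts[seq_chars[p], j] + 1L
        }
      }
    }
    csum <- colSums(counts)
    freq <- sweep(counts, 2, pmax(csum, 1L), "/")
    consensus <- apply(counts, 2, function(col) if (sum(col) == 0) NA_character_ else aa[which.max(col)])
    list(counts = counts, freq = freq, n_sites = n_used, consensus = consensus,
         skipped = dplyr::bind_rows(skipped))
  })
  names(out) <- classes
  out
}
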