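#' Normality-branched two-group test
#'
#' Applies a Shapiro-Wilk normality test to the log2 values of each group;
#' if both groups look normal (p >= `alpha_normality`) the groups are
#' compared with a two-sided Welch t-test on the log2 scale, otherwise with
#' a two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction). With all values identical in both groups there is no
#' evidence of a difference and p = 1.
#'
#' @param a,b positive intensity vectors for the two groups (linear scale;
#'   missing values removed by the caller).
#' @param alpha_normality level of the per-group normality screen.
#' @param pooled_normality test normality on the pooled log2 values of both
#'   groups instead of per group.
#' @return List with `test_used` (`"t"` or `"wilcoxon"`), `p_value`, and the
#'   normality p-values `normality_p_a`, `normality_p_b`.
#' @export
test_two_groups <- function(a, b, alpha_normality = 0.05, pooled_normality = FALSE) {
  la <- log2(a); lb <- log2(b)
  if (pooled_normality) {
    p_pool <- shapiro_p(c(la, lb))
    pa <- pb <- p_pool
  } else {
    pa <- shapiro_p(la)
    pb <- shapiro_p(lb)
  }
  normal <- pa >= alpha_normality && pb >= alpha_normality
  if (all(c(la, lb) == la[1])) {
    # no variation anywhere: no evidence against the null
    return(list(test_used = if (normal) "t" else "wilcoxon", p_value = 1,
                normality_p_a = pa, normality_p_b = pb))
  }
  if (normal) {
    p <- tryCatch(stats::t.test(la, lb)$p.value, error = function(e) NA_real_)
    test <- "t"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(la, lb, exact = FALSE, correct = FALSE)$p.value)
    test <- "wilcoxon"
  }
  if (is.na(p)) p <- 1
  list(test_used = test, p_value = p, normality_p_a = pa, normality_p_b = pb)
}

# Shapiro-Wilk p; constant or too-short input counts as a normality failure
# (p = 0) so the rank test handles it.
shapiro_p <- function(x) {
  if (length(x) < 3 || diff(range(x)) == 0) return(0)
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  stats::shapiro.test(x)$p.value
}

#' Two-group differential expression with fold-change gates
#'
#' Compares tumor samples of the LNM group against tumor samples of the
#' no-LNM group, feature by feature. The test runs on log2 intensities via
#' [test_two_groups()]; the fold change is the ratio of group arithmetic
#' means on the linear scale. A feature is called significant when
#' `p < alpha` and its fold change passes either gate
#' (`fold_change >= fc_up` or `<= fc_down`). A Benjamini-Hochberg adjusted
#' p-value is reported for reference but does not drive the call, matching
#' the raw-p gate convention of the discovery analysis this implements.
#'
#' @param qm preprocessed [quant_matrix()] (must carry the `"is_corrected"`
#'   provenance tag).
#' @param ann sample annotation tibble.
#' @param fc_up,fc_down linear fold-change gates (up and down).
#' @param alpha significance level on the raw p-value.
#' @param min_n minimum present values per group for a feature to be tested.
#' @param tissue which tissue to contrast (default `"tumor"`).
#' @param alpha_normality,pooled_normality forwarded to [test_two_groups()].
#' @return Object of class `de_result`: tibble with one row per feature
#'   (`feature_id`, `n_a`, `n_b`, `fold_change`, `log2fc`, `test_used`,
#'   `normality_p_a`, `normality_p_b`, `p_value`, `p_adj`, `significant`,
#'   `direction`, `skipped_reason`), group A = LNM, group B = noLNM.
#' @export
differential_expression <- function(qm, ann, fc_up = 1.5, fc_down = 0.67,
                                    alpha = 0.05, min_n = 3, tissue = "tumor",
                                    alpha_normality = 0.05, pooled_normality = FALSE) {
  if (!qm_has_tag(qm, "is_corrected")) {
    stop_design("matrix must be preprocessed (internal-standard corrected) before DE")
  }
  ann <- validate_annotations(ann)
  ids_a <- ann$sample_id[!ann$is_internal_standard & ann$tissue %in% tissue &
                           ann$group %in% "LNM"]
  ids_b <- ann$sample_id[!ann$is_internal_standard & ann$tissue %in% tissue &
                           ann$group %in% "noLNM"]
  ids_a <- intersect(ids_a, qm_samples(qm))
  ids_b <- intersect(ids_b, qm_samples(qm))
  if (!length(ids_a) || !length(ids_b)) {
    stop_design("empty contrast group (LNM n=", length(ids_a),
                ", noLNM n=", length(ids_b), ")")
  }
  va <- qm$values[, ids_a, drop = FALSE]
  vb <- qm$values[, ids_b, drop = FALSE]

  rows <- purrr::map(seq_len(nrow(va)), function(i) {
    a <- va[i, ][!is.na(va[i, ])]
    b <- vb[i, ][!is.na(vb[i, ])]
    fc <- mean(a) / mean(b)
    if (length(a) < min_n || length(b) < min_n) {
      return(tibble::tibble(
        feature_id = rownames(va)[i], n_a = length(a), n_b = length(b),
        fold_change = if (length(a) && length(b)) fc else NA_real_,
        log2fc = log2(fold_change), test_used = NA_character_,
        normality_p_a = NA_real_, normality_p_b = NA_real_,
        p_value = NA_real_, skipped_reason = "insufficient_n"))
    }
    tt <- test_two_groups(a, b, alpha_normality, pooled_normality)
    tibble::tibble(
      feature_id = rownames(va)[i], n_a = length(a), n_b = length(b),
      fold_change = fc, log2fc = log2(fc), test_used = tt$test_used,
      normality_p_a = tt$normality_p_a, normality_p_b = tt$normality_p_b,
      p_value = tt$p_value, skipped_reason = NA_character_)
  })
  res <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      p_adj = stats::p.adjust(.data$p_value, method = "BH"),
      significant = !is.na(.data$p_value) & .data$p_value < alpha &
        (.data$fold_change >= fc_up | .data$fold_change <= fc_down),
      direction = dplyr::case_when(
        .data$significant & .data$fold_change >= fc_up ~ "up",
        .data$significant & .data$fold_change <= fc_down ~ "down",
        TRUE ~ "ns")) |>
    dplyr::relocate("p_adj", .after = "p_value")
  attr(res, "contrast") <- c(a = "LNM", b = "noLNM")
  attr(res, "gates") <- c(fc_up = fc_up, fc_down = fc_down, alpha = alpha)
  class(res) <- c("de_result", class(res))
  res
}

#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_tested = sum(is.na(x$skipped_reason)),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_skipped = sum(!is.na(x$skipped_reason))
  )
}

#' Phosphosite-to-protein adjustment
#'
#' Divides each phosphosite's per-sample intensity by its parent protein's
#' intensity in the same sample, isolating phosphorylation-level change from
#' protein-expression change. Samples where the parent is missing become
#' missing for the site. Sites whose parent protein is absent from the
#' protein matrix pass through unadjusted and are flagged.
#'
#' @param site_qm phosphosite [quant_matrix()].
#' @param prot_qm protein [quant_matrix()] on the same samples.
#' @return Adjusted phosphosite [quant_matrix()]; logical vector attribute
#'   `"adjusted"` (per feature) marks sites whose parent was found.
#' @export
phospho_adjust <- function(site_qm, prot_qm) {
  common <- intersect(qm_samples(site_qm), qm_samples(prot_qm))
  if (!setequal(qm_samples(site_qm), qm_samples(prot_qm))) {
    stop_design("site and protein matrices must cover the same samples")
  }
  sv <- site_qm$values[, common, drop = FALSE]
  pv <- prot_qm$values[, common, drop = FALSE]
  parents <- parse_site_id(rownames(sv))$protein_id
  has_parent <- parents %in% rownames(pv)
  out <- sv
  out[has_parent, ] <- sv[has_parent, , drop = FALSE] /
    pv[parents[has_parent], , drop = FALSE]
  res <- qm_tag(quant_matrix(out, site_qm$level, site_qm$provenance), "phospho_adjusted")
  attr(res, "adjusted") <- stats::setNames(has_parent, rownames(sv))
  res
}

#' Over-representation analysis of a hit list
#'
#' Hypergeometric upper-tail test of each gene set against a hit list drawn
#' from a universe: p = P[X >= k] with X ~ Hypergeometric(N, K, n), where N
#' is the universe size, K the set size within the universe, n the number of
#' hits and k the overlap. Sets with zero overlap are reported but excluded
#' from testing (and from the Benjamini-Hochberg correction).
#'
#' @param hits character vector of hit feature ids (must be a subset of
#'   `universe`).
#' @param universe character vector of all testable feature ids.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @return Tibble with columns `set`, `overlap`, `set_size`, `universe_size`,
#'   `n_hits`, `p_value`, `tested`, `fdr` (`NA` for untested sets), ordered
#'   by p.
#' @export
ora_enrich <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  if (!all(hits %in% universe)) {
    stop_value("hits not contained in universe: ",
               paste(utils::head(setdiff(hits, universe), 5), collapse = ", "))
  }
  N <- length(universe); n <- length(hits)
  res <- purrr::map(names(sets), function(s) {
    members <- intersect(sets[[s]], universe)
    K <- length(members)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)  # k = 0 -> p = 1
    tibble::tibble(set = s, overlap = k, set_size = K, universe_size = N,
                   n_hits = n, p_value = p, tested = k > 0)
  }) |> dplyr::bind_rows()
  res$fdr <- NA_real_
  res$fdr[res$tested] <- stats::p.adjust(res$p_value[res$tested], method = "BH")
  dplyr::arrange(res, .data$p_value)
}
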