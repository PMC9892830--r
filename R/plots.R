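#' Volcano plot of a differential-expression result
#'
#' @param object a `de_result` from [differential_expression()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, ...) {
  gates <- attr(object, "gates")
  df <- dplyr::filter(object, !is.na(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey60")) +
    ggplot2::geom_vline(xintercept = log2(gates[c("fc_up", "fc_down")]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(gates[["alpha"]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold change (LNM / noLNM)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Sample scores of a PCA projection
#'
#' @param object a `qm_pca` from [pca_project()].
#' @param colour_by optional vector (named by sample or in column order)
#'   used to colour the points, e.g. tissue or group labels.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qm_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) {
    df$colour_by <- if (!is.null(names(colour_by))) colour_by[df$sample_id] else colour_by
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour_by)) +
    ggplot2::labs(colour = NULL)
}

#' Cluster centroid profiles across conditions
#'
#' @param object an `fcm_fit` from [fuzzy_cmeans()].
#' @param conditions optional condition labels for the x axis.
#' @param ... unused.
#' @return A ggplot of centroid profiles, one facet per cluster.
#' @exportS3Method ggplot2::autoplot
autoplot.fcm_fit <- function(object, conditions = NULL, ...) {
  cent <- object$centroids
  conds <- conditions %||% colnames(cent) %||% as.character(seq_len(ncol(cent)))
  df <- tibble::tibble(
    cluster = rep(rownames(cent), times = ncol(cent)),
    condition = factor(rep(conds, each = nrow(cent)), levels = conds),
    value = as.vector(cent))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$value,
                                   group = .data$cluster)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "standardized expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Kaplan-Meier step curve
#'
#' @param object a `km_curve` from [km_estimate()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                         object[c("time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' High/low cohort survival curves of a stratified analysis
#'
#' @param object a `surv_strat` from [survival_stratify()].
#' @param ... unused.
#' @return A ggplot with one step curve per cohort and the log-rank p in
#'   the subtitle.
#' @exportS3Method ggplot2::autoplot
autoplot.surv_strat <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                                   object$km$high[c("time", "surv")]), cohort = "high"),
    dplyr::mutate(dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                                   object$km$low[c("time", "surv")]), cohort = "low"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$cohort)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.4g", object$logrank$p_value),
                  colour = "expression") +
    ggplot2::theme_minimal()
}

#' KSEA kinase activity bar chart
#'
#' @param object a `ksea_result` from [ksea()].
#' @param ... unused.
#' @return A ggplot of kinase z-scores, significant kinases filled.
#' @exportS3Method ggplot2::autoplot
autoplot.ksea_result <- function(object, ...) {
  df <- dplyr::mutate(object, kinase_id = stats::reorder(.data$kinase_id, .data$z))
  ggplot2::ggplot(df, ggplot2::aes(.data$z, .data$kinase_id,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d73027", `FALSE` = "grey70")) +
    ggplot2::labs(x = "KSEA z-score", y = NULL, fill = "p < 0.05") +
    ggplot2::theme_minimal()
}
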