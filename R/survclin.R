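#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate S(t) = prod over event times t_i <= t of
#' (1 - d_i/n_i). Censored subjects leave the risk set just after their
#' censoring time.
#'
#' @param records tibble with columns `time` (nonnegative) and `event`
#'   (logical or 0/1; `TRUE` = event observed).
#' @return Tibble of class `km_curve` with one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records) {
  check_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

check_survival <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (nrow(records) < 1) stop_value("no survival records")
  if (any(records$time < 0)) stop_value("negative survival time")
  invisible(records)
}

#' Log-rank test between two groups
#'
#' Standard (unweighted) log-rank: at each distinct event time the observed
#' minus expected events in group A are accumulated with the hypergeometric
#' variance; chi2 = U^2 / V on 1 degree of freedom. With no events at all
#' there is nothing to compare and p = 1 (with a warning).
#'
#' @param records_a,records_b survival record tibbles (see [km_estimate()]).
#' @return Tibble: `chi2`, `df`, `p_value`.
#' @export
logrank <- function(records_a, records_b) {
  check_survival(records_a); check_survival(records_b)
  df <- dplyr::bind_rows(
    dplyr::mutate(records_a[c("time", "event")], grp = "a"),
    dplyr::mutate(records_b[c("time", "event")], grp = "b"))
  if (sum(df$event) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(tibble::tibble(chi2 = 0, df = 1L, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  tibble::tibble(chi2 = sd$chisq, df = 1L,
                 p_value = stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits log hazard = beta * x for a single expression covariate by partial
#' likelihood with Efron tie handling (Breslow available). Reports the
#' hazard ratio exp(beta), its Wald p-value, and the maximized partial
#' log-likelihood.
#'
#' @param records survival tibble carrying the covariate column.
#' @param gene name of the covariate column.
#' @param ties `"efron"` or `"breslow"`.
#' @return Tibble of class `cox_fit`: `gene`, `beta`, `hazard_ratio`, `se`,
#'   `wald_p`, `loglik`, `n`, `n_event`.
#' @export
cox_univariate <- function(records, gene, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_survival(records)
  x <- records[[gene]]
  if (is.null(x)) stop_value("no covariate column '", gene, "'")
  if (stats::sd(x) == 0) stop_value("no variation in covariate '", gene, "'")
  fml <- stats::as.formula(paste0("survival::Surv(time, event) ~ `", gene, "`"))
  fit <- survival::coxph(fml, data = records, ties = ties)
  s <- summary(fit)
  out <- tibble::tibble(
    gene = gene,
    beta = unname(stats::coef(fit)),
    hazard_ratio = unname(exp(stats::coef(fit))),
    se = unname(s$coefficients[, "se(coef)"]),
    wald_p = unname(s$coefficients[, "Pr(>|z|)"]),
    loglik = fit$loglik[2],
    n = s$n, n_event = fit$nevent)
  class(out) <- c("cox_fit", class(out))
  out
}

#' Median split of an expression vector
#'
#' Samples with expression strictly above the median form the
#' high-expression cohort; samples at or below it form the low-expression
#' cohort (ties at the median go low, per the strict "higher than the 50th
#' percentile" rule). Invariant under monotone transforms of the values.
#'
#' @param values numeric expression values, named by sample where available.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop_value("need at least 2 samples to split")
  med <- stats::median(values)
  if (diff(range(values)) == 0) stop_value("no split possible: all values equal")
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}

#' Two-gene panel cohorts by intersection
#'
#' For a two-gene prognostic panel, the high-expression cohort is the
#' intersection of the two genes' single-gene high cohorts, and likewise
#' for low; samples discordant between the genes are excluded from the
#' comparison.
#'
#' @param expr_g1,expr_g2 numeric expression vectors over the same samples
#'   (same order; names preserved if present).
#' @return Factor with levels `low`, `high` and `NA` for excluded samples.
#' @export
panel_cohorts <- function(expr_g1, expr_g2) {
  if (length(expr_g1) != length(expr_g2)) stop_value("expression vectors differ in length")
  s1 <- median_split(expr_g1)
  s2 <- median_split(expr_g2)
  out <- factor(ifelse(as.character(s1) == as.character(s2), as.character(s1), NA),
                levels = c("low", "high"))
  names(out) <- names(expr_g1)
  if (!any(out == "high", na.rm = TRUE)) stop_value("empty high-expression intersection")
  if (!any(out == "low", na.rm = TRUE)) stop_value("empty low-expression intersection")
  out
}

#' Stratified survival comparison for a gene or two-gene panel
#'
#' Splits samples by [median_split()] (one gene) or [panel_cohorts()] (two
#' genes), then compares the cohorts by Kaplan-Meier / log-rank and reports
#' the continuous-covariate Cox hazard ratio per gene.
#'
#' @param records survival tibble with expression columns.
#' @param genes one or two covariate column names.
#' @return List of class `surv_strat`: `cohort` (factor), `logrank`
#'   (tibble), `cox` (tibble, one row per gene), `km` (named list of
#'   `km_curve`s for the high/low cohorts).
#' @export
survival_stratify <- function(records, genes) {
  stopifnot(length(genes) %in% 1:2)
  cohort <- if (length(genes) == 1) median_split(records[[genes]])
            else panel_cohorts(records[[genes[1]]], records[[genes[2]]])
  keep <- !is.na(cohort)
  lr <- logrank(records[keep & cohort == "high", ], records[keep & cohort == "low", ])
  cox <- dplyr::bind_rows(lapply(genes, function(gn) cox_univariate(records, gn)))
  km <- list(high = km_estimate(records[keep & cohort == "high", ]),
             low = km_estimate(records[keep & cohort == "low", ]))
  structure(list(cohort = cohort, logrank = lr, cox = cox, km = km,
                 genes = genes), class = "surv_strat")
}

#' @export
print.surv_strat <- function(x, ...) {
  cat("<surv_strat> genes:", paste(x$genes, collapse = " + "),
      "\n  cohorts:", sum(x$cohort == "high", na.rm = TRUE), "high /",
      sum(x$cohort == "low", na.rm = TRUE), "low /",
      sum(is.na(x$cohort)), "excluded",
      "\n  log-rank p =", format(x$logrank$p_value, digits = 4), "\n")
  invisible(x)
}

#' Chi-square test of a clinical contingency table
#'
#' Pearson chi-square without continuity correction (the convention needed
#' to reproduce printed clinical-table p-values). Rows and columns that are
#' entirely zero (unused factor levels) are pruned before testing, and the
#' degrees of freedom reflect the pruned table.
#'
#' @param tab integer matrix of counts (factor levels x groups).
#' @return Tibble: `chi2`, `df`, `p_value`.
#' @export
chisq_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop_value("counts must be nonnegative integers")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop_value("degenerate table after pruning zero rows/columns")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Two-sample t-test on a clinical variable
#'
#' Pooled-variance Student t by default (the labeling convention of
#' clinical tables); Welch optional.
#'
#' @param values_a,values_b numeric vectors.
#' @param var_equal pooled variance (`TRUE`, default) or Welch.
#' @return Tibble: `t`, `df`, `p_value`.
#' @export
group_ttest <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) stop_value("need n >= 2 per group")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(tibble::tibble(t = 0, df = length(values_a) + length(values_b) - 2, p_value = 1))
    }
    return(tibble::tibble(t = Inf, df = length(values_a) + length(values_b) - 2, p_value = 0))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}
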