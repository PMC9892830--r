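#' Per-condition mean expression profiles
#'
#' Averages log2 intensities within each tissue-by-stage condition, in the
#' fixed order para-tumor I, II, III, tumor I, II, III, and standardizes each
#' feature's profile to mean 0 and standard deviation 1 (the scale on which
#' expression *shapes* are compared). Features missing an entire condition,
#' or with a constant profile, are dropped with a reason.
#'
#' @param qm preprocessed [quant_matrix()].
#' @param ann sample annotation tibble.
#' @param stages stages defining the condition grid (default I--III).
#' @return Object of class `condition_profiles`: list with `profiles`
#'   (feature x condition matrix of standardized means), `raw_means`,
#'   `conditions` (ordered labels), and `dropped` (tibble of feature, reason).
#' @export
condition_means <- function(qm, ann, stages = c("I", "II", "III")) {
  ann <- validate_annotations(ann)
  if (!"stage" %in% names(ann)) stop_design("annotations carry no stage column")
  ann <- ann[!ann$is_internal_standard & ann$sample_id %in% qm_samples(qm), ]
  conds <- as.vector(t(outer(c("para_tumor", "tumor"), stages, paste, sep = "_")))
  cond_of <- paste(ann$tissue, ann$stage, sep = "_")
  keep <- cond_of %in% conds
  ann <- ann[keep, ]; cond_of <- cond_of[keep]
  empty <- setdiff(conds, unique(cond_of))
  if (length(empty)) stop_design("condition(s) with no samples: ",
                                 paste(empty, collapse = ", "))
  lv <- log2(qm$values[, ann$sample_id, drop = FALSE])
  means <- vapply(conds, function(cn) {
    rowMeans(lv[, cond_of == cn, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(lv)))
  if (!is.matrix(means)) {
    means <- matrix(means, nrow = 1, dimnames = list(rownames(lv), conds))
  }
  means[is.nan(means)] <- NA
  miss <- rowSums(is.na(means)) > 0
  sds <- apply(means, 1, stats::sd)
  const <- !miss & sds == 0
  dropped <- tibble::tibble(
    feature_id = rownames(means)[miss | const],
    reason = unname(ifelse(miss[miss | const], "condition_unobserved", "constant_profile")))
  ok <- !miss & !const
  std <- (means[ok, , drop = FALSE] - rowMeans(means[ok, , drop = FALSE])) /
    apply(means[ok, , drop = FALSE], 1, stats::sd)
  structure(list(profiles = std, raw_means = means[ok, , drop = FALSE],
                 conditions = conds, dropped = dropped),
            class = "condition_profiles")
}

#' @export
print.condition_profiles <- function(x, ...) {
  cat("<condition_profiles> ", nrow(x$profiles), " features x ",
      length(x$conditions), " conditions (", nrow(x$dropped), " dropped)\n", sep = "")
  invisible(x)
}

#' Fuzzy c-means soft clustering
#'
#' Standard fuzzy c-means with Euclidean distance on standardized profiles.
#' Each feature receives a membership in `[0, 1]` for every cluster, summing
#' to 1; the fuzzifier `m` controls how soft the assignment is (m -> 1 gives
#' hard k-means-like assignments). Centroids are membership-weighted means
#' with weights `u^m`; memberships follow the inverse-distance-ratio update.
#' A feature exactly at a centroid receives membership 1 for that cluster.
#'
#' The objective `sum_ij u_ij^m d_ij^2` is checked to be non-increasing at
#' every iteration. `restarts` seeded initializations are run (centroids
#' drawn as distinct random profiles) and the best final objective kept, so
#' results are deterministic given `seed`.
#'
#' @param x a `condition_profiles` object or a numeric matrix of
#'   standardized profiles (features in rows).
#' @param c number of clusters.
#' @param m fuzzifier (> 1).
#' @param tol convergence threshold on the maximum membership change.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed for the initializations.
#' @param restarts number of random restarts.
#' @return Object of class `fcm_fit`: list with `membership` (feature x
#'   cluster matrix), `centroids` (cluster x condition), `cluster` (hard
#'   assignment, named integer), `objective` (trace of the kept run),
#'   `n_iter`.
#' @export
fuzzy_cmeans <- function(x, c = 6, m = 2, tol = 1e-6, max_iter = 500,
                         seed = 1, restarts = 5) {
  prof <- if (inherits(x, "condition_profiles")) x$profiles else as.matrix(x)
  n <- nrow(prof)
  if (m <= 1) stop_value("fuzzifier m must be > 1")
  if (c > n) stop_value("c = ", c, " exceeds the ", n, " available profiles")
  if (nrow(unique(prof)) < c) stop_value("fewer than c distinct profiles")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    init <- prof[sample.int(n, c), , drop = FALSE]
    while (nrow(unique(init)) < c) init <- prof[sample.int(n, c), , drop = FALSE]
    fit <- fcm_run(prof, init, m, tol, max_iter)
    if (is.null(best) || fit$objective[length(fit$objective)] <
        best$objective[length(best$objective)]) best <- fit
  }
  hard <- apply(best$u, 1, which.max)
  structure(list(membership = best$u, centroids = best$centroids,
                 cluster = stats::setNames(hard, rownames(prof)),
                 objective = best$objective, n_iter = length(best$objective)),
            class = "fcm_fit")
}

fcm_run <- function(xm, centroids, m, tol, max_iter) {
  n <- nrow(xm); c <- nrow(centroids)
  u <- fcm_memberships(xm, centroids, m)
  obj_trace <- numeric(0)
  obj_prev <- Inf
  for (iter in seq_len(max_iter)) {
    w <- u^m
    centroids <- (t(w) %*% xm) / colSums(w)
    u_new <- fcm_memberships(xm, centroids, m)
    d2 <- pmax(fcm_dist2(xm, centroids), 0)
    obj <- sum(u_new^m * d2)
    if (obj > obj_prev + 1e-8 * max(1, obj_prev)) {
      stop("fuzzy c-means objective increased; numerical fault")
    }
    obj_trace <- c(obj_trace, obj)
    delta <- max(abs(u_new - u))
    u <- u_new
    obj_prev <- obj
    if (delta < tol) break
  }
  rownames(u) <- rownames(xm)
  colnames(u) <- paste0("cluster_", seq_len(c))
  rownames(centroids) <- paste0("cluster_", seq_len(c))
  list(u = u, centroids = centroids, objective = obj_trace)
}

fcm_dist2 <- function(xm, centroids) {
  # squared Euclidean distances, n x c
  outer(rowSums(xm^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(xm)), rowSums(centroids^2)) - 2 * xm %*% t(centroids)
}

fcm_memberships <- function(xm, centroids, m) {
  d2 <- pmax(fcm_dist2(xm, centroids), 0)
  p <- 1 / (m - 1)
  # normalize by the row minimum so the power stays in (0, 1] even for
  # fuzzifiers close to 1 (d^(-p) alone overflows as m -> 1)
  dmin <- apply(d2, 1, min)
  rr <- d2 / pmax(dmin, .Machine$double.xmin)
  inv <- rr^(-p)
  u <- inv / rowSums(inv)
  zero_rows <- which(dmin < .Machine$double.eps)
  for (i in zero_rows) {
    # coincident with a centroid: full membership there
    u[i, ] <- 0
    u[i, which.min(d2[i, ])] <- 1
  }
  u
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("<fcm_fit> ", nrow(x$membership), " features in ", ncol(x$membership),
      " clusters; ", x$n_iter, " iterations, objective ",
      format(x$objective[length(x$objective)], digits = 6), "\n", sep = "")
  print(table(x$cluster))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fcm_fit <- function(x, ...) {
  tibble::tibble(
    feature_id = rownames(x$membership),
    cluster = as.integer(x$cluster),
    max_membership = x$membership[cbind(seq_len(nrow(x$membership)), x$cluster)]
  )
}

#' @exportS3Method generics::glance
glance.fcm_fit <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$membership), n_clusters = ncol(x$membership),
                 n_iter = x$n_iter, objective = x$objective[length(x$objective)])
}

#' Classify a centroid's trend across tumor stages
#'
#' A cluster is reported as `increasing` when its centroid is monotone
#' nondecreasing over the ordered tumor-stage conditions with a total rise
#' greater than `tau` standardized units; `decreasing` is the mirror image;
#' anything else is `non_monotone`. This picks out the clusters whose
#' expression trends with tumor progression.
#'
#' @param centroid numeric centroid over the ordered conditions, or a matrix
#'   of centroids (one per row).
#' @param tumor_idx indices of the tumor-stage conditions in stage order
#'   (default the last three of six).
#' @param tau minimum total change, in standardized units.
#' @return Character vector of trend classes.
#' @export
classify_trend <- function(centroid, tumor_idx = 4:6, tau = 0.5) {
  if (is.matrix(centroid)) {
    return(vapply(seq_len(nrow(centroid)),
                  function(i) classify_trend(centroid[i, ], tumor_idx, tau), ""))
  }
  z <- centroid[tumor_idx]
  d <- diff(z)
  total <- z[length(z)] - z[1]
  if (all(d >= 0) && total > tau) "increasing"
  else if (all(d <= 0) && total < -tau) "decreasing"
  else "non_monotone"
}

#' Summarize clusters by trend class
#'
#' @param fit an `fcm_fit`.
#' @inheritParams classify_trend
#' @return Tibble with one row per cluster: `cluster`, `trend`, `size`,
#'   ordered by trend class then decreasing size.
#' @export
cluster_trends <- function(fit, tumor_idx = 4:6, tau = 0.5) {
  trend <- classify_trend(fit$centroids, tumor_idx, tau)
  tibble::tibble(
    cluster = seq_len(nrow(fit$centroids)),
    trend = trend,
    size = as.integer(table(factor(fit$cluster, levels = seq_len(nrow(fit$centroids)))))
  ) |>
    dplyr::arrange(factor(.data$trend, levels = c("increasing", "decreasing", "non_monotone")),
                   dplyr::desc(.data$size))
}
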