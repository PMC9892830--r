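# Shared fixtures and independent oracles.

`%||%` <- function(x, y) if (is.null(x)) y else x

# small quant matrix with named dims
toy_qm <- function(values, level = "protein", features = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- features %||% paste0("F", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  quant_matrix(m, level)
}

# minimal annotation table: one batch per `batches` entry, samples assigned
# round-robin, IS channel appended per batch
toy_annotation <- function(sample_ids, groups, tissues = "tumor",
                           batch_of = NULL, stages = NULL) {
  n <- length(sample_ids)
  tissues <- rep_len(tissues, n)
  groups <- rep_len(groups, n)
  batch_of <- batch_of %||% rep("B1", n)
  ann <- tibble::tibble(
    sample_id = sample_ids,
    subject_id = paste0("SUB", seq_len(n)),
    tissue = tissues, group = groups,
    batch_id = batch_of,
    channel_id = paste0("ch", seq_len(n)),
    is_internal_standard = FALSE)
  if (!is.null(stages)) ann$stage <- rep_len(stages, n)
  is_rows <- tibble::tibble(
    sample_id = paste0("IS_", unique(batch_of)),
    subject_id = NA_character_, tissue = NA_character_, group = NA_character_,
    batch_id = unique(batch_of), channel_id = "chIS",
    is_internal_standard = TRUE)
  if (!is.null(stages)) is_rows$stage <- NA_character_
  dplyr::bind_rows(ann, is_rows)
}

# brute-force maximal-clique oracle: test every vertex subset
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  is_clique <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    all(adj[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))] == 1)
  }
  cliques <- list()
  for (code in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(idx)) next
    # maximal iff no outside vertex connects to all members
    ext <- setdiff(seq_len(n), idx)
    if (!any(vapply(ext, function(v) all(adj[v, idx] == 1), TRUE))) {
      cliques[[length(cliques) + 1]] <- sort(nodes[idx])
    }
  }
  cliques
}

oracle_mcc <- function(adj) {
  nodes <- rownames(adj)
  s <- stats::setNames(numeric(length(nodes)), nodes)
  for (cl in oracle_max_cliques(adj)) s[cl] <- s[cl] + factorial(length(cl) - 1)
  s
}

random_graph <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n_a * (n_a + 1) / 2
  }
  obs <- u_stat(seq_len(n_a))
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, u_stat)
  mu <- n_a * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# from-scratch chi-square of independence
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - e)^2 / e)
  list(chi2 = chi2, df = (nrow(tab) - 1) * (ncol(tab) - 1),
       p = stats::pchisq(chi2, (nrow(tab) - 1) * (ncol(tab) - 1), lower.tail = FALSE))
}

# from-scratch log-rank (two groups, per distinct event time)
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  tm <- c(time_a, time_b); ev <- c(event_a, event_b)
  grp <- rep(c(1, 0), c(length(time_a), length(time_b)))
  u <- 0; v <- 0
  for (t in sort(unique(tm[ev == 1]))) {
    at_risk <- tm >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(ev == 1 & tm == t); d1 <- sum(ev == 1 & tm == t & grp == 1)
    u <- u + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- u^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# adjusted Rand index between two hard partitions
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  (a - expected) / ((b + c_) / 2 - expected)
}

# small well-separated two-shape profile set (monotone up / monotone down)
planted_profiles <- function(n_per = 50, noise = 0.05, seed = 42) {
  set.seed(seed)
  up <- matrix(rep(seq(-1, 1, length.out = 6), each = n_per), n_per) +
    matrix(stats::rnorm(n_per * 6, 0, noise), n_per)
  down <- matrix(rep(seq(1, -1, length.out = 6), each = n_per), n_per) +
    matrix(stats::rnorm(n_per * 6, 0, noise), n_per)
  prof <- rbind(up, down)
  prof <- (prof - rowMeans(prof)) / apply(prof, 1, stats::sd)
  rownames(prof) <- paste0("F", seq_len(2 * n_per))
  list(profiles = prof, labels = rep(1:2, each = n_per))
}
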