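#' Confidence-filtered induced interaction subgraph
#'
#' Restricts a scored protein--protein interaction graph to a node set
#' (e.g. the upregulated proteins) and keeps edges at or above the
#' confidence threshold; 0.7 is the conventional "high confidence" cutoff
#' of STRING-style combined scores, and the comparison is inclusive.
#' Nodes from the request that are absent from the graph are ignored.
#'
#' @param g an igraph with edge attribute `confidence` (see
#'   [read_edge_list()]).
#' @param nodes character vector of node ids to induce on.
#' @param min_confidence inclusive edge-confidence threshold.
#' @return Induced igraph (requested nodes present in `g` are kept even if
#'   isolated after filtering).
#' @export
induced_subgraph_conf <- function(g, nodes, min_confidence = 0.7) {
  keep <- intersect(nodes, igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, keep)
  igraph::delete_edges(sub, igraph::E(sub)[igraph::E(sub)$confidence < min_confidence])
}

#' Maximal cliques of a graph
#'
#' Enumerates all maximal cliques (complete subgraphs not contained in any
#' larger complete subgraph), including isolated vertices as singleton
#' cliques. A guard refuses graphs whose maximal-clique count explodes.
#'
#' @param g an undirected igraph.
#' @param max_cliques abort if more maximal cliques than this are found.
#' @return List of character vectors of node names, each sorted.
#' @export
maximal_cliques <- function(g, max_cliques = 1e6) {
  if (igraph::vcount(g) == 0) return(list())
  cl <- igraph::max_cliques(g)
  if (length(cl) > max_cliques) {
    stop_value("maximal clique count ", length(cl), " exceeds guard ", max_cliques)
  }
  lapply(cl, function(v) sort(igraph::V(g)$name[v]))
}

#' Maximal clique centrality (MCC)
#'
#' MCC of a node v is `sum over maximal cliques C containing v of (|C|-1)!`.
#' Nodes in large cliques are rewarded factorially, which makes MCC
#' effective at picking out members of densely interconnected cores ("hub"
#' proteins). An isolated node's only maximal clique is itself, giving
#' MCC = (1-1)! = 1.
#'
#' @inheritParams maximal_cliques
#' @return Named numeric vector of MCC scores, one per node.
#' @export
mcc_scores <- function(g, max_cliques = 1e6) {
  nodes <- igraph::V(g)$name
  scores <- stats::setNames(numeric(length(nodes)), nodes)
  for (cl in maximal_cliques(g, max_cliques)) {
    scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  scores
}

#' Top hub nodes by MCC
#'
#' @inheritParams mcc_scores
#' @param k number of hubs to return (all nodes if `k` exceeds the node
#'   count). Ties in score are broken lexicographically by node id for
#'   determinism.
#' @return Tibble with columns `rank`, `node`, `mcc`.
#' @export
top_hubs <- function(g, k = 10, max_cliques = 1e6) {
  s <- mcc_scores(g, max_cliques)
  ord <- order(-s, names(s))
  k <- min(k, length(s))
  idx <- ord[seq_len(k)]
  tibble::tibble(rank = seq_len(k), node = names(s)[idx], mcc = unname(s[idx]))
}

#' Rank hub proteins among a set of interest
#'
#' Convenience wrapper: induce the confidence-filtered subgraph on `nodes`
#' and rank its members by maximal clique centrality.
#'
#' @inheritParams induced_subgraph_conf
#' @inheritParams top_hubs
#' @return Tibble as in [top_hubs()].
#' @export
rank_hubs <- function(g, nodes, min_confidence = 0.7, k = 10) {
  top_hubs(induced_subgraph_conf(g, nodes, min_confidence), k = k)
}
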