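#' Build a thresholded protein-protein interaction network
#'
#' Retains edges whose combined confidence score meets the threshold
#' (inclusive, default 0.700 - the usual high-confidence setting for
#' STRING-style exports), collapses duplicate unordered pairs keeping the
#' maximum score, and drops self-loops with a warning. The resulting graph
#' is simple and unweighted for topology statistics; scores are kept as
#' edge metadata only.
#'
#' @param edge_list data.frame with columns `node_a`, `node_b`,
#'   `combined_score` (scores in \[0, 1\]).
#' @param min_combined Confidence threshold, default 0.700.
#' @param nodes Optional character vector of node ids to include even when
#'   isolated (e.g. an explicit node file).
#' @return An `interaction_network` object: list with `graph` (igraph),
#'   `edges` (retained edge data.frame), `nodes`, `threshold`.
#' @examples
#' el <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
#'                  combined_score = c(0.9, 0.65))
#' net <- build_network(el)
#' igraph::ecount(net$graph)  # 1
#' @export
build_network <- function(edge_list, min_combined = 0.700, nodes = NULL) {
  need <- c("node_a", "node_b", "combined_score")
  if (!all(need %in% names(edge_list)))
    stop("build_network: edge list needs columns node_a, node_b, combined_score")
  bad <- which(is.na(edge_list$node_a) | is.na(edge_list$node_b) |
                 !is.finite(edge_list$combined_score))
  if (length(bad) > 0)
    stop("build_network: malformed edge row(s) at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(edge_list$combined_score < 0 | edge_list$combined_score > 1))
    stop("build_network: combined scores must lie in [0, 1]")

  el <- edge_list
  loops <- el$node_a == el$node_b
  if (any(loops)) {
    warning("build_network: dropping ", sum(loops), " self-loop(s)")
    el <- el[!loops, , drop = FALSE]
  }
  if (nrow(el) > 0) {
    a <- pmin(el$node_a, el$node_b)
    b <- pmax(el$node_a, el$node_b)
    key <- paste(a, b, sep = "\r")
    score <- tapply(el$combined_score, key, max)
    parts <- strsplit(names(score), "\r", fixed = TRUE)
    el <- data.frame(node_a = vapply(parts, `[`, "", 1),
                     node_b = vapply(parts, `[`, "", 2),
                     combined_score = as.numeric(score),
                     stringsAsFactors = FALSE)
    el <- el[el$combined_score >= min_combined, , drop = FALSE]
  }
  all_nodes <- sort(unique(c(el$node_a, el$node_b, nodes)))
  g <- igraph::graph_from_data_frame(
    el[, c("node_a", "node_b")], directed = FALSE,
    vertices = if (length(all_nodes) > 0) all_nodes else NULL
  )
  if (nrow(el) > 0) igraph::E(g)$combined_score <- el$combined_score
  structure(list(graph = g, edges = el, nodes = all_nodes,
                 threshold = min_combined),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "interaction network: %d nodes, %d edges (combined score >= %.3f)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

.check_net <- function(network) {
  if (!inherits(network, "interaction_network"))
    stop("expected an interaction_network (see build_network)")
  if (igraph::vcount(network$graph) == 0L)
    stop("graph is empty (no nodes)")
  network$graph
}

#' Average node degree
#'
#' `2 |E| / |V|` for a simple undirected graph.
#'
#' @param network An `interaction_network`.
#' @return A single number.
#' @export
average_degree <- function(network) {
  g <- .check_net(network)
  2 * igraph::ecount(g) / igraph::vcount(g)
}

#' Network-average local clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient
#' `C_i = 2 T_i / (k_i (k_i - 1))`, where `T_i` counts triangles through
#' node i. Nodes of degree < 2 contribute 0 when `include_low_degree` is
#' TRUE (the common network-average convention) and are excluded from the
#' mean otherwise.
#'
#' @param network An `interaction_network`.
#' @param include_low_degree Count degree-<2 nodes as 0 (default) or drop them.
#' @return A single number (NaN, with a warning, if no node has degree >= 2
#'   under the exclusion variant).
#' @export
avg_clustering <- function(network, include_low_degree = TRUE) {
  g <- .check_net(network)
  ci <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (include_low_degree) {
    ci[is.nan(ci)] <- 0
    mean(ci)
  } else {
    if (all(is.nan(ci))) {
      warning("avg_clustering: no node of degree >= 2")
      return(NaN)
    }
    mean(ci[!is.nan(ci)])
  }
}

#' Top-k hub nodes by degree
#'
#' @param network An `interaction_network`.
#' @param k Number of hubs to return (>= 1). If `k` exceeds the node count,
#'   all nodes are returned with a warning.
#' @return data.frame `node`, `degree`, `rank`, ordered by degree descending
#'   with ties broken by node id ascending.
#' @export
hub_rank <- function(network, k) {
  g <- .check_net(network)
  if (k < 1) stop("hub_rank: k must be >= 1")
  deg <- igraph::degree(g)
  ids <- igraph::V(g)$name %||% as.character(seq_along(deg))
  ord <- order(-deg, ids)
  if (k > length(deg)) {
    warning("hub_rank: k exceeds the number of nodes; returning all")
    k <- length(deg)
  }
  out <- data.frame(node = ids[ord], degree = as.integer(deg[ord]),
                    stringsAsFactors = FALSE)[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Topology report for an interaction network
#'
#' @param network An `interaction_network`.
#' @return A list with `n_nodes`, `n_edges`, `avg_degree`, `avg_clustering`
#'   and a `degree_table` data.frame (all nodes, degree-ranked).
#' @export
network_report <- function(network) {
  g <- .check_net(network)
  list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
       avg_degree = average_degree(network),
       avg_clustering = avg_clustering(network),
       degree_table = hub_rank(network, igraph::vcount(g)))
}
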