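# The nine deterministic topological measures. All operate on binarized
# connectomes; shortest-path based measures share one distance matrix from
# igraph. Disconnected graphs: CPL and closeness are computed over connected
# (reachable) pairs only, efficiency gives unreachable pairs a zero
# contribution, and radiality is undefined (NA) unless the graph is connected
# with diameter >= 2. Undefined results are explicit NA, never silent zeros.

conn_distances <- function(c) {
  igraph::distances(conn_igraph(c))
}

#' Average node degree
#'
#' Mean number of links per node, `AND = sum(d_i) / n` — the simplest node
#' centrality summary. By the handshake identity it equals `2 |E| / n`.
#'
#' @param c A binarized `connectome`.
#' @return A single number.
#' @export
average_node_degree <- function(c) {
  assert_binary(c)
  n <- n_nodes(c)
  if (n == 0) stop("empty graph")
  mean(rowSums(c$adjacency))
}

#' Characteristic path length
#'
#' Mean shortest-path length over unordered node pairs,
#' `CPL = sum_{i<j} sp_ij / (n (n-1) / 2)`. Pairs with no connecting path are
#' excluded from the mean (transiently disconnected functional connectomes
#' would otherwise have to be discarded wholesale).
#'
#' @inheritParams average_node_degree
#' @return A single number; error if no pair of nodes is connected.
#' @export
characteristic_path_length <- function(c) {
  assert_binary(c)
  d <- conn_distances(c)[upper.tri(c$adjacency)]
  d <- d[is.finite(d)]
  if (length(d) == 0) stop("no connected pair of nodes")
  mean(d)
}

#' Average efficiency
#'
#' Mean inverse shortest-path length over unordered pairs,
#' `AE = sum_{i<j} 2 / (n (n-1) sp_ij)`, in `[0, 1]`. Unreachable pairs
#' contribute 0, so the measure is defined on disconnected graphs.
#'
#' @inheritParams average_node_degree
#' @export
average_efficiency <- function(c) {
  assert_binary(c)
  if (n_nodes(c) < 2) stop("empty graph")
  d <- conn_distances(c)[upper.tri(c$adjacency)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

#' Average clustering coefficient
#'
#' Mean local clustering `ACC = (1/n) sum_i t_i / (k_i (k_i - 1) / 2)`, the
#' density of cross-interactions among each node's first neighbours. Nodes of
#' degree below 2 (where the formula is 0/0) contribute 0.
#'
#' @inheritParams average_node_degree
#' @export
average_clustering_coefficient <- function(c) {
  assert_binary(c)
  igraph::transitivity(conn_igraph(c), type = "localaverage",
                       isolates = "zero")
}

#' Average closeness centrality
#'
#' `ACCE = (1/n) sum_i (n-1) / sum_{j != i} sp_ij`. On disconnected graphs
#' each node's closeness is taken over its reachable set (the count of
#' reachable nodes replaces `n - 1`).
#'
#' @inheritParams average_node_degree
#' @export
average_closeness_centrality <- function(c) {
  assert_binary(c)
  d <- conn_distances(c)
  diag(d) <- NA
  cl <- apply(d, 1, function(r) {
    r <- r[is.finite(r) & !is.na(r)]
    if (length(r) == 0) 0 else length(r) / sum(r)
  })
  mean(cl)
}

#' Average node betweenness centrality
#'
#' Mean over nodes of the shortest-path load
#' `sum_{j<k, j,k != i} sigma_jk(i) / sigma_jk` (unordered pairs, endpoints
#' excluded, no further normalization beyond the leading `1/n`).
#'
#' @inheritParams average_node_degree
#' @export
average_node_betweenness <- function(c) {
  assert_binary(c)
  mean(igraph::betweenness(conn_igraph(c), directed = FALSE))
}

#' Average edge betweenness centrality
#'
#' Edge analogue of [average_node_betweenness()]: mean over links of the
#' shortest-path load over unordered pairs (a link counts for the pair made
#' of its own endpoints).
#'
#' @inheritParams average_node_degree
#' @return A single number; error on an edgeless graph.
#' @export
average_edge_betweenness <- function(c) {
  assert_binary(c)
  g <- conn_igraph(c)
  if (igraph::ecount(g) == 0) stop("edgeless graph")
  mean(igraph::edge_betweenness(g, directed = FALSE))
}

#' Average radiality
#'
#' `AR = (1/n) sum_i sum_{j != i} (D + 1 - sp_ij) / (D - 1)` with `D` the
#' graph diameter: how easily each node is reached from the rest of the
#' network. Undefined (`NA`) on disconnected graphs and when `D <= 1`
#' (complete graphs), where the denominator vanishes.
#'
#' @inheritParams average_node_degree
#' @export
average_radiality <- function(c) {
  assert_binary(c)
  d <- conn_distances(c)
  off <- d[upper.tri(d) | lower.tri(d)]
  if (any(!is.finite(off))) return(NA_real_)
  D <- max(off)
  if (D <= 1) return(NA_real_)
  diag(d) <- NA
  mean(rowSums(D + 1 - d, na.rm = TRUE) / (D - 1))
}

#' Common-neighbour and local-community-link arrays
#'
#' For every link whose endpoints share more than one common neighbour, `CN`
#' counts those common neighbours and `LCL` counts the links among them (the
#' cross-interactions inside the local community around the link). The two
#' aligned arrays are the raw material of the local-community-paradigm
#' correlation.
#'
#' @inheritParams average_node_degree
#' @return A list with integer vectors `CN` and `LCL` (possibly empty) and an
#'   `edges` matrix of the qualifying links (1-based node indices, i < j).
#' @export
cn_lcl_arrays <- function(c) {
  assert_binary(c)
  a <- c$adjacency
  e <- conn_edges(c)
  if (nrow(e) == 0)
    return(list(CN = integer(0), LCL = integer(0),
                edges = e))
  cn <- integer(nrow(e))
  lcl <- integer(nrow(e))
  for (k in seq_len(nrow(e))) {
    u <- e[k, 1]; v <- e[k, 2]
    common <- which(a[u, ] > 0 & a[v, ] > 0)
    cn[k] <- length(common)
    lcl[k] <- if (length(common) >= 2)
      sum(a[common, common]) / 2 else 0L
  }
  keep <- cn > 1
  list(CN = cn[keep], LCL = as.integer(lcl[keep]),
       edges = e[keep, , drop = FALSE])
}

#' Local-community-paradigm correlation
#'
#' Pearson correlation between the `CN` and `LCL` arrays of
#' [cn_lcl_arrays()], over all links with more than one common neighbour.
#' High values (> 0.7) signal a network organized in local communities whose
#' common neighbours cross-interact; normal brain connectomes typically score
#' above 0.8. Undefined (`NA`) with fewer than two qualifying links or when
#' either array is constant.
#'
#' @inheritParams average_node_degree
#' @return A number in `[-1, 1]`, or `NA`.
#' @export
lcp_correlation <- function(c) {
  arr <- cn_lcl_arrays(c)
  if (length(arr$CN) < 2) return(NA_real_)
  if (stats::sd(arr$CN) == 0 || stats::sd(arr$LCL) == 0) return(NA_real_)
  stats::cor(arr$CN, arr$LCL)
}
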