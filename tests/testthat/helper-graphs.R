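# Toy graph fixtures built in code, shared across test files.

conn_from_edges <- function(n, edges, node_ids = NULL, regions = NULL) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  connectome(a, node_ids = node_ids, regions = regions, binary = TRUE)
}

k3 <- function() conn_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))
k4 <- function() connectome(matrix(1, 4, 4) - diag(4), binary = TRUE)
k6 <- function() connectome(matrix(1, 6, 6) - diag(6), binary = TRUE)
path_graph <- function(n)
  conn_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
star4 <- function() conn_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
two_triangles <- function()
  conn_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                          c(4, 5), c(4, 6), c(5, 6)))

# K4 on nodes A-D plus E adjacent to A, B, C: the worked local-community
# example (every link's LCL equals its CN minus one).
f6_graph <- function() {
  conn_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                          c(3, 4), c(1, 5), c(2, 5), c(3, 5)),
                  node_ids = LETTERS[1:5])
}

ring_lattice_conn <- function(n, k_per_side) {
  edges <- list()
  for (d in seq_len(k_per_side))
    for (i in seq_len(n))
      edges[[length(edges) + 1]] <- c(i, ((i + d - 1) %% n) + 1)
  conn_from_edges(n, edges)
}

er_conn <- function(n, p_or_m, seed, gnm = FALSE) {
  set.seed(seed)
  g <- if (gnm) igraph::sample_gnm(n, p_or_m) else igraph::sample_gnp(n, p_or_m)
  as_connectome(g)
}

ws_conn <- function(n, nei, beta, seed) {
  set.seed(seed)
  as_connectome(igraph::sample_smallworld(1, n, nei, beta))
}

random_connected_conn <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) return(as_connectome(g))
  }
}

# a small weighted series for I/O tests
random_weighted_series <- function(n_steps = 2, n_mat = 3, n = 4, seed = 1) {
  set.seed(seed)
  ids <- paste0("p", 1:n)
  regions <- stats::setNames(rep(c("S1", "VPL"), length.out = n), ids)
  ens <- lapply(seq_len(n_steps), function(s)
    lapply(seq_len(n_mat), function(k) {
      a <- matrix(0, n, n)
      a[upper.tri(a)] <- round(stats::runif(n * (n - 1) / 2), 6) *
        (stats::runif(n * (n - 1) / 2) > 0.3)
      a <- a + t(a)
      connectome(a, ids, regions)
    }))
  connectome_series(seq_len(n_steps) * 24, ens,
                    stats::runif(n_steps, 10, 60))
}

# shared small synthetic study (cached across tests within one run)
small_study_cache <- new.env()
small_study <- function() {
  if (is.null(small_study_cache$study))
    small_study_cache$study <- generate_study(
      synthetic_config(n_matrices_per_step = 150, keep_middle = 60,
                       seed = 77))
  small_study_cache$study
}
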