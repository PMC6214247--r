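#' Configuration for null-network ensembles
#'
#' Controls the stochastic null models behind the small-worldness indices:
#' how many null realizations are averaged, how many degree-preserving
#' double-edge swaps are attempted per link, and the seed.
#'
#' @param n_realizations Number of null networks averaged (default 10).
#' @param swap_multiplier Attempted swaps per link (default 10).
#' @param seed Integer seed.
#' @return A list of class `null_config`.
#' @export
null_config <- function(n_realizations = 10, swap_multiplier = 10, seed = 1) {
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  if (swap_multiplier < 1) stop("swap_multiplier must be >= 1")
  structure(list(n_realizations = as.integer(n_realizations),
                 swap_multiplier = as.integer(swap_multiplier),
                 seed = as.integer(seed)),
            class = "null_config")
}

edges_to_connectome <- function(edges0, template) {
  n <- n_nodes(template)
  a <- matrix(0, n, n)
  idx <- cbind(edges0[, 1] + 1L, edges0[, 2] + 1L)
  a[idx] <- 1
  a[idx[, c(2, 1), drop = FALSE]] <- 1
  new_connectome(a, template$node_ids, template$regions, binary = TRUE)
}

#' Degree-preserving randomized equivalent
#'
#' Randomizes a binary connectome by double-edge swaps, preserving every node
#' degree exactly. `swap_multiplier * |E|` swaps are attempted; if the input
#' is connected, swaps that would disconnect it are resampled, so
#' connectedness is preserved too. A graph admitting no swap (e.g. a complete
#' graph) is returned unchanged with a warning.
#'
#' @param c A binarized `connectome`.
#' @param cfg A [null_config()]; its `seed` makes the result reproducible.
#' @return A binary `connectome` with the same degree sequence.
#' @export
random_equivalent <- function(c, cfg = null_config()) {
  assert_binary(c)
  e <- conn_edges(c)
  if (nrow(e) < 2) {
    warning("no degree-preserving swap possible; returning input unchanged")
    return(c)
  }
  connected <- igraph::is_connected(conn_igraph(c))
  out <- with_seed(cfg$seed,
    rewire_degseq_cpp(e - 1L, n_nodes(c),
                      cfg$swap_multiplier * nrow(e), connected))
  res <- edges_to_connectome(out, c)
  if (identical(res$adjacency, c$adjacency))
    warning("randomization left the graph unchanged ",
            "(degree sequence may admit a unique graph)")
  res
}

#' Lattice-like equivalent (latticization)
#'
#' Rearranges the links of a binary connectome toward the diagonal band of
#' the adjacency matrix while preserving the degree sequence: double-edge
#' swaps are accepted only when they reduce the total band distance
#' `sum min(|i - j|, n - |i - j|)` over links (a greedy band-compaction; the
#' distance wraps so a ring lattice is a fixed point). The result serves as
#' the lattice null in the small-worldness omega index, whose clustering a
#' lattice-like network should approach.
#'
#' @inheritParams random_equivalent
#' @return A binary `connectome` with the same degree sequence.
#' @export
lattice_equivalent <- function(c, cfg = null_config()) {
  assert_binary(c)
  e <- conn_edges(c)
  if (nrow(e) < 2) {
    warning("no swap possible; returning input unchanged")
    return(c)
  }
  out <- with_seed(cfg$seed,
    latticize_cpp(e - 1L, n_nodes(c), cfg$swap_multiplier * nrow(e)))
  edges_to_connectome(out, c)
}
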