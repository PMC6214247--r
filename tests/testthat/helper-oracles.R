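# Independent brute-force oracles: pure-R breadth-first search, explicit
# shortest-path enumeration, triangle counting and exhaustive partition
# search. Deliberately share no code with the package implementation.

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    level <- 0
    while (length(frontier) > 0) {
      level <- level + 1
      nxt <- integer(0)
      for (v in frontier)
        for (w in which(a[v, ] > 0))
          if (d[s, w] > level) {
            d[s, w] <- level
            nxt <- c(nxt, w)
          }
      frontier <- unique(nxt)
    }
  }
  d
}

oracle_and <- function(a) mean(rowSums(a))

oracle_cpl <- function(a) {
  d <- oracle_distances(a)[upper.tri(a)]
  mean(d[is.finite(d)])
}

oracle_ae <- function(a) {
  d <- oracle_distances(a)[upper.tri(a)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

oracle_acc <- function(a) {
  n <- nrow(a)
  mean(sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    t_i <- sum(a[nb, nb]) / 2
    t_i / (k * (k - 1) / 2)
  }))
}

oracle_acce <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  mean(sapply(seq_len(n), function(i) {
    dd <- d[i, -i]
    dd <- dd[is.finite(dd)]
    if (length(dd) == 0) 0 else length(dd) / sum(dd)
  }))
}

oracle_ar <- function(a) {
  d <- oracle_distances(a)
  off <- d[upper.tri(d)]
  if (any(!is.finite(off))) return(NA_real_)
  D <- max(off)
  if (D <= 1) return(NA_real_)
  n <- nrow(a)
  mean(sapply(seq_len(n), function(i) sum(D + 1 - d[i, -i]) / (D - 1)))
}

# enumerate every shortest path between a pair by walking the BFS
# predecessor structure backwards
all_shortest_paths_pair <- function(a, d, j, k) {
  extend <- function(v) {
    if (v == j) return(list(j))
    preds <- which(a[v, ] > 0 & d[j, ] == d[j, v] - 1)
    out <- list()
    for (u in preds)
      for (pp in extend(u))
        out[[length(out) + 1]] <- c(pp, v)
    out
  }
  extend(k)
}

oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  node_b <- numeric(n)
  edge_b <- matrix(0, n, n)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (!is.finite(d[j, k])) next
    paths <- all_shortest_paths_pair(a, d, j, k)
    sigma <- length(paths)
    for (p in paths) {
      inner <- setdiff(p, c(j, k))
      node_b[inner] <- node_b[inner] + 1 / sigma
      for (s in seq_len(length(p) - 1)) {
        u <- min(p[s], p[s + 1]); v <- max(p[s], p[s + 1])
        edge_b[u, v] <- edge_b[u, v] + 1 / sigma
      }
    }
  }
  list(anbc = mean(node_b),
       aebc = mean(edge_b[a > 0 & upper.tri(a)]))
}

oracle_cn_lcl <- function(a) {
  e <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
  cn <- lcl <- integer(0)
  if (nrow(e) > 0) for (r in seq_len(nrow(e))) {
    common <- intersect(which(a[e[r, 1], ] > 0), which(a[e[r, 2], ] > 0))
    if (length(common) > 1) {
      cn <- c(cn, length(common))
      lcl <- c(lcl, sum(a[common, common]) / 2)
    }
  }
  list(CN = cn, LCL = lcl)
}

# all set partitions of 1..n via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(rgs, maxv) {
    if (length(rgs) == n) {
      out[[length(out) + 1]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) rec(c(rgs, v), max(maxv, v))
  }
  rec(integer(0), 0)
  out
}

oracle_modularity_q <- function(a, membership) {
  m <- sum(a) / 2
  mods <- unique(membership)
  q <- 0
  for (u in mods) {
    idx <- which(membership == u)
    e_uu <- sum(a[idx, idx]) / 2 / m
    a_u <- sum(a[idx, ]) / 2 / m     # total link-end fraction of module u
    q <- q + e_uu - a_u^2
  }
  q
}

oracle_modularity_best <- function(a) {
  parts <- all_partitions(nrow(a))
  max(vapply(parts, function(p) oracle_modularity_q(a, p), 1))
}

# all connected graphs on n nodes up to isomorphism (adjacency matrices)
enumerate_connected_graphs <- function(n) {
  np <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  masks <- 0:(2^np - 1)
  bits <- sapply(0:(np - 1), function(k) (masks %/% 2^k) %% 2)
  keep <- rowSums(bits) >= n - 1
  seen <- new.env(hash = TRUE)
  reps <- list()
  for (r in which(keep)) {
    a <- matrix(0L, n, n)
    a[ut] <- bits[r, ]
    a <- a + t(a)
    reach <- a + diag(n)
    for (s in seq_len(ceiling(log2(n)))) reach <- (reach %*% reach > 0) * 1
    if (any(reach == 0)) next
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    cp <- igraph::canonical_permutation(g)$labeling
    key <- paste(as.vector(igraph::as_adjacency_matrix(
      igraph::permute(g, cp), sparse = FALSE)), collapse = "")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      reps[[length(reps) + 1]] <- a
    }
  }
  reps
}
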