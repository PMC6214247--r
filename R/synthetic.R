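# Synthetic study generator: a latent pain trajectory drives both the
# behavioural signal and the topology of the per-step connectome ensembles.
# The construction plants one positive control (local-community organization,
# i.e. LCP correlation, degraded by degree-preserving randomization as the
# latent rises) and one negative control (average degree, invariant across
# latent values because edge swaps preserve every node degree).

#' Configuration of the synthetic study
#'
#' Defaults emulate the study design: 31 nodes split 15/16 across S1 and
#' VPL, eight recording steps (hour 3 through day 16), 1000 matrices per
#' step of which the middle 400 are kept, and a latent pain trajectory with
#' an acute spike at day 4 followed by a chronic rise and plateau from day
#' 11.
#'
#' @param n_nodes Number of probes/nodes (default 31).
#' @param region_split Named integer vector of nodes per region
#'   (default `c(S1 = 15, VPL = 16)`).
#' @param step_labels Recording labels (default [default_step_labels()]).
#' @param n_matrices_per_step Matrices generated per step (default 1000).
#' @param keep_middle Middle-window size kept per step (default 400).
#' @param latent_trajectory Per-step pain level in `[0, 1]`
#'   (default `c(0.2, 0.9, 0.5, 0.45, 0.6, 0.65, 0.7, 0.7)`).
#' @param scale_grams Von Frey scale: grams at zero latent pain (default 60).
#' @param behavioral_noise_sd Gaussian noise on the behavioural values, in
#'   grams (default 1).
#' @param flip_prob Per-pair link flip probability generating within-step
#'   variability (default 0.02; must be in `[0, 0.5)`).
#' @param swap_budget Maximum degree-preserving swaps applied at latent 1,
#'   as a multiple of the link count (default 0.1, a partial randomization
#'   chosen so that local-community organization degrades gradually over the
#'   whole latent range while staying above the noise floor that the
#'   link-flip variability imposes on ensemble means).
#' @param instability Per-step values in `[0, 1]` scheduling how much each
#'   step's connectivity is independently rewired (turnover) on top of the
#'   shared latent trajectory; default `c(0, 1, 1, 1, 0, 0, 0, 0)` marks the
#'   acute-to-early-chronic steps (days 4-9) as unstable and the late steps
#'   as consolidated. Turnover swaps approximately preserve the LCP
#'   correlation, so the stability schedule is read out by retained-link
#'   counts without disturbing the planted behavioural coupling.
#' @param turnover_budget Turnover swaps at instability 1, as a multiple of
#'   the link count (default 0.08).
#' @param seed Master seed; every random choice cascades from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 31,
                             region_split = c(S1 = 15, VPL = 16),
                             step_labels = default_step_labels(),
                             n_matrices_per_step = 1000,
                             keep_middle = 400,
                             latent_trajectory = c(0.2, 0.9, 0.5, 0.45,
                                                   0.6, 0.65, 0.7, 0.7),
                             scale_grams = 60,
                             behavioral_noise_sd = 1,
                             flip_prob = 0.02,
                             swap_budget = 0.1,
                             instability = c(0, 1, 1, 1, 0, 0, 0, 0),
                             turnover_budget = 0.08,
                             seed = 1) {
  if (sum(region_split) != n_nodes)
    stop("region_split must sum to n_nodes")
  if (keep_middle > n_matrices_per_step)
    stop("keep_middle cannot exceed n_matrices_per_step")
  if (any(latent_trajectory < 0 | latent_trajectory > 1))
    stop("latent values must lie in [0, 1]")
  if (length(latent_trajectory) != length(step_labels))
    stop("one latent value per step required")
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must be in [0, 0.5)")
  if (scale_grams <= 0) stop("scale_grams must be positive")
  if (length(instability) != length(step_labels))
    stop("one instability value per step required")
  if (any(instability < 0 | instability > 1))
    stop("instability values must lie in [0, 1]")
  structure(list(n_nodes = as.integer(n_nodes),
                 region_split = region_split,
                 step_labels = step_labels,
                 n_matrices_per_step = as.integer(n_matrices_per_step),
                 keep_middle = as.integer(keep_middle),
                 latent_trajectory = latent_trajectory,
                 scale_grams = scale_grams,
                 behavioral_noise_sd = behavioral_noise_sd,
                 flip_prob = flip_prob,
                 swap_budget = swap_budget,
                 instability = instability,
                 turnover_budget = turnover_budget,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Behavioural values from the latent pain trajectory
#'
#' Maps latent pain in `[0, 1]` to Von Frey grams:
#' `grams = scale_grams * (1 - latent) + N(0, noise_sd)`. Monotone
#' decreasing in the latent (more pain, lower withdrawal threshold); at zero
#' noise the Spearman correlation with the latent is exactly -1.
#'
#' @param latent Numeric vector in `[0, 1]`.
#' @param scale_grams Positive scale (grams at zero pain).
#' @param noise_sd Gaussian noise standard deviation (grams).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return Numeric vector of grams.
#' @export
behavioral_from_latent <- function(latent, scale_grams = 60, noise_sd = 1,
                                   seed = NULL) {
  if (scale_grams <= 0) stop("scale_grams must be positive")
  if (any(latent < 0 | latent > 1)) stop("latent values must lie in [0, 1]")
  with_seed(seed,
            scale_grams * (1 - latent) + stats::rnorm(length(latent),
                                                      sd = noise_sd))
}

# The structured end-point of the latent interpolation: two region-aligned
# ring-lattice communities (each node linked to its 3 nearest neighbours per
# side within its region) joined by a few inter-region bridges. Ring
# lattices carry strong local-community organization (high LCP correlation).
structured_base <- function(cfg, seed) {
  sizes <- cfg$region_split
  n <- cfg$n_nodes
  node_ids <- paste0("p", seq_len(n))
  regions <- stats::setNames(rep(names(sizes), sizes), node_ids)
  a <- matrix(0, n, n)
  offset <- 0L
  for (sz in sizes) {
    idx <- offset + seq_len(sz)
    for (k in 1:3) {
      for (i in seq_len(sz)) {
        j <- ((i + k - 1L) %% sz) + 1L
        a[idx[i], idx[j]] <- a[idx[j], idx[i]] <- 1
      }
    }
    offset <- offset + sz
  }
  # seeded inter-region bridges (one per ~5 node pairs of the smaller region)
  n1 <- sizes[1]
  with_seed(seed, {
    from <- sample.int(n1, 6)
    to <- n1 + sample.int(n - n1, 6)
    for (b in seq_along(from)) a[from[b], to[b]] <- a[to[b], from[b]] <- 1
  })
  new_connectome(a, node_ids, regions, binary = TRUE)
}

# Build the seeded randomization trajectory: a sequence of double-edge swaps
# from the structured base, each preserving connectivity and accepted only if
# it does not increase the LCP correlation. Filtering the stream this way
# makes local-community degradation monotone along the trajectory, so the
# planted latent -> LCP-corr coupling is well-defined rather than merely a
# trend in expectation. Returns the adjacency after each accepted swap.
build_swap_stream <- function(base, n_swaps, seed,
                              max_attempts = 200L * n_swaps) {
  a <- base$adjacency
  n <- nrow(a)
  states <- vector("list", n_swaps)
  lcp_cur <- lcp_correlation_adj(a)
  with_seed(seed, {
    accepted <- 0L
    attempts <- 0L
    while (accepted < n_swaps && attempts < max_attempts) {
      attempts <- attempts + 1L
      e <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
      pick <- sample.int(nrow(e), 2L)
      flip <- stats::runif(1) < 0.5
      p <- e[pick[1], ]; q <- e[pick[2], ]
      if (flip) q <- rev(q)
      if (p[1] == q[1] || p[2] == q[2]) next
      if (a[p[1], q[1]] > 0 || a[p[2], q[2]] > 0) next
      a2 <- a
      a2[p[1], p[2]] <- a2[p[2], p[1]] <- 0
      a2[q[1], q[2]] <- a2[q[2], q[1]] <- 0
      a2[p[1], q[1]] <- a2[q[1], p[1]] <- 1
      a2[p[2], q[2]] <- a2[q[2], p[2]] <- 1
      if (!is_connected_adj(a2)) next
      lcp_new <- lcp_correlation_adj(a2)
      if (is.na(lcp_new)) lcp_new <- -1 # fully degraded local communities
      if (!is.na(lcp_cur) && lcp_new > lcp_cur) next
      a <- a2
      lcp_cur <- lcp_new
      accepted <- accepted + 1L
      states[[accepted]] <- a
    }
    if (accepted < n_swaps)
      states[(accepted + 1L):n_swaps] <- states[accepted]
  })
  states
}

# Turnover rewiring: double-edge swaps that approximately preserve the LCP
# correlation (|change| <= tol per accepted swap), preserving connectivity
# and degrees. Used to plant per-step instability that retained-link counts
# can read out without disturbing the latent -> LCP coupling.
perturb_preserving_lcp <- function(base, n_swaps, seed, tol = 0.02,
                                   max_attempts = 400L * max(n_swaps, 1L)) {
  if (n_swaps == 0) return(base)
  a <- base$adjacency
  lcp_ref <- lcp_correlation_adj(a)
  with_seed(seed, {
    accepted <- 0L
    attempts <- 0L
    while (accepted < n_swaps && attempts < max_attempts) {
      attempts <- attempts + 1L
      e <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
      pick <- sample.int(nrow(e), 2L)
      flip <- stats::runif(1) < 0.5
      p <- e[pick[1], ]; q <- e[pick[2], ]
      if (flip) q <- rev(q)
      if (p[1] == q[1] || p[2] == q[2]) next
      if (a[p[1], q[1]] > 0 || a[p[2], q[2]] > 0) next
      a2 <- a
      a2[p[1], p[2]] <- a2[p[2], p[1]] <- 0
      a2[q[1], q[2]] <- a2[q[2], q[1]] <- 0
      a2[p[1], q[1]] <- a2[q[1], p[1]] <- 1
      a2[p[2], q[2]] <- a2[q[2], p[2]] <- 1
      if (!is_connected_adj(a2)) next
      lcp_new <- lcp_correlation_adj(a2)
      if (is.na(lcp_new) || is.na(lcp_ref) ||
          abs(lcp_new - lcp_ref) > tol) next
      a <- a2
      accepted <- accepted + 1L
    }
  })
  new_connectome(a, base$node_ids, base$regions, binary = TRUE)
}

# adjacency-level helpers for the generator hot loop
lcp_correlation_adj <- function(a) {
  cc <- new_connectome(a, paste0("n", seq_len(nrow(a))),
                       stats::setNames(rep("R1", nrow(a)),
                                       paste0("n", seq_len(nrow(a)))),
                       binary = TRUE)
  lcp_correlation(cc)
}

is_connected_adj <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(a[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Base connectome at a latent pain level
#'
#' Interpolates between a structured, local-community-rich connectome (two
#' region-aligned ring-lattice communities with inter-region bridges) at
#' latent 0 and a degree-preserving randomization at latent 1, by truncating
#' a seeded trajectory of `swap_budget * |E|` double-edge swaps at
#' `round(latent * swap_budget * |E|)`. The trajectory is shared across
#' latent values for a fixed seed (each is a prefix of the same sequence), so
#' the degree sequence is identical at every latent level, nearby latent
#' levels share most of their links, and the local-community organization
#' (LCP correlation, which the trajectory degrades monotonically by
#' construction) falls as the latent rises.
#'
#' @param latent_value Pain level in `[0, 1]`.
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @param stream Optional precomputed trajectory from the same seed (used
#'   internally to share work across the steps of one study).
#' @return A binarized `connectome`.
#' @export
base_graph <- function(latent_value, cfg = synthetic_config(), seed = 1,
                       stream = NULL) {
  if (latent_value < 0 || latent_value > 1)
    stop("latent value must lie in [0, 1]")
  seeds <- derive_seeds(seed, 2L)
  base <- structured_base(cfg, seeds[1])
  total <- round(cfg$swap_budget * n_links(base))
  n_swaps <- round(latent_value * cfg$swap_budget * n_links(base))
  if (n_swaps == 0) return(base)
  if (is.null(stream)) stream <- build_swap_stream(base, total, seeds[2])
  new_connectome(stream[[n_swaps]], base$node_ids, base$regions,
                 binary = TRUE)
}

#' Noisy ensemble around a base connectome
#'
#' Generates `n` copies of the base connectome with every node pair flipped
#' (link added or removed) independently with probability `flip_prob`,
#' symmetry and zero diagonal preserved: the within-step variability of the
#' short-time-varying matrices.
#'
#' @param base A binarized `connectome`.
#' @param n Number of copies.
#' @param flip_prob Per-pair flip probability in `[0, 0.5)`.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return List of `n` binarized `connectome`s.
#' @export
step_ensemble <- function(base, n, flip_prob = 0.02, seed = NULL) {
  assert_binary(base)
  if (n < 1) stop("n must be >= 1")
  if (flip_prob < 0 || flip_prob >= 0.5) stop("flip_prob must be in [0, 0.5)")
  nn <- n_nodes(base)
  ut <- upper.tri(base$adjacency)
  base_vec <- base$adjacency[ut]
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      flips <- stats::runif(length(base_vec)) < flip_prob
      v <- ifelse(flips, 1 - base_vec, base_vec)
      a <- matrix(0, nn, nn)
      a[ut] <- v
      a <- a + t(a)
      new_connectome(a, base$node_ids, base$regions, binary = TRUE)
    })
  })
}

#' Generate the full synthetic study
#'
#' For each time step: a base connectome at the step's latent pain level,
#' `n_matrices_per_step` noisy copies of it, of which only the middle
#' `keep_middle` are retained (via [middle_window_filter()]); behavioural
#' values from [behavioral_from_latent()]. Everything is deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `series` (a `connectome_series`) and `ground_truth`
#'   (latent trajectory, behavioural mapping parameters, per-step base
#'   connectomes, seeds).
#' @export
generate_study <- function(cfg = synthetic_config()) {
  n_steps <- length(cfg$step_labels)
  hours <- step_hours_from_labels(cfg$step_labels)
  seeds <- derive_seeds(cfg$seed, n_steps + 2L)
  discard <- cfg$n_matrices_per_step - cfg$keep_middle
  d_head <- discard %/% 2L
  d_tail <- discard - d_head
  ensembles <- vector("list", n_steps)
  bases <- vector("list", n_steps)
  # one shared swap trajectory across steps: each step truncates the same
  # randomization sequence at its own latent level, so per-step structure
  # varies smoothly with the latent instead of re-randomizing
  bseeds <- derive_seeds(seeds[1], 2L)
  base0 <- structured_base(cfg, bseeds[1])
  stream <- build_swap_stream(base0, round(cfg$swap_budget * n_links(base0)),
                              bseeds[2])
  tseeds <- derive_seeds(seeds[n_steps + 2L] + 1L, n_steps)
  for (s in seq_len(n_steps)) {
    bases[[s]] <- base_graph(cfg$latent_trajectory[s], cfg, seeds[1],
                             stream = stream)
    turnover <- round(cfg$instability[s] * cfg$turnover_budget *
                        n_links(bases[[s]]))
    bases[[s]] <- perturb_preserving_lcp(bases[[s]], turnover, tseeds[s])
    full <- step_ensemble(bases[[s]], cfg$n_matrices_per_step,
                          cfg$flip_prob, seeds[1L + s])
    ensembles[[s]] <- middle_window_filter(full, d_head, d_tail)
  }
  behavioral <- behavioral_from_latent(cfg$latent_trajectory,
                                       cfg$scale_grams,
                                       cfg$behavioral_noise_sd,
                                       seeds[n_steps + 2L])
  list(series = connectome_series(hours, ensembles, behavioral),
       ground_truth = list(latent_trajectory = cfg$latent_trajectory,
                           instability = cfg$instability,
                           scale_grams = cfg$scale_grams,
                           behavioral_noise_sd = cfg$behavioral_noise_sd,
                           base_graphs = bases,
                           seed = cfg$seed,
                           sub_seeds = seeds))
}
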