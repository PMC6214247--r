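# The five stochastic measures: two small-worldness indices against
# degree-preserving random / lattice nulls, the bootstrap power-law
# goodness-of-fit p-value, modularity of the best heuristic partition, and
# structural consistency (link predictability via first-order eigen
# perturbation). All take explicit seeds; repeated runs with the same seed
# are bit-identical.

sw_ingredients <- function(c, cfg, what = c("rand", "latt")) {
  what <- match.arg(what, several.ok = TRUE)
  seeds <- derive_seeds(cfg$seed, 2 * cfg$n_realizations)
  out <- list()
  if ("rand" %in% what) {
    cr <- lr <- numeric(cfg$n_realizations)
    for (i in seq_len(cfg$n_realizations)) {
      r <- suppressWarnings(random_equivalent(
        c, null_config(1, cfg$swap_multiplier, seeds[i])))
      cr[i] <- average_clustering_coefficient(r)
      lr[i] <- characteristic_path_length(r)
    }
    out$C_rand <- mean(cr); out$L_rand <- mean(lr)
  }
  if ("latt" %in% what) {
    cl <- numeric(cfg$n_realizations)
    for (i in seq_len(cfg$n_realizations)) {
      l <- suppressWarnings(lattice_equivalent(
        c, null_config(1, cfg$swap_multiplier,
                       seeds[cfg$n_realizations + i])))
      cl[i] <- average_clustering_coefficient(l)
    }
    out$C_latt <- mean(cl)
  }
  out
}

#' Small-worldness sigma
#'
#' `sigma = (C / C_rand) / (L / L_rand)`, comparing clustering and
#' characteristic path length against the means over `n_realizations`
#' degree-preserving randomized equivalents. Values above 1 indicate a
#' small-world network (clustering well above random at near-random path
#' length); an Erdos-Renyi-like graph scores near 1. Undefined (`NA`) if the
#' random-null clustering averages to zero.
#'
#' @param c A connected binarized `connectome`.
#' @param cfg A [null_config()].
#' @return A single number or `NA`.
#' @export
smallworldness_sigma <- function(c, cfg = null_config()) {
  assert_binary(c)
  C <- average_clustering_coefficient(c)
  L <- characteristic_path_length(c)
  ing <- sw_ingredients(c, cfg, "rand")
  if (ing$C_rand == 0) return(NA_real_)
  (C / ing$C_rand) / (L / ing$L_rand)
}

#' Small-worldness omega
#'
#' `omega = L_rand / L - C / C_latt`, with the clustering reference taken
#' from a latticized (not random) equivalent, which makes the index robust to
#' fluctuations of the small random-null clustering. Lies in `[-1, 1]` up to
#' sampling noise: near 0 for small-world networks, positive for more random
#' graphs, negative for more lattice-like ones. Undefined (`NA`) if the
#' lattice-null clustering averages to zero.
#'
#' @inheritParams smallworldness_sigma
#' @export
smallworldness_omega <- function(c, cfg = null_config()) {
  assert_binary(c)
  C <- average_clustering_coefficient(c)
  L <- characteristic_path_length(c)
  ing <- sw_ingredients(c, cfg, c("rand", "latt"))
  if (ing$C_latt == 0) return(NA_real_)
  ing$L_rand / L - C / ing$C_latt
}

# ---- discrete power-law fit (Clauset-style) --------------------------------

# Hurwitz-style tail sum: zeta(alpha, x) = sum_{k >= x} k^-alpha, computed by
# explicit summation to `kmax` plus an integral tail correction.
pl_tail_sum <- function(alpha, xs, kmax = 1000L) {
  ks <- seq_len(kmax)
  w <- ks^(-alpha)
  cum <- rev(cumsum(rev(w)))                  # cum[x] = sum_{k=x}^{kmax}
  tail_corr <- kmax^(1 - alpha) / (alpha - 1) # integral beyond kmax
  res <- numeric(length(xs))
  small <- xs <= kmax
  res[small] <- cum[xs[small]] + tail_corr
  res[!small] <- xs[!small]^(1 - alpha) / (alpha - 1)
  res
}

# Fit a discrete power law to positive integer data: for each candidate xmin,
# alpha by the standard discrete MLE approximation
# alpha = 1 + n_tail / sum(log(x / (xmin - 0.5))), then xmin chosen to
# minimize the KS distance between the empirical and fitted tail CDFs.
pl_fit <- function(x, min_tail = 2) {
  x <- as.integer(x[x >= 1])
  cands <- sort(unique(x))
  kmax <- max(1000L, 4L * max(x))
  best <- NULL
  for (xmin in cands) {
    tail <- x[x >= xmin]
    ntail <- length(tail)
    if (ntail < min_tail) next
    denom <- sum(log(tail / (xmin - 0.5)))
    if (denom <= 0) next
    alpha <- 1 + ntail / denom
    if (!is.finite(alpha) || alpha <= 1) next
    # KS over the observed tail support
    vals <- sort(unique(tail))
    emp_cdf <- cumsum(tabulate(tail - xmin + 1L,
                               max(tail) - xmin + 1L))[vals - xmin + 1L] / ntail
    z <- pl_tail_sum(alpha, c(xmin, vals + 1L), kmax)
    # fitted CDF at val = 1 - P(X >= val + 1)
    fit_cdf <- 1 - z[-1] / z[1]
    ks <- max(abs(emp_cdf - fit_cdf))
    if (is.null(best) || ks < best$ks)
      best <- list(alpha = alpha, xmin = xmin, ks = ks, ntail = ntail)
  }
  best
}

# Sample one value from the fitted discrete power law (Clauset's continuous
# approximation rounded to the integer grid).
pl_sample <- function(n, alpha, xmin) {
  u <- stats::runif(n)
  floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
}

#' Power-law goodness-of-fit p-value from a degree sequence
#'
#' Fits a discrete power law to the positive degrees (exponent by maximum
#' likelihood, lower cutoff `xmin` by Kolmogorov-Smirnov minimization) and
#' computes the goodness-of-fit p-value by semi-parametric bootstrap: each of
#' `n_bootstrap` replicates resamples the body of the data empirically and
#' the tail from the fitted law, refits, and the p-value is the fraction of
#' replicates whose KS distance reaches the observed one. The power-law
#' hypothesis is conventionally accepted when `p >= 0.1`.
#'
#' @param degrees Integer vector of node degrees (zeros are excluded from the
#'   fit; the cutoff search starts at 1).
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A p-value in `[0, 1]`, or `NA` if fewer than two distinct positive
#'   degrees are present (degenerate sequence).
#' @export
power_lawness_degrees <- function(degrees, n_bootstrap = 1000, seed = 1) {
  x <- as.integer(degrees[degrees >= 1])
  if (length(unique(x)) < 2) return(NA_real_)
  obs <- pl_fit(x)
  if (is.null(obs)) return(NA_real_)
  n <- length(x)
  body <- x[x < obs$xmin]
  p_tail <- obs$ntail / n
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_bootstrap)) {
      from_tail <- stats::runif(n) < p_tail
      nt <- sum(from_tail)
      rep_x <- integer(n)
      if (nt > 0) rep_x[from_tail] <- pl_sample(nt, obs$alpha, obs$xmin)
      if (nt < n) rep_x[!from_tail] <- sample(body, n - nt, replace = TRUE)
      f <- pl_fit(rep_x)
      if (!is.null(f) && f$ks >= obs$ks) hits <- hits + 1L
    }
    hits / n_bootstrap
  })
}

#' Power-law goodness-of-fit p-value of a connectome
#'
#' Applies [power_lawness_degrees()] to the degree sequence of a binarized
#' connectome.
#'
#' @param c A binarized `connectome`.
#' @param n_bootstrap,seed Passed on to [power_lawness_degrees()].
#' @return A p-value in `[0, 1]`, or `NA` on a degenerate degree sequence.
#' @export
power_lawness <- function(c, n_bootstrap = 1000, seed = 1) {
  assert_binary(c)
  power_lawness_degrees(rowSums(c$adjacency), n_bootstrap, seed)
}

#' Modularity of the best heuristic partition
#'
#' `Q = sum_u [e_uu - (sum_v e_uv)^2]` over the modules `u` of a node
#' partition, where `e_uv` is the fraction of links between modules `u` and
#' `v`. The partition is the best found by seeded heuristics — multilevel
#' Louvain restarts, greedy agglomeration and seeded random partitions,
#' each polished by greedy node moves and community merges, with the
#' single-module partition (`Q = 0`) as floor — so the returned value is in
#' `[-1/2, 1)` and never negative. Values above about 0.3 indicate marked
#' community structure.
#'
#' @param c A binarized `connectome` with at least one link.
#' @param seed Integer seed for the heuristic restarts.
#' @return A single number.
#' @export
modularity_q <- function(c, seed = 1) {
  assert_binary(c)
  g <- conn_igraph(c)
  if (igraph::ecount(g) == 0) stop("edgeless graph")
  e <- conn_edges(c)
  deg <- rowSums(c$adjacency)
  m <- nrow(e)
  q_of <- function(memb) {
    memb <- as.integer(factor(memb))   # consecutive labels, no empty groups
    k <- max(memb)
    same <- memb[e[, 1]] == memb[e[, 2]]
    e_uu <- tabulate(memb[e[, 1]][same], nbins = k) / m
    d_u <- as.vector(rowsum(deg, memb)) / (2 * m)
    sum(e_uu - d_u^2)
  }
  # greedy refinement: single-node moves (including splitting a node off
  # into a fresh singleton community) interleaved with pairwise community
  # merges, until neither improves
  refine <- function(memb) {
    memb <- as.integer(factor(memb))
    q <- q_of(memb)
    repeat {
      improved <- FALSE
      repeat {
        moved <- FALSE
        for (i in seq_along(memb)) {
          targets <- setdiff(unique(c(memb, max(memb) + 1L)), memb[i])
          for (tg in targets) {
            cand <- memb
            cand[i] <- tg
            cand <- as.integer(factor(cand))
            qc <- q_of(cand)
            if (qc > q + 1e-12) {
              memb <- cand
              q <- qc
              moved <- TRUE
              improved <- TRUE
            }
          }
        }
        if (!moved) break
      }
      best_merge <- NULL
      comms <- sort(unique(memb))
      if (length(comms) > 1) {
        for (u in comms) for (v in comms[comms > u]) {
          cand <- memb
          cand[cand == v] <- u
          cand <- as.integer(factor(cand))
          qc <- q_of(cand)
          if (qc > q + 1e-12 &&
              (is.null(best_merge) || qc > best_merge$q)) {
            best_merge <- list(memb = cand, q = qc)
          }
        }
      }
      if (!is.null(best_merge)) {
        memb <- best_merge$memb
        q <- best_merge$q
        improved <- TRUE
      }
      if (!improved) return(list(memb = memb, q = q))
    }
  }
  seeds <- derive_seeds(seed, 10L)
  n <- n_nodes(c)
  cands <- list(rep(1L, n),                # single-module floor (Q = 0)
                seq_len(n))                # all-singletons start
  for (s in seeds[1:3])
    cands[[length(cands) + 1]] <- as.integer(with_seed(
      s, igraph::membership(igraph::cluster_louvain(g))))
  cands[[length(cands) + 1]] <- as.integer(with_seed(
    seeds[4], igraph::membership(igraph::cluster_fast_greedy(g))))
  # seeded random restarts guard against the deterministic starts sharing
  # one basin of attraction
  for (s in seeds[5:10])
    cands[[length(cands) + 1]] <- with_seed(
      s, sample.int(2L + s %% 2L, n, replace = TRUE))
  qs <- vapply(cands, q_of, 1)
  max(qs, vapply(cands, function(cd) refine(cd)$q, 1))
}

#' Structural consistency (link predictability)
#'
#' For each of `n_repeats` repeats, a random fraction `perturb_fraction` of
#' links is removed; the remaining adjacency matrix is eigendecomposed and a
#' first-order perturbed matrix is rebuilt with eigenvalues corrected by
#' `x_k' dA x_k` while keeping the unperturbed eigenvectors. Structural
#' consistency is the fraction of the removed links found among the top
#' `|dE|` non-observed entries of the perturbed matrix, averaged over
#' repeats. Lies in `[0, 1]`: 0 means no link predictability, 1 full
#' predictability.
#'
#' @param c A binarized `connectome` with enough links to remove at least one.
#' @param perturb_fraction Fraction of links removed per repeat (default 0.1).
#' @param n_repeats Number of repeats averaged (default 10).
#' @param seed Integer seed.
#' @return A single number in `[0, 1]`.
#' @export
structural_consistency <- function(c, perturb_fraction = 0.1,
                                   n_repeats = 10, seed = 1) {
  assert_binary(c)
  if (perturb_fraction <= 0 || perturb_fraction >= 1)
    stop("perturb_fraction must be in (0, 1)")
  e <- conn_edges(c)
  m <- nrow(e)
  n_remove <- ceiling(perturb_fraction * m)
  if (m < ceiling(1 / perturb_fraction) || n_remove >= m)
    stop("too few links for the requested perturbation")
  n <- n_nodes(c)
  a <- c$adjacency
  with_seed(seed, {
    vals <- numeric(n_repeats)
    warned <- FALSE
    for (r in seq_len(n_repeats)) {
      rem <- sample.int(m, n_remove)
      da <- matrix(0, n, n)
      idx <- e[rem, , drop = FALSE]
      da[idx] <- 1; da[idx[, c(2, 1), drop = FALSE]] <- 1
      ar <- a - da
      dec <- eigen(ar, symmetric = TRUE)
      if (!warned && any(abs(diff(dec$values)) < 1e-10)) {
        warned <- TRUE
        warning("degenerate eigenvalues in structural consistency; ",
                "relying on the decomposition's deterministic ordering")
      }
      dl <- colSums(dec$vectors * (da %*% dec$vectors))
      at <- dec$vectors %*% ((dec$values + dl) * t(dec$vectors))
      # rank non-observed entries (i < j, not links of the perturbed graph)
      cand <- which(upper.tri(ar) & ar == 0)
      ord <- cand[order(at[cand], decreasing = TRUE)]
      top <- ord[seq_len(n_remove)]
      removed_lin <- (idx[, 2] - 1L) * n + idx[, 1]
      vals[r] <- mean(top %in% removed_lin)
    }
    mean(vals)
  })
}

#' Compute all fourteen topological measures
#'
#' Evaluates the nine deterministic measures and the five stochastic measures
#' of a binarized connectome in one call, deterministic given `cfg$seed`.
#' Measures undefined on the input (radiality on diameter <= 1, LCP
#' correlation on constant arrays, ...) come back as `NA`.
#'
#' @param c A binarized `connectome`.
#' @param cfg A [measure_config()].
#' @return A named numeric vector with elements `AND`, `CPL`, `AE`, `ACC`,
#'   `ACCE`, `ANBC`, `AEBC`, `AR`, `LCPcorr`, `SWsigma`, `SWomega`,
#'   `PLpvalue`, `Q`, `SC`.
#' @export
measure_all <- function(c, cfg = measure_config()) {
  assert_binary(c)
  seeds <- derive_seeds(cfg$seed, 5L)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  ncfg1 <- null_config(cfg$n_realizations, cfg$swap_multiplier, seeds[1])
  ncfg2 <- null_config(cfg$n_realizations, cfg$swap_multiplier, seeds[2])
  out <- c(
    AND = safe(average_node_degree(c)),
    CPL = safe(characteristic_path_length(c)),
    AE = safe(average_efficiency(c)),
    ACC = safe(average_clustering_coefficient(c)),
    ACCE = safe(average_closeness_centrality(c)),
    ANBC = safe(average_node_betweenness(c)),
    AEBC = safe(average_edge_betweenness(c)),
    AR = safe(average_radiality(c)),
    LCPcorr = safe(lcp_correlation(c)),
    SWsigma = safe(suppressWarnings(smallworldness_sigma(c, ncfg1))),
    SWomega = safe(suppressWarnings(smallworldness_omega(c, ncfg2))),
    PLpvalue = safe(power_lawness(c, cfg$n_bootstrap, seeds[3])),
    Q = safe(modularity_q(c, seeds[4])),
    SC = safe(suppressWarnings(structural_consistency(
      c, cfg$perturb_fraction, cfg$sc_repeats, seeds[5]))))
  out
}

#' Names of the fourteen topological measures
#' @return Character vector of measure names in canonical order.
#' @export
measure_names <- function() {
  c("AND", "CPL", "AE", "ACC", "ACCE", "ANBC", "AEBC", "AR", "LCPcorr",
    "SWsigma", "SWomega", "PLpvalue", "Q", "SC")
}

#' Configuration for measure evaluation
#'
#' Bundles the tunables of the stochastic measures: null-ensemble size and
#' swap budget for small-worldness, bootstrap replicates for power-lawness,
#' perturbation fraction and repeat count for structural consistency, and the
#' master seed from which each measure's sub-seed is derived.
#'
#' @param n_realizations,swap_multiplier See [null_config()].
#' @param n_bootstrap Bootstrap replicates for [power_lawness()].
#' @param perturb_fraction,sc_repeats See [structural_consistency()].
#' @param seed Master seed.
#' @return A list of class `measure_config`.
#' @export
measure_config <- function(n_realizations = 10, swap_multiplier = 10,
                           n_bootstrap = 1000, perturb_fraction = 0.1,
                           sc_repeats = 10, seed = 1) {
  structure(list(n_realizations = as.integer(n_realizations),
                 swap_multiplier = as.integer(swap_multiplier),
                 n_bootstrap = as.integer(n_bootstrap),
                 perturb_fraction = perturb_fraction,
                 sc_repeats = as.integer(sc_repeats),
                 seed = as.integer(seed)),
            class = "measure_config")
}

#' Stability check of a stochastic measure
#'
#' Evaluates `measure_fn(c, seed = s_i)` for `k` derived seeds and reports
#' the mean and standard error over the evaluations, the convergence check
#' used to trust the settling value of a stochastic measure (its standard
#' error should be small against the mean).
#'
#' @param measure_fn Function of `(c, seed)` returning one number.
#' @param c A binarized `connectome`.
#' @param k Number of evaluations (>= 2).
#' @param seed Master seed.
#' @return A list with `mean`, `se` and the `values` drawn.
#' @export
stability_check <- function(measure_fn, c, k = 10, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  seeds <- derive_seeds(seed, k)
  vals <- vapply(seeds, function(s) measure_fn(c, seed = s), 1)
  if (all(is.na(vals))) stop("measure undefined on this connectome")
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(length(vals)),
       values = vals)
}
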