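test_that("synthetic config validates its invariants", {
  expect_error(synthetic_config(n_nodes = 30), "sum to n_nodes")
  expect_error(synthetic_config(keep_middle = 2000), "cannot exceed")
  expect_error(synthetic_config(latent_trajectory = rep(2, 8)), "\\[0, 1\\]")
  expect_error(synthetic_config(flip_prob = 0.6), "flip_prob")
  expect_error(synthetic_config(instability = c(1, 0)), "per step")
})

test_that("behavioural mapping is monotone decreasing in the latent", {
  expect_equal(behavioral_from_latent(0, 60, noise_sd = 0, seed = 1), 60)
  g <- behavioral_from_latent(c(0, 1, 0.5), 60, noise_sd = 0, seed = 1)
  expect_equal(order(g), c(2, 3, 1))             # high pain -> low grams
  # default acute-dip trajectory bottoms out at step 2 (day 4)
  cfg <- synthetic_config()
  g2 <- behavioral_from_latent(cfg$latent_trajectory, cfg$scale_grams,
                               noise_sd = 0)
  expect_equal(which.min(g2), 2L)
  expect_equal(cor(g2, cfg$latent_trajectory, method = "spearman"), -1)
  expect_error(behavioral_from_latent(0.5, -2), "positive")
})

test_that("base graphs plant the latent/local-community coupling", {
  cfg <- synthetic_config()
  lcp0 <- sapply(1:10, function(s) lcp_correlation(base_graph(0, cfg, s)))
  expect_true(all(lcp0 > 0.7))                   # community-rich end point
  drops <- sapply(1:10, function(s) {
    l1 <- lcp_correlation(base_graph(1, cfg, s))
    is.na(l1) || l1 < lcp0[s]
  })
  expect_gte(sum(drops), 9)
  # degree sequence identical across latent values for a fixed seed
  b0 <- base_graph(0, cfg, 3); b1 <- base_graph(1, cfg, 3)
  expect_equal(rowSums(b0$adjacency), rowSums(b1$adjacency))
})

test_that("step ensembles apply seeded independent link flips", {
  base <- base_graph(0.3, synthetic_config(), 5)
  same <- step_ensemble(base, 4, flip_prob = 0, seed = 1)
  for (cc in same) expect_identical(cc$adjacency, base$adjacency)
  ens <- step_ensemble(base, 400, flip_prob = 0.05, seed = 2)
  expect_identical(step_ensemble(base, 2, 0.05, seed = 9)[[1]]$adjacency,
                   step_ensemble(base, 2, 0.05, seed = 9)[[1]]$adjacency)
  # flipped-pair count matches the binomial expectation within 3 sd
  n_pairs <- 31 * 30 / 2
  flips <- sapply(ens, function(cc)
    sum(cc$adjacency[upper.tri(cc$adjacency)] !=
          base$adjacency[upper.tri(base$adjacency)]))
  expected <- 0.05 * n_pairs
  expect_lt(abs(mean(flips) - expected),
            3 * sqrt(0.05 * 0.95 * n_pairs / 400))
})

test_that("the default study has the study-design shape", {
  study <- generate_study(synthetic_config(seed = 42))
  s <- study$series
  expect_length(s$step_hours, 8)
  expect_equal(s$step_hours, c(3, 96, 144, 216, 264, 288, 360, 384))
  expect_true(all(vapply(s$ensembles, length, 1L) == 400))
  expect_equal(length(s$ensembles[[1]][[1]]$node_ids), 31)
  expect_equal(as.vector(table(s$ensembles[[1]][[1]]$regions)[c("S1", "VPL")]),
               c(15L, 16L))
  expect_length(study$ground_truth$base_graphs, 8)
})

test_that("study generation is deterministic and round-trips through disk", {
  cfg <- synthetic_config(n_matrices_per_step = 8, keep_middle = 4,
                          seed = 13)
  s1 <- generate_study(cfg)$series
  s2 <- generate_study(cfg)$series
  for (st in seq_along(s1$ensembles))
    for (k in seq_along(s1$ensembles[[st]]))
      expect_identical(s1$ensembles[[st]][[k]]$adjacency,
                       s2$ensembles[[st]][[k]]$adjacency)
  expect_identical(s1$behavioral, s2$behavioral)
  dir <- withr::local_tempdir()
  man <- write_series(s1, dir)
  s3 <- read_series(man)
  expect_equal(s3$behavioral, s1$behavioral)
  expect_identical(s3$ensembles[[3]][[2]]$adjacency,
                   s1$ensembles[[3]][[2]]$adjacency)
})
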