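test_that("step summaries average the measure over the ensemble", {
  ens <- replicate(5, k3(), simplify = FALSE)
  sm <- summarize_step(ens, "AND")
  expect_equal(sm$mean, 2)
  expect_equal(sm$se, 0)

  set.seed(3)
  ens2 <- lapply(1:8, function(i) er_conn(12, 0.4, i + 70))
  direct <- sapply(ens2, average_node_degree)
  sm2 <- summarize_step(ens2, "AND")
  expect_equal(sm2$mean, mean(direct))
  expect_equal(sm2$se, sd(direct) / sqrt(length(direct)))

  # AR undefined on every member (complete graphs) is an error
  expect_error(summarize_step(replicate(3, k3(), simplify = FALSE), "AR"),
               "undefined on every")
  expect_error(summarize_step(list(), "AND"), "empty ensemble")
})

test_that("day labels map onto the hourly schedule", {
  expect_equal(step_hours_from_labels(default_step_labels()),
               c(3, 96, 144, 216, 264, 288, 360, 384))
  expect_equal(step_hours_from_labels("3 h"), 3)
  expect_equal(step_hours_from_labels("16 days"), 384)
  expect_error(step_hours_from_labels(c("4 days", "3 h")), "increasing")
  expect_error(step_hours_from_labels("soon"), "unparseable")
})

test_that("the interpolant honours its shape-preserving contract", {
  hours <- c(3, 96, 144, 216, 264, 288, 360, 384)
  set.seed(12)
  vals <- rnorm(8)
  sig <- pchip_interpolate(hours, vals)
  expect_length(sig$values, 382)
  # knots reproduced exactly
  expect_equal(sig$values[match(hours, sig$grid_hours)], vals,
               tolerance = 1e-12)
  # linear data reproduced exactly
  lin <- pchip_interpolate(hours, 2 * hours + 1)
  expect_equal(lin$values, 2 * lin$grid_hours + 1, tolerance = 1e-12)
  # monotone samples stay monotone on the full grid
  mono <- pchip_interpolate(hours, sort(vals))
  expect_true(all(diff(mono$values) >= -1e-12))
  # no overshoot: each interval bounded by its local sample range
  for (i in 1:7) {
    inside <- sig$grid_hours >= hours[i] & sig$grid_hours <= hours[i + 1]
    lo <- min(vals[i:(i + 1)]); hi <- max(vals[i:(i + 1)])
    expect_true(all(sig$values[inside] >= lo - 1e-9 &
                      sig$values[inside] <= hi + 1e-9))
  }
  expect_error(pchip_interpolate(hours, vals, grid_hours = 0:10),
               "no extrapolation")
  expect_error(pchip_interpolate(hours[1], vals[1]), "at least 2")
  expect_error(pchip_interpolate(hours, c(vals[-1], NA)), "undefined")
})

test_that("correlation of interpolated signals behaves as expected", {
  hours <- c(0, 10, 25, 40)
  a <- pchip_interpolate(hours, c(1, 3, 2, 5))
  expect_equal(unname(correlate(a, a)), c(1, 1))
  neg <- a; neg$values <- -a$values
  expect_equal(unname(correlate(a, neg)), c(-1, -1))
  inc <- pchip_interpolate(hours, c(1, 2, 3, 6))
  mono <- inc; mono$values <- exp(inc$values)
  cc <- correlate(inc, mono)
  expect_equal(unname(cc["spearman"]), 1)
  expect_lt(cc["pearson"], 1)
  flat <- a; flat$values <- rep(1, length(a$values))
  expect_error(correlate(a, flat), "zero-variance")
})

test_that("null behavioural models have the stated distributions", {
  g <- null_behavioral_G(10000, seed = 4)
  expect_lt(abs(mean(g)), 0.05)
  expect_lt(abs(var(g) - 1), 0.05)
  expect_identical(null_behavioral_G(8, seed = 9), null_behavioral_G(8, seed = 9))
  expect_length(null_behavioral_G(8, seed = 1), 8)

  x <- c(5, 1, 9, 2)
  perm <- null_behavioral_DP(x, seed = 2)
  expect_equal(sort(perm), sort(x))
  expect_identical(null_behavioral_DP(x, seed = 2), perm)
  # permutation orders cover the space uniformly (chi-square at n = 3)
  set.seed(8)
  counts <- table(replicate(60000, paste(null_behavioral_DP(1:3, NULL),
                                         collapse = "")))
  expect_length(counts, 6)
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("significance test follows the printed two-tailed formula", {
  hours <- c(3, 96, 144, 216, 264, 288, 360, 384)
  set.seed(5)
  topo <- sort(rnorm(8))
  # identical signals: observed pearson is 1, above every null draw
  res <- interpolation_significance_test(topo, topo, hours, model = "G",
                                         M = 200, corr_type = "pearson",
                                         seed = 3)
  expect_equal(res$c, 1)
  expect_equal(res$p, 0)
  expect_gt(res$p_cc, 0)
  expect_length(res$null$correlations, 200)
  # deterministic given the seed
  res2 <- interpolation_significance_test(topo, topo, hours, model = "G",
                                          M = 200, corr_type = "pearson",
                                          seed = 3)
  expect_identical(res2$p, res$p)
  expect_identical(res2$null$correlations, res$null$correlations)
  # DP model draws permutations of the behavioural values
  behav <- rnorm(8)
  resdp <- interpolation_significance_test(topo, behav, hours, model = "DP",
                                           M = 150, corr_type = "spearman",
                                           seed = 6)
  expect_gte(resdp$p, 0)
  expect_lte(resdp$p, 1)
  expect_error(interpolation_significance_test(topo, behav, hours, M = 50),
               "below minimum")
})

test_that("summary table recovers the planted marker on a small study", {
  study <- small_study()
  cfg <- measure_config(seed = 5)
  tcs <- list(measure_timecourse(study$series, "LCPcorr", cfg),
              measure_timecourse(study$series, "AND", cfg))
  st <- summary_table(study$series, cfg, measures = c("LCPcorr", "AND"),
                      M = 500, seed = 6, timecourses = tcs)
  expect_lte(nrow(st), 14)
  expect_named(st, c("measure", "pearson", "spearman", "p_G_pearson",
                     "p_G_spearman", "p_DP_pearson", "p_DP_spearman",
                     "max_correlation", "max_p", "significant"))
  lcp <- st[st$measure == "LCPcorr", ]
  expect_gt(abs(lcp$max_correlation), 0.8)
  expect_lt(lcp$max_p, 0.05)
  # max correlation is the larger in absolute value, sign retained
  expect_equal(lcp$max_correlation,
               c(lcp$pearson, lcp$spearman)[which.max(abs(
                 c(lcp$pearson, lcp$spearman)))])
  # conclusions robust to the interpolation scheme
  st_lin <- summary_table(study$series, cfg, measures = c("LCPcorr", "AND"),
                          M = 500, seed = 6, timecourses = tcs,
                          interp_fn = linear_interpolate)
  expect_equal(st_lin$significant, st$significant)
})

test_that("constant-over-time measures are excluded with a note", {
  study <- small_study()
  cfg <- measure_config(seed = 5)
  tc <- measure_timecourse(study$series, "AND", cfg)
  tc$means <- rep(2, length(tc$means)) # force a flat curve
  st <- summary_table(study$series, cfg, measures = "AND", M = 200,
                      seed = 1, timecourses = list(tc))
  expect_equal(nrow(st), 0)
  expect_match(attr(st, "excluded"), "zero variance")
})
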