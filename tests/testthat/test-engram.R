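test_that("hour labels match the study figure conventions", {
  expect_equal(hour_label(c(3, 96, 384)), c("3 h", "4d", "16d"))
})

test_that("representative selection minimizes distance to the mean LCP", {
  ens <- list(k3(), f6_graph(), k4())
  one <- representative_connectome(list(f6_graph()))
  expect_equal(attr(one, "index"), 1)
  r <- representative_connectome(ens, lcp_values = c(0.2, 0.5, 0.8))
  expect_equal(attr(r, "index"), 2)              # mean is 0.5
  rt <- representative_connectome(ens[1:2], lcp_values = c(0, 1))
  expect_equal(attr(rt, "index"), 1)             # tie -> first
  expect_error(representative_connectome(ens, lcp_values = rep(NA_real_, 3)),
               "no defined LCP")
})

test_that("region link counts partition the edge set", {
  regions2 <- function(n1, n2) {
    ids <- paste0("p", seq_len(n1 + n2))
    stats::setNames(rep(c("S1", "VPL"), c(n1, n2)), ids)
  }
  # complete bipartite across regions
  a <- matrix(0, 5, 5)
  a[1:2, 3:5] <- 1; a <- a + t(a) - diag(diag(a))
  cb <- connectome((a > 0) * 1, paste0("p", 1:5), regions2(2, 3),
                   binary = TRUE)
  counts <- region_link_counts(cb)
  expect_equal(unname(counts["intra_S1"]), 0L)
  expect_equal(unname(counts["intra_VPL"]), 0L)
  expect_equal(unname(counts["inter"]), 6L)
  # two intra-region triangles, no cross links
  tt <- two_triangles()
  tt2 <- connectome(tt$adjacency, paste0("p", 1:6), regions2(3, 3),
                    binary = TRUE)
  counts2 <- region_link_counts(tt2)
  expect_equal(unname(counts2["inter"]), 0L)
  expect_equal(sum(counts2), n_links(tt2))
  # random graph: counts match brute-force edge classification
  set.seed(6)
  c31 <- er_conn(31, 0.2, 44)
  c31 <- connectome(c31$adjacency, paste0("p", 1:31), regions2(15, 16),
                    binary = TRUE)
  counts3 <- region_link_counts(c31)
  e <- which(c31$adjacency > 0 & upper.tri(c31$adjacency), arr.ind = TRUE)
  brute_inter <- sum((e[, 1] <= 15) != (e[, 2] <= 15))
  expect_equal(unname(counts3["inter"]), brute_inter)
  expect_equal(sum(counts3), nrow(e))
})

test_that("retained links are the edge-set intersection, classified by region", {
  g1 <- small_study()$series$ensembles[[1]][[1]]
  g2 <- small_study()$series$ensembles[[2]][[1]]
  same <- retained_links(g1, g1)
  expect_equal(unname(same$counts["full"]), n_links(g1))
  r12 <- retained_links(g1, g2, label = "a/b")
  expect_lte(r12$counts["full"], min(n_links(g1), n_links(g2)))
  r21 <- retained_links(g2, g1)
  expect_equal(unname(r12$counts), unname(r21$counts))
  # disjoint graphs retain nothing
  ids <- g1$node_ids; regs <- g1$regions
  e1 <- conn_from_edges(31, list(c(1, 2)), ids, regs)
  e2 <- conn_from_edges(31, list(c(3, 4)), ids, regs)
  expect_equal(unname(retained_links(e1, e2)$counts["full"]), 0L)
  expect_error(retained_links(g1, k3()), "mismatch")
})

test_that("engram time course flags consolidation in the final phase", {
  study <- small_study()
  eng <- engram_timecourse(study$series)
  expect_length(eng$retained, 7)                  # 8 steps -> 7 intervals
  expect_equal(eng$retained[[1]]$label, "3 h/4d")
  # counts satisfy the region sum invariant at every step
  for (s in seq_len(nrow(eng$region_counts))) {
    rc <- eng$region_counts[s, ]
    expect_equal(rc$intra_S1 + rc$intra_VPL + rc$inter,
                 n_links(eng$representatives[[s]]))
  }
  ret <- sapply(eng$retained, function(r) unname(r$counts["full"]))
  # planted instability (days 4-9) vs consolidation (day 11 onward)
  expect_gt(min(ret[5:7]), max(ret[2:4]))
  # a 2-step series yields exactly one retained record
  sub <- connectome_series(study$series$step_hours[1:2],
                           study$series$ensembles[1:2],
                           study$series$behavioral[1:2])
  expect_length(engram_timecourse(sub)$retained, 1)
})
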