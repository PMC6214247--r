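test_that("connectome construction enforces the adjacency invariants", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.5
  expect_s3_class(connectome(a), "connectome")

  bad <- a; bad[1, 2] <- -0.1
  expect_error(connectome(bad), "negative weight")
  asym <- a; asym[1, 2] <- 0.5 + 1e-6
  expect_error(connectome(asym), "not symmetric")
  diagw <- a; diag(diagw) <- 1
  expect_error(connectome(diagw), "diagonal")
  expect_error(connectome(a, regions = c(p9 = "S1")), "cover every node")
  expect_error(connectome(a, binary = TRUE), "0/1")
})

test_that("binarize keeps links strictly above the threshold and is idempotent", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.2
  a[1, 3] <- a[3, 1] <- 0.9
  cw <- connectome(a)
  b0 <- binarize(cw, 0)
  expect_equal(n_links(b0), 2)
  expect_true(b0$binary)
  b5 <- binarize(cw, 0.5)
  expect_equal(n_links(b5), sum(a[upper.tri(a)] > 0.5))
  expect_equal(n_links(binarize(cw, 1)), 0)         # threshold >= max weight
  expect_identical(binarize(b5, 0)$adjacency, b5$adjacency) # idempotence
  expect_error(binarize(cw, -1), "non-negative")
})

test_that("middle window filter drops exactly the head and the tail", {
  expect_length(middle_window_filter(as.list(1:1000), 300, 300), 400)
  expect_identical(middle_window_filter(as.list(1:10), 0, 0), as.list(1:10))
  expect_identical(middle_window_filter(as.list(1:7), 3, 3), list(4L))
  expect_error(middle_window_filter(as.list(1:5), 3, 3), "too short")
  # length postcondition over random cases
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    h <- sample(0:2, 1); t <- sample(0:2, 1)
    expect_length(middle_window_filter(as.list(seq_len(n)), h, t), n - h - t)
  }
})

test_that("write/read series round-trip is lossless", {
  s <- random_weighted_series(seed = 1)
  dir <- withr::local_tempdir()
  man <- write_series(s, dir)
  s2 <- read_series(man)
  expect_equal(s2$step_hours, s$step_hours)
  expect_equal(s2$behavioral, s$behavioral)
  for (st in seq_along(s$ensembles))
    for (k in seq_along(s$ensembles[[st]]))
      expect_identical(s2$ensembles[[st]][[k]]$adjacency,
                       s$ensembles[[st]][[k]]$adjacency)
  expect_identical(s2$ensembles[[1]][[1]]$regions,
                   s$ensembles[[1]][[1]]$regions)
})

test_that("read_series rejects invalid inputs", {
  s <- random_weighted_series(seed = 2, n_steps = 1, n_mat = 1)
  dir <- withr::local_tempdir()
  man <- write_series(s, dir)
  # corrupt one matrix with a negative entry
  f <- list.files(dir, pattern = "step.*txt", full.names = TRUE)[1]
  writeLines(gsub("^0 ", "-0.1 ", readLines(f)), f)
  expect_error(read_series(man), "negative weight")
  expect_error(read_series(file.path(dir, "nope.json")), "missing manifest")
  # shape mismatch
  s2dir <- withr::local_tempdir()
  man2 <- write_series(s, s2dir)
  f2 <- list.files(s2dir, pattern = "step.*txt", full.names = TRUE)[1]
  writeLines(readLines(f2)[-1], f2)
  expect_error(read_series(man2), "shape mismatch")
})

test_that("series constructor validates shape and ordering", {
  s <- random_weighted_series(seed = 3)
  expect_error(connectome_series(c(24, 24), s$ensembles, s$behavioral),
               "strictly increasing")
  expect_error(connectome_series(s$step_hours, list(list(), list()),
                                 s$behavioral), "empty ensemble")
  expect_error(connectome_series(s$step_hours, s$ensembles, 1),
               "one behavioral value")
})

test_that("behavioral signal exports as a two-column CSV", {
  s <- random_weighted_series(seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_behavioral_csv(s, f)
  df <- read.csv(f)
  expect_named(df, c("hours", "grams"))
  expect_equal(df$grams, s$behavioral)
})
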