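make_signals <- function(seed = 1, n = 6, p = 40) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  rownames(m) <- paste0("s", seq_len(n))
  m
}

test_that("row z-scoring standardizes, is idempotent and rejects constants", {
  m <- make_signals(1)
  z <- zscore_rows(m)
  expect_equal(unname(rowMeans(z)), rep(0, nrow(m)), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(m)), tolerance = 1e-9)
  expect_equal(zscore_rows(z), z, ignore_attr = TRUE)
  bad <- rbind(m, const = rep(2, ncol(m)))
  expect_error(zscore_rows(bad), "constant row")
})

test_that("sign alignment leaves no negative correlation with the reference", {
  m <- make_signals(2)
  rownames(m)[1] <- "VonFrey"
  m[2, ] <- -m["VonFrey", ]           # perfectly anti-correlated
  m[3, ] <- m["VonFrey", ]
  al <- sign_align(m, "VonFrey")
  expect_equal(al[2, ], m["VonFrey", ], ignore_attr = TRUE)
  expect_equal(al[3, ], m[3, ], ignore_attr = TRUE)
  cors <- apply(al, 1, function(r) cor(r, al["VonFrey", ]))
  expect_true(all(cors >= 0))
  expect_true("s2" %in% attr(al, "flipped"))
  expect_error(sign_align(m, "nope"), "not found")
})

test_that("PCA embedding orders variance and maps duplicates together", {
  m <- make_signals(3, n = 8)
  m[2, ] <- m[1, ]
  co <- pca_embed(m)
  expect_equal(co[1, ], co[2, ], ignore_attr = TRUE)
  v <- attr(co, "variances")
  expect_gte(v[1], v[2])
  expect_error(pca_embed(m[1:2, , drop = FALSE]), "at least 3")
  expect_error(pca_embed(m, dims = 50), "rank")
})

test_that("PCA separates two planted signal clusters", {
  set.seed(9)
  base1 <- rnorm(60); base2 <- rnorm(60)
  m <- rbind(t(replicate(5, base1 + rnorm(60, 0, 0.2))),
             t(replicate(5, base2 + rnorm(60, 0, 0.2))))
  rownames(m) <- paste0("s", 1:10)
  co <- pca_embed(zscore_rows(m))
  lab <- rep(1:2, each = 5)
  d <- as.matrix(dist(co))
  sil <- sapply(1:10, function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0.5)
})

test_that("quantile normalization equalizes row distributions, keeps ranks", {
  m <- make_signals(4)
  qn <- quantile_normalize_rows(m)
  sorted <- apply(qn, 1, sort)
  for (i in 2:nrow(m))
    expect_equal(sorted[, i], sorted[, 1], ignore_attr = TRUE)
  for (i in seq_len(nrow(m)))
    expect_equal(cor(m[i, ], qn[i, ], method = "spearman"), 1)
  expect_true(attr(qn, "quantile_normalized"))
})

test_that("the MC-kernel is a tree metric and the embedding needs the flag", {
  m <- make_signals(5)
  expect_error(mce_embed(m), "quantile-normalized")
  qn <- quantile_normalize_rows(m)
  co <- mce_embed(qn)
  k <- attr(co, "kernel")
  expect_equal(k, t(k))
  expect_equal(unname(diag(k)), rep(0, nrow(m)))
  # three collinear points: kernel distances accumulate along the chain
  x <- rbind(a = rep(0, 10), b = rep(1, 10), c = rep(2, 10))
  attr(x, "quantile_normalized") <- TRUE
  kc <- attr(mce_embed(x), "kernel")
  expect_equal(kc["a", "c"], kc["a", "b"] + kc["b", "c"])
  # degenerate: identical rows everywhere
  same <- matrix(1, 4, 6)
  attr(same, "quantile_normalized") <- TRUE
  expect_error(mce_embed(same), "degenerate")
})

test_that("embeddings are equivariant under row permutation", {
  m <- make_signals(6, n = 7)
  qn <- quantile_normalize_rows(m)
  co <- mce_embed(qn)
  set.seed(2)
  perm <- sample(nrow(m))
  co_p <- mce_embed(quantile_normalize_rows(m[perm, ]))
  # kernels agree up to the permutation; axes may flip sign
  expect_equal(attr(co_p, "kernel"),
               attr(co, "kernel")[perm, perm])
  for (d in 1:2)
    expect_true(isTRUE(all.equal(co_p[, d], co[perm, d])) ||
                  isTRUE(all.equal(co_p[, d], -co[perm, d])))
})

test_that("MCE recovers a warped one-dimensional latent ordering", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    tgrid <- seq(0, 1, length.out = 200)
    theta <- seq(0, 1, length.out = 15)
    mu <- theta^2                      # nonlinear warp of the latent
    m <- t(sapply(mu, function(u) exp(-(tgrid - u)^2 / (2 * 0.25^2)))) +
      matrix(rnorm(15 * 200, 0, 0.02), 15)
    rownames(m) <- paste0("s", 1:15)
    co <- mce_embed(quantile_normalize_rows(m))
    rho <- max(abs(cor(co[, 1], theta, method = "spearman")),
               abs(cor(co[, 2], theta, method = "spearman")))
    hits <- hits + (rho > 0.9)
  }
  expect_equal(hits, 5)
})
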