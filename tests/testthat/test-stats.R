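test_that("variance explained is 1 for rank-5 mixtures and n = d", {
  B <- synthetic_basis()
  set.seed(41)
  mix <- matrix(rexp(200 * 5), 200, 5) %*% t(B$matrix)  # rank <= 5, d = 310
  res <- pca_variance_explained(mix, 5)
  expect_equal(res$variance_explained, 1, tolerance = 1e-10)

  X <- matrix(rnorm(40 * 6), 40, 6)
  expect_equal(pca_variance_explained(X, 6)$variance_explained, 1,
               tolerance = 1e-12)
})

test_that("PCA matches a direct covariance-eigendecomposition oracle", {
  set.seed(42)
  X <- matrix(rnorm(50 * 8), 50, 8)
  res <- pca_variance_explained(X, 3)
  ev <- sort(eigen(cov(scale(X, scale = FALSE)), symmetric = TRUE)$values,
             decreasing = TRUE)
  expect_equal(res$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(res$variance_explained, sum(ev[1:3]) / sum(ev),
               tolerance = 1e-10)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
})

test_that("variance explained is monotone non-decreasing in n", {
  set.seed(43)
  X <- matrix(rnorm(80 * 6), 80, 6) + matrix(rnorm(80), 80, 6)
  ve <- vapply(1:6, function(n) {
    pca_variance_explained(X, n)$variance_explained
  }, numeric(1))
  expect_true(all(diff(ve) >= -1e-12))
  expect_equal(ve[6], 1, tolerance = 1e-12)
})

test_that("constant data is a zero-variance error", {
  expect_error(pca_variance_explained(matrix(3, 10, 4), 2),
               class = "hsifluor_zero_variance_error")
})

test_that("t-SNE embedding is deterministic and separates far blobs", {
  set.seed(44)
  X <- rbind(matrix(rnorm(60 * 5), 60, 5),
             matrix(rnorm(60 * 5, mean = 20), 60, 5))
  labels <- rep(c("a", "b"), each = 60)
  e1 <- tsne_embed(X, dims = 2, perplexity = 10, seed = 5)
  e2 <- tsne_embed(X, dims = 2, perplexity = 10, seed = 5)
  expect_identical(e1, e2)
  expect_gt(silhouette_mean(e1, labels), 0.5)
  e3 <- tsne_embed(X, dims = 3, perplexity = 10, seed = 5)
  expect_equal(ncol(e3), 3)
  expect_error(tsne_embed(X[1:20, ], perplexity = 10),
               class = "hsifluor_parameter_error")
})

test_that("KS edge cases: identical samples and disjoint ranges", {
  x <- rnorm(30)
  same <- ks_two_sample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- runif(50, 0, 1)
  b <- runif(50, 2, 3)
  sep <- ks_two_sample(a, b)
  expect_equal(sep$statistic, 1)
  expect_lt(sep$p_value, 0.01)
})

test_that("permutation KS matches a hand-enumerated oracle", {
  x <- c(0.1, 0.2, 0.3)
  y <- c(0.15, 0.25, 0.9)
  res <- ks_two_sample(x, y, method = "permutation")

  # independent enumeration of all 20 label assignments
  pooled <- c(x, y)
  combs <- combn(6, 3)
  ds <- apply(combs, 2, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    v <- sort(unique(pooled))
    max(abs(ecdf(xs)(v) - ecdf(ys)(v)))
  })
  d_obs <- {
    v <- sort(unique(pooled))
    max(abs(ecdf(x)(v) - ecdf(y)(v)))
  }
  expect_equal(res$statistic, d_obs)
  expect_equal(res$p_value, mean(ds >= d_obs - 1e-12))
})

test_that("asymptotic KS agrees with the standard implementation", {
  set.seed(46)
  for (i in 1:10) {
    x <- rnorm(40 + i)
    y <- rnorm(60, mean = 0.3)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    # same Kolmogorov limit; the small-sample correction differs slightly
    expect_lt(abs(ours$p_value - ref$p.value), 0.05)
  }
})

test_that("KS battery reports symmetric p-values and exceptions", {
  set.seed(47)
  A <- rbind(matrix(rnorm(50 * 5, 0), 50, 5),
             matrix(rnorm(50 * 5, 3), 50, 5),
             matrix(rnorm(50 * 5, 0), 50, 5))  # third class == first class
  colnames(A) <- c("PpIX634", "PpIX620", "NADH", "lipofuscin", "flavins")
  labels <- rep(c("a", "b", "c"), each = 50)
  rep_ <- ks_battery(A, labels)
  expect_equal(nrow(rep_$table), 5 * 3)
  for (f in names(rep_$p_values)) {
    M <- rep_$p_values[[f]]
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, 3))
    expect_true(all(M >= 0 & M <= 1))
  }
  # the identically-distributed pair (a, c) should dominate the exceptions
  expect_true(all(rep_$exceptions$class_a == "a" &
                  rep_$exceptions$class_b == "c"))
  # the separated pairs are all significant
  sep <- rep_$table[rep_$table$class_b == "b" | rep_$table$class_a == "b", ]
  expect_true(all(sep$significant))
})

test_that("classes with fewer than two samples are excluded with a warning", {
  A <- matrix(rnorm(41 * 5), 41, 5)
  labels <- c(rep("a", 20), rep("b", 20), "tiny")
  expect_warning(rep_ <- ks_battery(A, labels), "tiny")
  expect_setequal(rep_$classes, c("a", "b"))
})

test_that("KS battery CSV export has the documented long format", {
  set.seed(48)
  A <- matrix(rnorm(40 * 5), 40, 5)
  rep_ <- ks_battery(A, rep(c("x", "y"), each = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ks_csv(rep_, path, task = "margin")
  df <- read.csv(path)
  expect_identical(names(df), c("task", "fluorophore", "class_a", "class_b",
                                "D", "p_value", "significant"))
})
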