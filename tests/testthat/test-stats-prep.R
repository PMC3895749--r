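test_that("min-max standardization rescales, preserves bounds and inverts", {
  x <- data.frame(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0.25, 1))
  sc <- minmax_standardize(x)
  expect_equal(sc$values$a, c(0, 0.5, 1))
  expect_equal(sc$values$b, c(0, 0, 0))       # constant column maps to 0
  expect_equal(sc$values$c, c(0, 0.25, 1))    # already-[0,1] column unchanged
  expect_equal(minmax_invert(sc, sc$values)$a, x$a)
  expect_equal(minmax_invert(sc, sc$values)$b, x$b)
  expect_equal(minmax_invert(sc, sc$values$c, variable = "c"), x$c)

  set.seed(4)
  y <- as.data.frame(matrix(rnorm(200, sd = 30), 40, 5))
  sc2 <- minmax_standardize(y)
  expect_true(all(as.matrix(sc2$values) >= 0 & as.matrix(sc2$values) <= 1))
  expect_true(all(apply(sc2$values, 2, function(v) any(v == 0) && any(v == 1))))
  expect_equal(as.matrix(minmax_invert(sc2, sc2$values)), as.matrix(y),
               tolerance = 1e-9)

  expect_error(minmax_standardize(y[1, ]), "at least 2 rows")
  expect_error(minmax_standardize(data.frame(a = c("x", "y"))), "non-numeric")
})

test_that("Pearson correlations match the definition and flag degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  m <- data.frame(x = x, y = 2 * x + 1, z = -x + 10)
  cm <- pearson_correlation_matrix(m)
  expect_equal(cm["x", "y"], 1.0)
  expect_equal(cm["x", "z"], -1.0)
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), c(x = 1, y = 1, z = 1))

  set.seed(8)
  r <- as.data.frame(matrix(rnorm(120), 20, 6))
  cr <- pearson_correlation_matrix(r)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(cr[i, j], oracle_pearson(r[[i]], r[[j]]), tolerance = 1e-12)
  }
  expect_true(all(eigen(cr, symmetric = TRUE, only.values = TRUE)$values
                  > -1e-10))

  expect_error(pearson_correlation_matrix(data.frame(a = 1:5, b = rep(2, 5))),
               "constant column.*b")
  expect_error(pearson_correlation_matrix(m[1:2, ]), "at least 3 rows")
})

test_that("collinearity pruning removes the lower-priority partner", {
  env <- generate_environment(generator_config(seed = 3))
  vars <- c("temperature", "discharge_q", "ph", "do_mgl", "ec", "bod5", "tds")
  corr <- pearson_correlation_matrix(env[, vars])
  kept <- drop_collinear(corr, threshold = 0.95, keep_priority = vars)
  expect_true("ec" %in% kept)
  expect_false("tds" %in% kept)
  sub <- corr[kept, kept]
  expect_true(all(abs(sub[upper.tri(sub)]) < 0.95))

  ident <- diag(3)
  dimnames(ident) <- list(letters[1:3], letters[1:3])
  expect_equal(drop_collinear(ident, 0.95), letters[1:3])

  near <- matrix(c(1, 0.99, 0.99, 1), 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  expect_equal(drop_collinear(near, threshold = 1.0), c("a", "b"))
  expect_equal(drop_collinear(near, threshold = 0.9), "a")
  expect_equal(drop_collinear(near, threshold = 0.9,
                              keep_priority = c("b", "a")), "b")
})

test_that("k-means recovers separated clouds and behaves like Lloyd", {
  set.seed(5)
  cloud1 <- matrix(rnorm(60, mean = 0, sd = 0.2), 30, 2)
  cloud2 <- matrix(rnorm(60, mean = 5, sd = 0.2), 30, 2)
  X <- rbind(cloud1, cloud2)
  rownames(X) <- sprintf("p%02d", 1:60)
  res <- kmeans_cluster(X, k = 2, seed = 1)
  expect_length(res$cluster, 60)
  expect_setequal(unique(res$cluster), 1:2)
  expect_equal(length(unique(res$cluster[1:30])), 1)
  expect_equal(length(unique(res$cluster[31:60])), 1)
  expect_true(res$cluster[1] != res$cluster[31])
  # SSE trajectory of Lloyd iterations is non-increasing
  expect_true(all(diff(res$sse_trajectory) <= 1e-9))
  # cross-check the optimum against the stock implementation
  ref <- kmeans(X, centers = 2, nstart = 10, algorithm = "Lloyd")
  expect_equal(res$tot_withinss, ref$tot.withinss, tolerance = 1e-8)

  each_own <- kmeans_cluster(X[1:5, ], k = 5, seed = 2)
  expect_equal(each_own$tot_withinss, 0)
  expect_error(kmeans_cluster(X[1:3, ], k = 4, seed = 1), "invalid k")
  expect_identical(kmeans_cluster(X, 2, seed = 9)$cluster,
                   kmeans_cluster(X, 2, seed = 9)$cluster)
})

test_that("winter-cluster exclusion drops the December-February cluster", {
  months <- rep(1:12, 2)
  assignment <- structure(list(
    cluster = ifelse(months %in% c(12, 1, 2), 1L, 2L),
    centers = NULL, tot_withinss = 0, sse_trajectory = 0, k = 2L
  ), class = "kmeans_assignment")
  names(assignment$cluster) <- sprintf("m%02d_%d", months, rep(1:2, each = 12))
  keep <- exclude_winter_cluster(assignment, months)
  expect_setequal(keep, names(assignment$cluster)[!(months %in% c(12, 1, 2))])

  bad_k <- assignment
  bad_k$k <- 3L
  expect_error(exclude_winter_cluster(bad_k, months), "k = 2")

  tie <- assignment
  tie$cluster <- rep(2L, 24)
  tie$cluster[c(1, 2, 12)] <- 1L      # winter samples split 3/3
  expect_error(exclude_winter_cluster(tie, months), "ambiguous season")
  expect_error(exclude_winter_cluster(assignment, months[-1]), "align")
})

test_that("PCA on the correlation matrix rotates without losing communality", {
  set.seed(6)
  n <- 100
  shared <- rnorm(n)
  x <- data.frame(a = shared + rnorm(n, sd = 0.1),
                  b = -shared + rnorm(n, sd = 0.1),
                  c = rnorm(n), d = rnorm(n), e = rnorm(n))
  p <- pca_varimax(x, n_components = 3)
  expect_equal(p$explained_variance, sort(p$explained_variance,
                                          decreasing = TRUE))
  expect_equal(sum(p$explained_variance), 1)
  # unrotated loading columns are orthogonal
  gram <- t(p$loadings) %*% p$loadings
  expect_true(all(abs(gram[upper.tri(gram)]) < 1e-8))
  # varimax preserves per-variable communality
  expect_equal(rowSums(p$rotated^2),
               rowSums(p$loadings[, 1:3]^2), tolerance = 1e-6)
  # the correlated pair loads together on one rotated component
  lead <- apply(abs(p$rotated), 1, which.max)
  expect_equal(lead[["a"]], lead[["b"]])
  expect_gt(abs(p$rotated["a", lead[["a"]]]), 0.9)
  expect_gt(abs(p$rotated["b", lead[["b"]]]), 0.9)

  # isotropic noise spreads variance nearly evenly
  iso <- as.data.frame(matrix(rnorm(6 * 400), 400, 6))
  pv <- pca_varimax(iso, 2)$explained_variance
  expect_lt(max(pv), 0.3)

  expect_error(pca_varimax(x[1:2, ], 2), "insufficient data")
  expect_error(pca_varimax(x, 9), "n_components")
})

test_that("train/validation split is a seeded partition", {
  keys <- sprintf("k%02d", 1:50)
  sp <- train_validation_split(keys, 0.8, seed = 7)
  expect_length(sp$train, 40)
  expect_length(sp$validation, 10)
  expect_identical(sp, train_validation_split(keys, 0.8, seed = 7))
  expect_false(identical(sp, train_validation_split(keys, 0.8, seed = 8)))
  for (frac in c(0.5, 0.66, 0.8)) {
    sp_i <- train_validation_split(keys, frac, seed = 1)
    expect_setequal(c(sp_i$train, sp_i$validation), keys)
    expect_length(intersect(sp_i$train, sp_i$validation), 0)
    expect_length(sp_i$train, round(frac * 50))
  }
  expect_error(train_validation_split(keys[1], 0.8, 1), "at least 2")
  expect_error(train_validation_split(keys[1:2], 0.1, 1), "invalid split")
})
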