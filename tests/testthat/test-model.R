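# Paths, cluster-count targeting and the adaptive scheme.

blob_views <- function(seed = 1, n_per = 5, sep = 8) {
  set.seed(seed)
  mu <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  lab <- rep(1:3, each = n_per)
  X <- mu[lab, ] + matrix(rnorm(3 * n_per * 2, sd = 0.4), 3 * n_per)
  list(views = list(dataView(X, "euclidean")), labels = lab)
}

test_that("warm-started paths match cold fits", {
  b <- blob_views()
  g <- suppressWarnings(ccWeights(b$views, kappa = 4))
  gam <- c(0.5, 1, 2, 4)
  p <- solvePath(b$views, g, gam, tol = 1e-7, max_iter = 50000)
  expect_equal(nrow(p@grid), 4L)
  for (i in seq_along(gam)) {
    cold <- ccFit(b$views, g, gamma = gam[i], tol = 1e-7, max_iter = 50000)
    expect_equal(p@fits[[i]]@objective, cold@objective, tolerance = 1e-5)
  }
  # cluster counts broadly decrease along the path
  expect_true(p@grid$nClusters[4] <= p@grid$nClusters[1])
  expect_error(solvePath(b$views, g, rev(gam)), class = "icclust_contract")
})

test_that("fitForClusters recovers well-separated groups at the target", {
  b <- blob_views(seed = 2)
  g <- suppressWarnings(ccWeights(b$views, kappa = 4))
  f <- fitForClusters(b$views, g, 3)
  expect_equal(sort(unique(f@labels)), 1:3)
  expect_equal(adjustedRandIndex(f@labels, b$labels), 1)
})

test_that("labels are equivariant under row permutation", {
  b <- blob_views(seed = 3)
  X <- b$views[[1]]@X
  set.seed(1)
  perm <- sample(nrow(X))
  v2 <- dataView(X[perm, ], "euclidean")
  g1 <- suppressWarnings(ccWeights(b$views, kappa = 4))
  g2 <- suppressWarnings(ccWeights(list(v2), kappa = 4))
  f1 <- fitForClusters(b$views, g1, 3)
  f2 <- fitForClusters(list(v2), g2, 3)
  expect_equal(adjustedRandIndex(f1@labels[perm], f2@labels), 1)
})

test_that("adaptive feature weights penalize shrunk features most", {
  # zeta = (max imp + eps) / (imp + eps) with eps at 1% of the largest
  # importance: a fully shrunk feature gets the ceiling 101, a feature at
  # maximal importance gets 1
  imp <- c(0.99, 0)
  e <- 0.01 * max(imp)
  zeta <- (max(imp) + e) / (imp + e)
  expect_equal(zeta[1], 1)
  expect_equal(zeta[2], 101)
})

test_that("adaptive fitting recovers the partition on clean data", {
  # low-noise single view: 3 clear blobs in 2 informative features plus a
  # little noise
  set.seed(11)
  b <- blob_views(seed = 11, n_per = 10, sep = 10)
  X <- cbind(b$views[[1]]@X, matrix(rnorm(30 * 4, sd = 0.5), 30))
  fit <- suppressWarnings(
    adaptiveGeccoPlus(X, "euclidean", n_clusters = 3, n_features = 2,
                      max_iter = 5000L))
  expect_equal(adjustedRandIndex(fit@labels, b$labels), 1)
  expect_equal(fit@selected[[1]][1:2], c(TRUE, TRUE))
})

test_that("fitForTargets hits oracle cluster and feature counts", {
  set.seed(12)
  b <- blob_views(seed = 12, n_per = 8, sep = 9)
  X <- cbind(b$views[[1]]@X, matrix(rnorm(24 * 3, sd = 0.5), 24))
  v <- dataView(X, "euclidean")
  g <- suppressWarnings(ccWeights(list(v), kappa = 4))
  fit <- suppressWarnings(
    fitForTargets(list(v), g, n_clusters = 3, n_features = 2,
                  max_iter = 5000L))
  expect_equal(fit@nFeatures, 2L)
  expect_equal(icclust:::.bulk_count(fit, 2L), 3L)
})

test_that("penalty grid and gammaMax behave", {
  grid <- penaltyGrid(10, length = 5, ratio = 100)
  expect_equal(length(grid), 5L)
  expect_equal(grid[5], 10)
  expect_equal(grid[1], 0.1)
  b <- blob_views(seed = 13)
  g <- suppressWarnings(ccWeights(b$views, kappa = 4))
  gm <- gammaMax(b$views, g, gamma0 = 0.1)
  f <- ccFit(b$views, g, gamma = gm)
  # fusion cannot cross graph components, so gammaMax targets one cluster
  # per connected component of the kNN graph
  ig <- igraph::graph_from_edgelist(g@edges, directed = FALSE)
  expect_equal(f@nClusters, igraph::components(ig)$no)
})
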