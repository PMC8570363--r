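# ADMM solver: limiting cases, engine agreement, one-step vs full solve,
# and equivalence with an independent convex oracle on toy problems.

toy_views <- function(seed = 1, n = 6) {
  set.seed(seed)
  X1 <- matrix(rnorm(n * 2), n)
  X2 <- matrix(abs(rnorm(n * 2)) + 0.3, n)
  list(dataView(X1, "euclidean"), dataView(X2, "manhattan"))
}
toy_graph <- function(views, kappa = 3)
  suppressWarnings(ccWeights(views, kappa = kappa, scheme = "gaussian"))

test_that("with no penalties distance losses reproduce the data", {
  vs <- toy_views()
  g <- toy_graph(vs)
  f <- ccFit(vs, g, gamma = 0, alpha = 0, tol = 1e-7, max_iter = 50000)
  expect_lt(max(abs(f@U[[1]] - vs[[1]]@X)), 1e-3)
  expect_lt(max(abs(f@U[[2]] - vs[[2]]@X)), 1e-3)
  expect_equal(f@nClusters, 6L)
})

test_that("large gamma fuses all centroids to the loss-specific centers", {
  # odd n so the manhattan center (median) is unique
  vs <- toy_views(seed = 2, n = 7)
  g <- toy_graph(vs)
  f <- ccFit(vs, g, gamma = 1e5, tol = 1e-8, max_iter = 50000)
  expect_equal(f@nClusters, 1L)
  for (k in 1:2) {
    ctr <- matrix(vs[[k]]@center, 7, 2, byrow = TRUE)
    expect_lt(max(abs(f@U[[k]] - ctr)), 1e-5)
  }
  # large alpha shrinks every feature column to its center
  f2 <- ccFit(vs, g, gamma = 0, alpha = 1e5, tol = 1e-7, max_iter = 50000)
  expect_equal(f2@nFeatures, 0L)
})

test_that("compiled and R engines reach the same objective", {
  vs <- toy_views(seed = 3)
  g <- toy_graph(vs)
  fc <- ccFit(vs, g, gamma = 0.4, alpha = 0.2, engine = "cpp",
              tol = 1e-7, max_iter = 50000)
  fr <- ccFit(vs, g, gamma = 0.4, alpha = 0.2, engine = "r",
              tol = 1e-7, max_iter = 50000)
  expect_equal(fc@objective, fr@objective, tolerance = 1e-5)
})

test_that("one-step updates and the full ADMM agree (and match the oracle)", {
  for (seed in 1:3) {
    vs <- toy_views(seed = seed)
    g <- toy_graph(vs)
    f1 <- ccFit(vs, g, gamma = 0.5, alpha = 0.3, tol = 1e-8,
                max_iter = 100000)
    f2 <- fitFullADMM(vs, g, gamma = 0.5, alpha = 0.3, tol = 1e-7,
                      max_iter = 20000)
    expect_equal(f1@objective, f2@objective, tolerance = 1e-4)
    orc <- oracle_solve(oracle_views_from(vs), g@edges, g@weights,
                        gamma = 0.5, alpha = 0.3)
    expect_equal(f1@objective, orc$objective, tolerance = 1e-4)
  }
})

test_that("solutions are initialization-independent (global optimum)", {
  vs <- toy_views(seed = 4)
  g <- toy_graph(vs)
  base <- ccFit(vs, g, gamma = 0.6, alpha = 0.2, tol = 1e-9,
                max_iter = 200000)
  set.seed(99)
  for (rep in 1:3) {
    warm <- list(U = lapply(vs, function(v) v@X + matrix(rnorm(12, sd = 2), 6)),
                 V = matrix(rnorm(nrow(g@edges) * 4), nrow(g@edges)),
                 Lambda = lapply(vs, function(v)
                   matrix(0, nrow(g@edges), 2)))
    f <- ccFit(vs, g, gamma = 0.6, alpha = 0.2, warm = warm, tol = 1e-9,
               max_iter = 200000)
    expect_equal(f@objective, base@objective, tolerance = 1e-6)
  }
})

test_that("solutions vary continuously with gamma", {
  vs <- toy_views(seed = 5)
  g <- toy_graph(vs)
  f1 <- ccFit(vs, g, gamma = 0.5, tol = 1e-8, max_iter = 100000)
  f2 <- ccFit(vs, g, gamma = 0.505, tol = 1e-8, max_iter = 100000)
  rel <- sqrt(sum((f1@U[[1]] - f2@U[[1]])^2)) /
         (1 + sqrt(sum(f1@U[[1]]^2)))
  expect_lt(rel, 0.05)
})

test_that("special cases: K = 1, alpha = 0 and the centered Euclidean case", {
  set.seed(6)
  X <- matrix(rnorm(12), 6)
  v <- dataView(X, "euclidean")
  g <- toy_graph(list(v))
  a <- igeccoPlus(list(v), gamma = 0.3, alpha = 0.1, graph = g)
  b <- geccoPlus(v, gamma = 0.3, alpha = 0.1, graph = g)
  expect_equal(a@objective, b@objective, tolerance = 1e-10)
  expect_identical(a@labels, b@labels)
  # alpha = 0 is the pure integrative fit
  a0 <- igeccoPlus(list(v), gamma = 0.3, alpha = 0, graph = g)
  b0 <- igecco(list(v), gamma = 0.3, graph = g)
  expect_equal(a0@objective, b0@objective, tolerance = 1e-10)
  # centered data: the loss-specific centers vanish, so the shifted penalty
  # reduces to the plain group lasso of sparse convex clustering
  Xc <- scale(X, center = TRUE, scale = FALSE)
  vc <- dataView(Xc, "euclidean")
  expect_lt(max(abs(vc@center)), 1e-12)
  fc <- ccFit(list(vc), toy_graph(list(vc)), gamma = 0.2, alpha = 0.2,
              tol = 1e-8, max_iter = 50000)
  # selected features are exactly the columns with nonzero group norm
  # (sparsity with respect to zero, since the centers vanish)
  nrm <- sqrt(colSums(fc@U[[1]]^2))
  expect_true(all(nrm[fc@selected[[1]]] > 1e-4 * max(nrm)))
  expect_true(all(nrm[!fc@selected[[1]]] < 1e-4 * max(nrm)))
})

test_that("non-convergence within max_iter is flagged", {
  vs <- toy_views(seed = 7)
  g <- toy_graph(vs)
  f <- ccFit(vs, g, gamma = 0.5, max_iter = 3L)
  expect_false(f@converged)
  expect_equal(f@iter, 3L)
})

test_that("cluster and feature extraction follow the fitted pattern", {
  # hand-built states: fused edges (1,2),(2,3) on n = 5
  g <- fusionGraph(5, rbind(c(1, 2), c(2, 3), c(4, 5)), rep(1, 3))
  st <- list(V = rbind(c(0, 0), c(0, 0), c(3, 1)),
             U = list(matrix(1, 5, 2)))
  lab <- extractClusters(st, g)
  expect_equal(lab, c(1L, 1L, 1L, 2L, 3L))
  # all V rows zero -> one cluster per graph component ({1,2,3} and {4,5});
  # none below tol -> all singletons
  st$V <- matrix(0, 3, 2)
  expect_equal(extractClusters(st, g), c(1L, 1L, 1L, 2L, 2L))
  st$V <- matrix(5, 3, 2)
  expect_equal(extractClusters(st, g), 1:5)
  # feature masks: exactly the shrunk column is dropped
  set.seed(8)
  X <- matrix(rnorm(10), 5)
  v <- dataView(X, "euclidean")
  U <- X; U[, 2] <- v@center[2]
  m <- extractFeatures(list(U = list(U)), list(v))
  expect_equal(m[[1]], c(TRUE, FALSE))
})
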