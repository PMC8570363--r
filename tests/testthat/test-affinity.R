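# Distances, kNN masks and fusion-weight graphs.

test_that("Gower distance matches hand calculations and its invariances", {
  # one feature, values {0, R} -> distance 1
  v <- dataView(matrix(c(0, 4, 2), 3, 1), "euclidean")
  D <- gowerDistance(list(v))
  expect_equal(D[1, 2], 1)
  expect_equal(D[1, 3], 0.5)
  expect_equal(diag(D), rep(0, 3))
  expect_equal(D, t(D))
  # two views, one feature each, diffs 0.5R and 0.25R -> (0.5+0.25)/2
  v1 <- dataView(matrix(c(0, 1, 2), 3, 1), "euclidean")      # diff12 = 0.5R
  v2 <- dataView(matrix(c(0, 1, 4), 3, 1), "euclidean")      # diff12 = 0.25R
  D2 <- gowerDistance(list(v1, v2))
  expect_equal(D2[1, 2], (0.5 + 0.25) / 2)
  # affine rescaling of a feature leaves Gower unchanged
  set.seed(1)
  X <- matrix(rnorm(30), 10)
  va <- dataView(X, "euclidean")
  Xb <- X; Xb[, 2] <- 5 * Xb[, 2] - 3
  vb <- dataView(Xb, "euclidean")
  expect_equal(gowerDistance(list(va)), gowerDistance(list(vb)),
               tolerance = 1e-12)
  # zero-range features are dropped from numerator and denominator, so a
  # constant column leaves the distances unchanged
  Xc <- cbind(X, 7)
  vc <- dataView(Xc, "euclidean")
  expect_equal(gowerDistance(list(vc)), gowerDistance(list(va)),
               tolerance = 1e-12)
})

test_that("kNN mask implements the 'or vice versa' rule", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 1
  D[1, 3] <- D[3, 1] <- 2
  D[2, 3] <- D[3, 2] <- 3
  m <- knnMask(D, 1)
  # 3's nearest is 1, so (1,3) survives via the union rule
  expect_true(m[1, 2] && m[1, 3])
  expect_false(m[2, 3])
  expect_equal(m, t(m))
  set.seed(2)
  Dr <- as.matrix(dist(matrix(rnorm(20), 10)))
  mr <- knnMask(Dr, 3)
  expect_equal(mr, t(mr))
  expect_false(any(diag(mr)))
  # brute-force check of the union rule
  for (i in 1:10) for (j in 1:10) {
    if (i == j) next
    nn_i <- order(replace(Dr[i, ], i, Inf))[1:3]
    nn_j <- order(replace(Dr[j, ], j, Inf))[1:3]
    expect_equal(mr[i, j], (j %in% nn_i) || (i %in% nn_j))
  }
  expect_error(knnMask(Dr, 0), class = "icclust_contract")
  expect_error(knnMask(Dr, 10), class = "icclust_contract")
})

test_that("kernel weights follow the Gaussian and SNE formulas", {
  set.seed(3)
  Dm <- as.matrix(dist(matrix(rnorm(16), 8)))
  g <- kernelWeights(Dm, kappa = 7, phi = 0, scheme = "gaussian")
  expect_true(all(g@weights == 1))          # exp(0), all pairs masked in
  expect_equal(nrow(g@edges), choose(8, 2)) # kappa = n-1: everyone
  # SNE on n = 2: p12 = (1 + 1) / (2 * 2)
  D2 <- matrix(c(0, 1, 1, 0), 2)
  g2 <- kernelWeights(D2, kappa = 1, phi = 1, scheme = "sne")
  expect_equal(g2@weights, 0.5)
  # symmetrized conditionals sum to 1 over all ordered pairs before masking
  E <- exp(-0.8 * Dm); diag(E) <- 0
  P <- E / rowSums(E)
  Psym <- (P + t(P)) / (2 * nrow(Dm))
  expect_equal(sum(Psym[upper.tri(Psym)]) * 2, 1, tolerance = 1e-12)
  # disconnected mask warns
  Dfar <- matrix(10, 6, 6); diag(Dfar) <- 0
  Dfar[1:3, 1:3] <- 0.1; Dfar[4:6, 4:6] <- 0.1; diag(Dfar) <- 0
  expect_warning(kernelWeights(Dfar, kappa = 2, phi = 1),
                 class = "icclust_disconnected")
})

test_that("the incidence matrix D encodes row differences", {
  g <- fusionGraph(5, rbind(c(1, 2), c(2, 4), c(3, 5)), c(1, 2, 3))
  U <- matrix(rnorm(10), 5)
  DU <- as.matrix(g@D %*% U)
  expect_equal(DU[1, ], U[1, ] - U[2, ])
  expect_equal(DU[2, ], U[2, ] - U[4, ])
  expect_equal(DU[3, ], U[3, ] - U[5, ])
  expect_equal(Matrix::rowSums(g@D), rep(0, 3))
  expect_error(fusionGraph(5, rbind(c(2, 1)), 1))            # l1 < l2
  expect_error(fusionGraph(5, rbind(c(1, 2), c(1, 2)), c(1, 1)))  # dupes
  expect_error(fusionGraph(5, rbind(c(1, 2)), -1))           # weight > 0
})

test_that("weighted Gower update scales features by importance", {
  set.seed(4)
  X <- matrix(rnorm(20), 10, 2)
  v <- dataView(X, "euclidean")
  ctr <- matrix(v@center, 10, 2, byrow = TRUE)
  # importances (1, 0.5): second feature's contribution is halved
  U1 <- ctr + cbind(rep(1, 10) / sqrt(10), rep(0.5, 10) / sqrt(10))
  Dw <- weightedGowerUpdate(list(v), list(U1))
  d1 <- abs(outer(X[, 1], X[, 1], "-")) / diff(range(X[, 1]))
  d2 <- abs(outer(X[, 2], X[, 2], "-")) / diff(range(X[, 2]))
  expect_equal(Dw, (d1 + 0.5 * d2) / v@weight, tolerance = 1e-10)
  # fully shrunk view contributes zero, with a warning
  expect_warning(D0 <- weightedGowerUpdate(list(v), list(ctr)),
                 class = "icclust_allshrunk")
  expect_equal(D0, matrix(0, 10, 10))
})
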