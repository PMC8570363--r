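# Clustering and feature-selection metrics.

test_that("adjusted Rand index matches hand values and mclust", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # crossed pairs: sum_ij C(n_ij,2) = 0, index terms sum_a = sum_b = 2,
  # E = 2*2/C(4,2) = 2/3, max = 2, so ARI = (0 - 2/3)/(2 - 2/3) = -1/2
  # (cross-checked against mclust below)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -1/2)
  # symmetry and label-permutation invariance
  set.seed(1)
  a <- sample(1:4, 50, replace = TRUE)
  b <- sample(1:3, 50, replace = TRUE)
  expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(b, a))
  expect_equal(adjustedRandIndex(a, b),
               adjustedRandIndex(5 - a, letters[b]))
  for (rep in 1:10) {
    x <- sample(1:5, 40, replace = TRUE)
    y <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjustedRandIndex(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
  expect_error(adjustedRandIndex(1:3, 1:4), class = "icclust_contract")
})

test_that("random relabelings score near zero on average", {
  set.seed(2)
  a <- rep(1:3, each = 40)
  vals <- replicate(1000, adjustedRandIndex(a, sample(a)))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("feature F1 handles edge cases and pools views", {
  t4 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(featureF1(t4, t4), 1)
  expect_equal(featureF1(c(FALSE, FALSE, TRUE, TRUE), t4), 0)
  expect_equal(featureF1(rep(FALSE, 4), t4), 0)
  # P = 0.5, R = 1 -> 2/3
  expect_equal(featureF1(c(TRUE, TRUE, TRUE, TRUE), t4), 2/3)
  # pooling across views
  expect_equal(featureF1(list(c(TRUE, FALSE), c(TRUE, FALSE)),
                         list(c(TRUE, FALSE), c(FALSE, TRUE))), 0.5)
  expect_error(featureF1(t4, rep(FALSE, 4)),
               class = "icclust_undefined_metric")
})

test_that("metricReport combines ARI and per-view selection accuracy", {
  set.seed(3)
  X <- matrix(rnorm(40), 20)
  v <- dataView(X, "euclidean")
  g <- suppressWarnings(ccWeights(list(v), kappa = 3))
  fit <- ccFit(list(v), g, gamma = 1e4)
  rep_ <- metricReport(fit, rep(1L, 20), informative = list(c(TRUE, FALSE)))
  expect_equal(rep_$ari, 1)
  expect_true(rep_$f1 >= 0 && rep_$f1 <= 1)
  expect_length(rep_$per_view, 1L)
})
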