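# Synthetic benchmark generators.

test_that("single-view scenarios have the stated shapes and labels", {
  s <- simSingleView("S1A", p_noise = 25, seed = 3)
  expect_equal(dim(s$views[[1]]), c(120L, 35L))
  expect_equal(as.vector(table(s$labels)), rep(40L, 3))
  expect_equal(sum(s$informative[[1]]), 10L)
  # 5% outliers per class, exact counts
  expect_equal(length(s$outliers), 3 * round(0.05 * 40))
  # determinism
  s2 <- simSingleView("S1A", p_noise = 25, seed = 3)
  expect_identical(s$views[[1]], s2$views[[1]])
  s3 <- simSingleView("S1A", p_noise = 25, seed = 4)
  expect_false(identical(s$views[[1]], s3$views[[1]]))
})

test_that("count scenario produces nonnegative integers, no outliers", {
  s <- simSingleView("S3", p_noise = 10, seed = 1)
  X <- s$views[[1]]
  expect_true(all(X >= 0))
  expect_true(all(X == round(X)))
  expect_length(s$outliers, 0L)
})

test_that("half-moon scenario marks outliers and keeps moon geometry", {
  s <- simSingleView("S2", p_noise = 15, seed = 2)
  expect_equal(dim(s$views[[1]]), c(120L, 25L))
  expect_equal(length(s$outliers), 6L)
  # non-outlier moon coordinates stay within the arc envelope
  keep <- setdiff(1:120, s$outliers)
  expect_lt(max(abs(s$views[[1]][keep, 2])), 1.7)
})

test_that("multi-view scenarios have the stated view dimensions", {
  dims <- list(S1 = c(10, 10, 10), S3 = c(200, 100, 50),
               S4 = c(50, 200, 100), S5 = c(200, 100, 50),
               S6 = c(50, 200, 100))
  for (sc in names(dims)) {
    s <- simMultiView(sc, seed = 1)
    expect_equal(vapply(s$views, ncol, 1L), as.integer(dims[[sc]]),
                 label = sc)
    expect_true(all(vapply(s$views, nrow, 1L) == 120L))
    expect_equal(vapply(s$informative, sum, 1L), rep(10L, 3))
  }
  s <- simMultiView("S1", seed = 1)
  expect_true(all(s$views[[2]] >= 0 & s$views[[2]] == round(s$views[[2]])))
  expect_true(all(s$views[[3]] %in% c(0, 1)))
})

test_that("half-moon multi-view copula views have the right supports", {
  s <- simMultiView("S5", seed = 2)
  cnt <- s$views[[2]][, 1:10]
  prp <- s$views[[3]][, 1:10]
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
  expect_true(all(prp > 0 & prp < 1))
  # copula transform is rank-preserving within a column by construction:
  # the count view's ranks follow the latent moon coordinate ranks, so
  # cluster medians must differ along x-coordinates (features 1, 3, ...)
  med <- tapply(s$views[[2]][, 1], s$labels, median)
  expect_gt(max(med) - min(med), 0)
})

test_that("informative Gaussian class means concentrate at mu_k", {
  # law-of-large-numbers check on the first informative feature (class
  # means -2.5 / 0 / 2.5), averaged over replicates
  means <- rowMeans(sapply(1:30, function(r) {
    s <- simSingleView("S1A", p_noise = 0, seed = 100 + r)
    tapply(s$views[[1]][, 1], s$labels, mean)
  }))
  expect_equal(unname(means), c(-2.5, 0, 2.5), tolerance = 0.15)
})
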