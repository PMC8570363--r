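# Loss evaluators, gradients, proximal operators, loss-specific centers and
# null-deviance weights.

test_that("loss evaluation matches hand calculations", {
  expect_equal(evalLoss(lossSpec("euclidean"), c(1, 2), c(1, 2)), 0)
  expect_equal(evalLoss(lossSpec("manhattan"), c(1, 2), c(0, 0)), 3)
  expect_equal(evalLoss(lossSpec("poisson_ll"), 1, 0), 1)  # -1*0 + e^0
  expect_equal(evalLoss(lossSpec("chebychev"),
                        matrix(c(1, 2), 1), matrix(0, 1, 2)), 2)
  expect_equal(evalLoss(lossSpec("minkowski", q = 2),
                        matrix(c(3, 4), 1), matrix(0, 1, 2)), 5)
  C <- diag(2)
  expect_equal(evalLoss(lossSpec("mahalanobis", C = C),
                        matrix(c(1, 2), 1), matrix(0, 1, 2)), 5)
  # deviances vanish at the saturated point and are positive elsewhere
  expect_equal(evalLoss(lossSpec("poisson_dev"), c(0, 2, 5), c(1e-8, 2, 5)),
               0, tolerance = 1e-6)
  expect_gt(evalLoss(lossSpec("poisson_dev"), c(1, 2), c(2, 1)), 0)
  expect_equal(evalLoss(lossSpec("binomial_dev"), c(0, 1), c(1e-9, 1 - 1e-9)),
               0, tolerance = 1e-6)
})

test_that("domain and shape contracts are enforced", {
  expect_error(evalLoss(lossSpec("poisson_ll"), -1, 0),
               class = "icclust_invalid_domain")
  expect_error(evalLoss(lossSpec("binomial_dev"), 0.5, 1.5),
               class = "icclust_invalid_domain")
  expect_error(evalLoss(lossSpec("euclidean"), 1:2, 1:3),
               class = "icclust_contract")
  expect_error(gradLoss(lossSpec("manhattan"), 1, 0),
               class = "icclust_unsupported")
  expect_error(proxLoss(lossSpec("euclidean"), 1, 1),
               class = "icclust_unsupported")
  expect_error(lossSpec("hinge"), class = "icclust_unsupported")
  expect_error(lossSpec("minkowski", q = 0.5))
  expect_error(lossSpec("negbin_ll", theta = -1))
})

test_that("gradients match central finite differences", {
  set.seed(42)
  specs <- list(lossSpec("euclidean"), lossSpec("poisson_ll"),
                lossSpec("bernoulli_ll"), lossSpec("poisson_dev"),
                lossSpec("binomial_dev"), lossSpec("negbin_ll", theta = 2),
                lossSpec("negbin_dev", theta = 2),
                lossSpec("minkowski", q = 3))
  for (sp in specs) {
    X <- switch(sp@family,
      bernoulli_ll = , binomial_dev = matrix(runif(6, 0.1, 0.9), 2),
      poisson_ll = , poisson_dev = , negbin_ll = ,
      negbin_dev = matrix(rpois(6, 4), 2),
      matrix(rnorm(6), 2))
    U <- switch(sp@family,
      poisson_dev = , negbin_dev = matrix(runif(6, 0.5, 4), 2),
      binomial_dev = matrix(runif(6, 0.2, 0.8), 2),
      matrix(rnorm(6, sd = 0.5), 2))
    G <- gradLoss(sp, X, U)
    h <- 1e-6
    for (idx in seq_len(6)) {
      Up <- U; Up[idx] <- U[idx] + h
      Um <- U; Um[idx] <- U[idx] - h
      fd <- (evalLoss(sp, X, Up) - evalLoss(sp, X, Um)) / (2 * h)
      expect_equal(G[idx], fd, tolerance = 1e-4,
                   label = sprintf("%s grad[%d]", sp@family, idx))
    }
  }
})

test_that("losses are convex in the centroid argument", {
  set.seed(7)
  specs <- list(lossSpec("euclidean"), lossSpec("manhattan"),
                lossSpec("chebychev"), lossSpec("minkowski", q = 3),
                lossSpec("poisson_ll"), lossSpec("poisson_dev"),
                lossSpec("bernoulli_ll"), lossSpec("binomial_dev"),
                lossSpec("negbin_ll", theta = 1),
                lossSpec("negbin_dev", theta = 1),
                lossSpec("mahalanobis", C = crossprod(matrix(rnorm(4), 2))))
  for (sp in specs) {
    for (rep in 1:5) {
      X <- switch(sp@family,
        bernoulli_ll = , binomial_dev = matrix(runif(4, 0.1, 0.9), 2),
        poisson_ll = , poisson_dev = , negbin_ll = ,
        negbin_dev = matrix(rpois(4, 3), 2),
        matrix(rnorm(4), 2))
      ru <- function() switch(sp@family,
        poisson_dev = , negbin_dev = matrix(runif(4, 0.3, 5), 2),
        binomial_dev = matrix(runif(4, 0.1, 0.9), 2),
        matrix(rnorm(4), 2))
      U1 <- ru(); U2 <- ru()
      lam <- runif(1)
      lhs <- evalLoss(sp, X, lam * U1 + (1 - lam) * U2)
      rhs <- lam * evalLoss(sp, X, U1) + (1 - lam) * evalLoss(sp, X, U2)
      expect_lte(lhs, rhs + 1e-8)
    }
  }
})

test_that("proximal operators satisfy the subgradient optimality condition", {
  expect_equal(proxLoss(lossSpec("manhattan"), 3, 1), matrix(2))
  expect_equal(proxLoss(lossSpec("manhattan"), 0.5, 1), matrix(0))
  A <- matrix(rnorm(12), 3)
  expect_equal(proxLoss(lossSpec("manhattan"), A, 0), A)
  # 0 in Z - A + t * subdiff f(Z): check via the Moreau envelope being
  # minimized at Z (numeric perturbation test)
  set.seed(11)
  for (sp in list(lossSpec("manhattan"), lossSpec("chebychev"),
                  lossSpec("minkowski", q = 3))) {
    A <- matrix(rnorm(8), 2)
    t <- 0.7
    fval <- function(Z) {
      f <- switch(sp@family,
        manhattan = sum(abs(Z)),
        chebychev = sum(apply(abs(Z), 1, max)),
        minkowski = sum(rowSums(abs(Z)^3)^(1 / 3)))
      0.5 * sum((A - Z)^2) + t * f
    }
    Z <- proxLoss(sp, A, t)
    base <- fval(Z)
    for (rep in 1:20) {
      P <- Z + matrix(rnorm(8, sd = 1e-4), 2)
      expect_gte(fval(P), base - 1e-10)
    }
  }
})

test_that("loss-specific centers minimize the columnwise loss", {
  expect_equal(lossCenter(lossSpec("manhattan"), c(1, 2, 9)), 2)
  expect_equal(lossCenter(lossSpec("euclidean"), c(0, 2, 4)), 2)
  expect_equal(lossCenter(lossSpec("poisson_ll"), c(1, 2, 6)), log(3))
  expect_equal(lossCenter(lossSpec("bernoulli_ll"), c(0, 1, 1, 1)),
               log(0.75 / 0.25))
  expect_equal(lossCenter(lossSpec("poisson_dev"), c(1, 2, 6)), 3)
  # numeric centers (no closed form) beat perturbed values on a delta grid
  set.seed(3)
  for (sp in list(lossSpec("chebychev"), lossSpec("minkowski", q = 3))) {
    x <- rnorm(9)
    ctr <- lossCenter(sp, x)
    l1 <- function(u) sum(abs(x - u))  # 1-D restriction of either family
    for (d in c(-0.1, -0.01, 0.01, 0.1))
      expect_gte(l1(ctr + d), l1(ctr) - 1e-7)
  }
  expect_error(lossCenter(lossSpec("euclidean"), numeric(0)),
               class = "icclust_contract")
  expect_warning(lossCenter(lossSpec("poisson_ll"), c(0, 0, 0)),
                 class = "icclust_degenerate_center")
  expect_warning(lossCenter(lossSpec("bernoulli_ll"), c(1, 1, 1)),
                 class = "icclust_degenerate_center")
})

test_that("null-deviance weights normalize each view", {
  v <- dataView(matrix(c(0, 2), 2, 1), "euclidean")
  expect_equal(v@weight, 1)  # center 1, loss 0.5*(1+1) = 1
  # pi * null deviance = 1 by construction, on deviance scale
  set.seed(5)
  for (fam in c("euclidean", "manhattan", "poisson_dev", "poisson_ll",
                "bernoulli_ll")) {
    X <- switch(fam, bernoulli_ll = matrix(rbinom(40, 1, 0.4), 20),
                poisson_dev = , poisson_ll = matrix(rpois(40, 3), 20),
                matrix(rnorm(40), 20))
    v <- dataView(X, fam)
    Xt <- matrix(v@center, nrow(X), ncol(X), byrow = TRUE)
    dev <- evalLoss(v@loss, X, Xt) - icclust:::.saturated_loss(v)
    expect_equal(v@weight * dev, 1, tolerance = 1e-10)
  }
  expect_error(dataView(matrix(1, 5, 2), "euclidean"),
               class = "icclust_degenerate_view")
})
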