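# Convex losses, gradients, proximal operators and loss-specific centers.
#
# Conventions:
#  * *_ll families parameterize centroids U on the natural-parameter scale
#    (their loss-specific center is log / logit of the column mean);
#  * *_dev families parameterize U on the mean scale (center = column mean).
#  * Deviance terms x*log(x/u) are defined as 0 when x = 0; means are clamped
#    away from the boundary (at .center_eps) before log/logit with a warning.

.center_eps <- 1e-8
.domain_eps <- 1e-10

.stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "icclust_error")))
}

#' Supported loss family names
#'
#' Lower-case identifiers accepted by \code{\link{lossSpec}}. The hinge,
#' KL-divergence, Hamming, Canberra and multinomial rows of the generalized
#' convex clustering loss table are recognized names but not implemented
#' (the first two are never exercised by the method's benchmarks; the next
#' two are non-convex; multinomial requires a three-index formulation).
#'
#' @return character vector of implemented family names.
#' @export
lossFamilies <- function() {
  c("euclidean", "manhattan", "minkowski", "chebychev", "mahalanobis",
    "poisson_ll", "poisson_dev", "bernoulli_ll", "binomial_dev",
    "negbin_ll", "negbin_dev")
}

.recognized_unimplemented <- c("hinge", "kl_div", "canberra", "hamming",
                               "multinomial_ll", "multinomial_dev")

#' Construct a loss specification
#'
#' @param family one of \code{\link{lossFamilies}()}.
#' @param q Minkowski exponent (>= 1), required for \code{family =
#'   "minkowski"}.
#' @param C symmetric positive-definite matrix for \code{"mahalanobis"}.
#' @param theta negative-binomial dispersion (> 0), required for the
#'   \code{negbin_*} families.
#' @return a \linkS4class{LossSpec}.
#' @examples
#' lossSpec("manhattan")
#' lossSpec("minkowski", q = 3)
#' @export
lossSpec <- function(family, q = NULL, C = NULL, theta = NULL) {
  family <- match.arg(family, c(lossFamilies(), .recognized_unimplemented))
  if (family %in% .recognized_unimplemented)
    .stop("icclust_unsupported",
          "loss family '%s' is recognized but not implemented", family)
  params <- list()
  if (family == "minkowski") params$q <- q
  if (family == "mahalanobis") params$C <- C
  if (family %in% c("negbin_ll", "negbin_dev")) params$theta <- theta
  smooth <- !(family %in% c("manhattan", "chebychev") ||
              (family == "minkowski" && isTRUE(q == 1)))
  new("LossSpec", family = family, smooth = smooth, params = params)
}

.is_distance <- function(family)
  family %in% c("euclidean", "manhattan", "minkowski", "chebychev",
                "mahalanobis")

# Admissible data domain for X.
.check_data_domain <- function(loss, X) {
  f <- loss@family
  if (f %in% c("poisson_ll", "poisson_dev", "negbin_ll", "negbin_dev")) {
    if (any(X < 0))
      .stop("icclust_invalid_domain", "counts must be >= 0 for %s loss", f)
  } else if (f %in% c("bernoulli_ll", "binomial_dev")) {
    if (any(X < 0 | X > 1))
      .stop("icclust_invalid_domain", "data must lie in [0,1] for %s loss", f)
  }
  invisible(TRUE)
}

# Admissible centroid-parameter domain for U.
.check_param_domain <- function(loss, U) {
  f <- loss@family
  if (f %in% c("poisson_dev", "negbin_dev") && any(U <= 0))
    .stop("icclust_invalid_domain", "%s requires means U > 0", f)
  if (f == "binomial_dev" && any(U <= 0 | U >= 1))
    .stop("icclust_invalid_domain", "binomial_dev requires means U in (0,1)")
  invisible(TRUE)
}

.xlogxu <- function(x, u) {
  # x * log(x/u) with the convention 0*log(0/u) = 0
  out <- rep(0, length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos] / u[pos])
  out
}

#' Evaluate a convex clustering loss
#'
#' Sum over all samples (and features) of the per-element or per-row loss
#' between data \code{X} and centroids \code{U}. Log-likelihood families take
#' \code{U} on the natural-parameter scale, deviance families on the mean
#' scale.
#'
#' @param loss a \linkS4class{LossSpec}.
#' @param X,U numeric matrices (or vectors) of identical shape.
#' @return scalar loss value.
#' @examples
#' evalLoss(lossSpec("manhattan"), c(1, 2), c(0, 0))  # 3
#' evalLoss(lossSpec("poisson_ll"), 1, 0)             # 1
#' @export
evalLoss <- function(loss, X, U) {
  X <- as.matrix(X); U <- as.matrix(U)
  if (!all(dim(X) == dim(U)))
    .stop("icclust_contract", "X and U must have the same shape")
  .check_data_domain(loss, X)
  .check_param_domain(loss, U)
  D <- X - U
  val <- switch(loss@family,
    euclidean   = 0.5 * sum(D^2),
    manhattan   = sum(abs(D)),
    minkowski   = sum(rowSums(abs(D)^loss@params$q)^(1 / loss@params$q)),
    chebychev   = sum(apply(abs(D), 1L, max)),
    mahalanobis = {
      Ci <- solve(loss@params$C)
      sum((D %*% Ci) * D)
    },
    poisson_ll   = sum(-X * U + exp(U)),
    poisson_dev  = sum(.xlogxu(X, U) - X + U),
    bernoulli_ll = sum(-X * U + log1p(exp(-abs(U))) + pmax(U, 0)),
    binomial_dev = sum(.xlogxu(X, U) + .xlogxu(1 - X, 1 - U)),
    negbin_ll    = {
      th <- loss@params$theta
      sum(-X * U + (X + 1 / th) * log(1 / th + exp(U)))
    },
    negbin_dev   = {
      th <- loss@params$theta
      sum(.xlogxu(X, U) - (X + 1 / th) * log((1 + th * X) / (1 + th * U)))
    })
  if (!is.finite(val))
    .stop("icclust_invalid_domain", "non-finite loss value for %s",
          loss@family)
  val
}

#' Gradient of a smooth loss with respect to the centroids
#'
#' @inheritParams evalLoss
#' @return matrix of the same shape as \code{U}.
#' @examples
#' gradLoss(lossSpec("poisson_ll"), 1, 0)  # 0
#' @export
gradLoss <- function(loss, X, U) {
  if (!loss@smooth)
    .stop("icclust_unsupported", "gradLoss: %s loss is non-smooth",
          loss@family)
  X <- as.matrix(X); U <- as.matrix(U)
  if (!all(dim(X) == dim(U)))
    .stop("icclust_contract", "X and U must have the same shape")
  .check_data_domain(loss, X)
  .check_param_domain(loss, U)
  D <- X - U
  switch(loss@family,
    euclidean   = U - X,
    minkowski   = {
      q <- loss@params$q
      nrm <- rowSums(abs(D)^q)^(1 / q)
      G <- -sign(D) * abs(D)^(q - 1) * ifelse(nrm > 0, nrm^(1 - q), 0)
      G[nrm == 0, ] <- 0
      G
    },
    mahalanobis  = -2 * D %*% solve(loss@params$C),
    poisson_ll   = -X + exp(U),
    poisson_dev  = 1 - X / U,
    bernoulli_ll = -X + 1 / (1 + exp(-U)),
    binomial_dev = -X / U + (1 - X) / (1 - U),
    negbin_ll    = {
      th <- loss@params$theta
      eu <- exp(U)
      -X + (X + 1 / th) * eu / (1 / th + eu)
    },
    negbin_dev   = {
      th <- loss@params$theta
      -X / U + (th * X + 1) / (1 + th * U)
    })
}

# Euclidean projection of each row of A onto the l1 ball of radius r
# (duality partner of the Chebychev prox). Standard sort/threshold scheme.
.proj_l1_rows <- function(A, r) {
  t(apply(A, 1L, function(a) {
    if (sum(abs(a)) <= r) return(a)
    u <- sort(abs(a), decreasing = TRUE)
    cs <- cumsum(u)
    k <- max(which(u > (cs - r) / seq_along(u)))
    tau <- (cs[k] - r) / k
    sign(a) * pmax(abs(a) - tau, 0)
  }))
}

# prox of t * ||.||_q for one row vector (q > 1), by Moreau decomposition
# plus direct smooth minimization when nonzero.
.prox_lq_row <- function(a, t, q) {
  qs <- if (is.finite(q)) q / (q - 1) else 1
  dual_norm <- if (is.finite(qs)) sum(abs(a)^qs)^(1 / qs) else max(abs(a))
  if (dual_norm <= t) return(rep(0, length(a)))
  obj <- function(z) 0.5 * sum((z - a)^2) + t * sum(abs(z)^q)^(1 / q)
  grd <- function(z) {
    nrm <- sum(abs(z)^q)^(1 / q)
    g <- if (nrm > 0) t * sign(z) * abs(z)^(q - 1) * nrm^(1 - q) else 0 * z
    (z - a) + g
  }
  res <- stats::optim(a * 0.5, obj, grd, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  res$par
}

#' Proximal operator of a distance loss
#'
#' For distance losses expressible as \code{f(X - U)} with \code{f} convex
#' (manhattan, minkowski, chebychev), returns
#' \code{argmin_Z 0.5 * ||A - Z||^2 + t * f(Z)}: the elementwise
#' soft-threshold for manhattan, a rowwise l1-ball projection residual for
#' chebychev (Moreau decomposition) and a rowwise dual-checked numeric
#' minimization for general Minkowski exponents.
#'
#' @param loss a distance \linkS4class{LossSpec}.
#' @param A numeric matrix (or vector).
#' @param t nonnegative scalar threshold.
#' @return matrix of the same shape as \code{A}.
#' @examples
#' proxLoss(lossSpec("manhattan"), 3, 1)  # 2
#' @export
proxLoss <- function(loss, A, t) {
  if (t < 0) .stop("icclust_contract", "t must be >= 0")
  A <- as.matrix(A)
  if (t == 0) return(A)
  switch(loss@family,
    manhattan = sign(A) * pmax(abs(A) - t, 0),
    chebychev = A - .proj_l1_rows(A, t),
    minkowski = {
      q <- loss@params$q
      if (q == 1) sign(A) * pmax(abs(A) - t, 0)
      else t(apply(A, 1L, .prox_lq_row, t = t, q = q))
    },
    .stop("icclust_unsupported",
          "proxLoss: no proximal operator for %s loss", loss@family))
}

# 1-D restriction of a loss for numeric center finding.
.loss_1d <- function(loss) {
  switch(loss@family,
    minkowski = function(x, u) abs(x - u),
    chebychev = function(x, u) abs(x - u),
    function(x, u) evalLoss(loss, matrix(x), matrix(u, nrow = length(x))))
}

#' Columnwise loss-specific centers
#'
#' The minimizer of the loss summed over each column: mean (euclidean,
#' mahalanobis, *_dev families), median (manhattan), log of the mean
#' (poisson_ll, negbin_ll), logit of the mean (bernoulli_ll); Minkowski and
#' Chebychev centers are found by per-column derivative-free minimization of
#' the 1-D restriction of the loss. Degenerate means (0 for log, 0/1 for
#' logit) are clamped with a warning.
#'
#' @param loss a \linkS4class{LossSpec}.
#' @param X numeric matrix (or vector) of admissible data.
#' @return numeric vector of length \code{ncol(X)}.
#' @examples
#' lossCenter(lossSpec("manhattan"), c(1, 2, 9))   # 2
#' lossCenter(lossSpec("poisson_ll"), c(1, 2, 6))  # log(3)
#' @export
lossCenter <- function(loss, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L)
    .stop("icclust_contract", "X must be nonempty")
  .check_data_domain(loss, X)
  f <- loss@family
  m <- colMeans(X)
  clamp_log <- function(m) {
    if (any(m < .center_eps)) {
      warning(warningCondition(
        "degenerate column mean clamped before log/logit",
        class = c("icclust_degenerate_center", "icclust_warning")))
      m <- pmax(m, .center_eps)
    }
    m
  }
  switch(f,
    euclidean   = m,
    mahalanobis = m,  # quadratic form: the mean minimizes for any PD C
    manhattan   = apply(X, 2L, stats::median),
    poisson_dev = clamp_log(m),  # 0 mean is outside the deviance domain
    negbin_dev  = clamp_log(m),
    binomial_dev = pmin(pmax(m, .center_eps), 1 - .center_eps),
    poisson_ll  = log(clamp_log(m)),
    negbin_ll   = log(clamp_log(m)),
    bernoulli_ll = {
      m2 <- pmin(clamp_log(m), 1 - .center_eps)
      if (any(m > 1 - .center_eps))
        warning(warningCondition(
          "degenerate column mean clamped before logit",
          class = c("icclust_degenerate_center", "icclust_warning")))
      log(m2 / (1 - m2))
    },
    {
      # no closed form: 1-D minimization per column, tolerance 1e-8
      l1 <- .loss_1d(loss)
      apply(X, 2L, function(x) {
        rng <- range(x)
        if (rng[1] == rng[2]) return(rng[1])
        stats::optimize(function(u) sum(l1(x, u)), interval = rng,
                        tol = 1e-8)$minimum
      })
    })
}

#' Construct a data view
#'
#' Wraps a sample-by-feature matrix with its loss, computing the per-feature
#' loss-specific centers and, unless overridden, the null-deviance loss weight
#' \code{pi = 1 / loss(X, center)} that puts heterogeneous views on a common
#' scale.
#'
#' @param X numeric matrix (samples in rows).
#' @param loss a \linkS4class{LossSpec} or a family name passed to
#'   \code{\link{lossSpec}}.
#' @param weight optional positive scalar overriding the null-deviance weight.
#' @param ... further arguments to \code{\link{lossSpec}} when \code{loss} is
#'   a name.
#' @return a \linkS4class{DataView}.
#' @examples
#' v <- dataView(matrix(rnorm(20), 10, 2), "euclidean")
#' @export
dataView <- function(X, loss, weight = NULL, ...) {
  if (is.character(loss)) loss <- lossSpec(loss, ...)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  center <- lossCenter(loss, X)
  view <- new("DataView", X = X, loss = loss, center = center, weight = 1)
  view@weight <- if (is.null(weight)) nullDevianceWeight(view) else weight
  validObject(view)
  view
}

# Loss at the saturated model (centroids equal to the data, on the
# parameter scale). Zero for distances and deviances; for log-likelihood
# families this is the value at u = link(x), making the null deviance below
# a genuine deviance (nonnegative).
.saturated_loss <- function(view) {
  f <- view@loss@family
  if (!f %in% c("poisson_ll", "bernoulli_ll", "negbin_ll")) return(0)
  evalLoss(view@loss, view@X, .param_image(view))
}

#' Null-deviance loss weight
#'
#' The reciprocal of the view's null deviance: the loss at the loss-specific
#' centers (broadcast to all rows) minus the loss at saturation. For
#' distance and deviance losses the saturated loss is zero, so this is
#' simply the loss at the centers; for log-likelihood families the
#' subtraction makes the quantity a genuine (nonnegative) deviance - the
#' raw log-likelihood value at the center can have either sign. Views whose
#' columns are all (numerically) constant have zero null deviance and are
#' rejected.
#'
#' @param view a \linkS4class{DataView}.
#' @param tol positive tolerance below which the null deviance is treated as
#'   degenerate.
#' @return positive scalar.
#' @export
nullDevianceWeight <- function(view, tol = 1e-10) {
  Xt <- matrix(view@center, nrow = nrow(view@X), ncol = ncol(view@X),
               byrow = TRUE)
  dev <- evalLoss(view@loss, view@X, Xt) - .saturated_loss(view)
  if (!is.finite(dev) || dev <= tol)
    .stop("icclust_degenerate_view",
          "null deviance is numerically zero (all columns constant?)")
  1 / dev
}

# Broadcast centers of a view to a full matrix.
.center_matrix <- function(view)
  matrix(view@center, nrow = nrow(view@X), ncol = ncol(view@X), byrow = TRUE)

# Centroid matrix implied by a partition: each sample's row is its
# cluster's columnwise loss-specific center. Used to score feature
# importance at a fitted partition without the gamma-contraction bias of
# the raw ADMM centroids.
.partition_centers <- function(view, labels) {
  U <- matrix(0, nrow(view@X), ncol(view@X))
  for (g in split(seq_along(labels), labels)) {
    ctr <- suppressWarnings(
      lossCenter(view@loss, view@X[g, , drop = FALSE]))
    U[g, ] <- matrix(ctr, length(g), ncol(view@X), byrow = TRUE)
  }
  U
}

# Image of the data on the centroid-parameter scale: the gamma -> 0,
# alpha -> 0 limit of the fitted centroids (clamped link transform for
# natural-parameter families, the data itself otherwise).
.param_image <- function(view) {
  X <- view@X
  switch(view@loss@family,
    poisson_ll = ,
    negbin_ll = log(pmax(X, .center_eps)),
    bernoulli_ll = {
      Xc <- pmin(pmax(X, .center_eps), 1 - .center_eps)
      log(Xc / (1 - Xc))
    },
    binomial_dev = pmin(pmax(X, .center_eps), 1 - .center_eps),
    poisson_dev = ,
    negbin_dev = pmax(X, .center_eps),
    X)
}
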