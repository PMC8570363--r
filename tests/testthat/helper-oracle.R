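# Independent convex oracle for small problems: minimizes the penalized
# objective by BFGS on a smoothed surrogate with decreasing smoothing
# (sqrt(x^2 + mu^2) for absolute values and group norms), entirely separate
# from the ADMM code paths. Losses are hand-coded here on purpose.

# elementwise losses and gradients (euclidean / manhattan / bernoulli_ll)
.or_loss <- function(family, x, u, mu) {
  switch(family,
    euclidean = 0.5 * (x - u)^2,
    manhattan = sqrt((x - u)^2 + mu^2) - mu,
    bernoulli_ll = -x * u + log1p(exp(-abs(u))) + pmax(u, 0))
}
.or_grad <- function(family, x, u, mu) {
  switch(family,
    euclidean = u - x,
    manhattan = (u - x) / sqrt((x - u)^2 + mu^2),
    bernoulli_ll = -x + 1 / (1 + exp(-u)))
}
.or_norm <- function(v, mu) sqrt(sum(v^2) + mu^2) - mu

# views: list of list(X, family, pi, center); edges: matrix, weights w;
# zeta: list of per-view vectors
oracle_solve <- function(views, edges, w, gamma, alpha, zeta = NULL) {
  K <- length(views)
  n <- nrow(views[[1]]$X)
  pk <- vapply(views, function(v) ncol(v$X), 1L)
  if (is.null(zeta)) zeta <- lapply(pk, function(p) rep(1, p))
  unpack <- function(th) {
    out <- vector("list", K); o <- 0L
    for (k in seq_len(K)) {
      out[[k]] <- matrix(th[(o + 1L):(o + n * pk[k])], n, pk[k])
      o <- o + n * pk[k]
    }
    out
  }
  obj <- function(th, mu) {
    U <- unpack(th)
    val <- 0
    for (k in seq_len(K)) {
      v <- views[[k]]
      val <- val + v$pi * sum(.or_loss(v$family, v$X, U[[k]], mu))
      if (alpha > 0) {
        Ctr <- matrix(v$center, n, pk[k], byrow = TRUE)
        val <- val + alpha * sum(vapply(seq_len(pk[k]), function(j)
          zeta[[k]][j] * .or_norm(U[[k]][, j] - Ctr[, j], mu), 1))
      }
    }
    if (gamma > 0 && nrow(edges)) {
      for (l in seq_len(nrow(edges))) {
        d <- unlist(lapply(U, function(Uk)
          Uk[edges[l, 1], ] - Uk[edges[l, 2], ]))
        val <- val + gamma * w[l] * .or_norm(d, mu)
      }
    }
    val
  }
  grad <- function(th, mu) {
    U <- unpack(th)
    G <- lapply(seq_len(K), function(k) {
      v <- views[[k]]
      g <- v$pi * .or_grad(v$family, v$X, U[[k]], mu)
      if (alpha > 0) {
        Ctr <- matrix(v$center, n, pk[k], byrow = TRUE)
        for (j in seq_len(pk[k])) {
          d <- U[[k]][, j] - Ctr[, j]
          g[, j] <- g[, j] + alpha * zeta[[k]][j] *
            d / sqrt(sum(d^2) + mu^2)
        }
      }
      g
    })
    if (gamma > 0 && nrow(edges)) {
      for (l in seq_len(nrow(edges))) {
        d <- unlist(lapply(U, function(Uk)
          Uk[edges[l, 1], ] - Uk[edges[l, 2], ]))
        s <- gamma * w[l] / sqrt(sum(d^2) + mu^2)
        o <- 0L
        for (k in seq_len(K)) {
          dk <- d[(o + 1L):(o + pk[k])]
          G[[k]][edges[l, 1], ] <- G[[k]][edges[l, 1], ] + s * dk
          G[[k]][edges[l, 2], ] <- G[[k]][edges[l, 2], ] - s * dk
          o <- o + pk[k]
        }
      }
    }
    unlist(G)
  }
  th <- unlist(lapply(views, function(v) v$X))
  for (mu in c(1e-1, 1e-3, 1e-5, 1e-7)) {
    th <- stats::optim(th, obj, grad, mu = mu, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-15))$par
  }
  list(U = unpack(th), objective = obj(th, 0))
}

# package-side view builder mirrored for convenience in tests
oracle_views_from <- function(dviews) {
  lapply(dviews, function(v)
    list(X = v@X, family = v@loss@family, pi = v@weight, center = v@center))
}
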